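solute,solvent
butyl paraben,methanol
butyl paraben,ethyl acetate
butyl paraben,ethanol
butyl paraben,1-propanol
butyl paraben,acetonitrile
butyl paraben,acetone
fenoxycarb,methanol
fenoxycarb,toluene
fenoxycarb,ethanol
fenoxycarb,2-propanol
fenoxycarb,ethyl acetate
fenofibrate,methanol
fenofibrate,ethyl acetate
fenofibrate,ethanol
fenofibrate,1-propanol
fenofibrate,2-propanol
fenofibrate,acetonitrile
risperidone,methanol
risperidone,toluene
risperidone,ethanol
risperidone,1-propanol
risperidone,2-propanol
risperidone,1-butanol
risperidone,acetone
risperidone,ethyl acetate
butamben,methanol
butamben,1-propanol
butamben,2-propanol
butamben,1-butanol
butamben,toluene
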