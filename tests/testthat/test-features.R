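test_that("heat-capacity difference is linear with value q at the melting point", {
  expect_equal(delta_cp("butyl paraben", 340.5), 77.2)
  expect_equal(delta_cp("risperidone", 442.4), 158.1)
  # 124.3 + 0.5192 * (-50)
  expect_equal(delta_cp("fenofibrate", 302.05), 98.34)
  expect_equal(delta_cp(list(q_J_K_mol = 10, r_J_K2_mol = 0.5, Tm_K = 300),
                        c(290, 300, 310)), c(5, 10, 15))
})

test_that("one-hot blocks activate exactly one solute and one solvent indicator", {
  corp <- toy_corpus()
  d <- build_design_matrix(corp)
  ind <- d$schema$kind == "indicator"
  expect_equal(sum(ind), 4) # 2 solutes + 2 solvents
  su_block <- startsWith(d$schema$name, "solute=")
  sv_block <- startsWith(d$schema$name, "solvent=")
  expect_true(all(rowSums(d$X[, su_block]) == 1))
  expect_true(all(rowSums(d$X[, sv_block]) == 1))
  # lexicographic and shuffle-invariant column order
  expect_equal(d$schema$name[su_block],
               paste0("solute=", sort(unique(corp$records$solute))))
  shuffled <- solubility_corpus(toy_records()[c(5, 1, 6, 3, 2, 4), ])
  expect_equal(build_design_matrix(shuffled)$schema$name, d$schema$name)
})

test_that("a name unseen at schema-fit time encodes as an all-zero block", {
  corp <- toy_corpus()
  d <- build_design_matrix(corp)
  new_rec <- tibble::tibble(solute = "butamben", solvent = "methanol",
                            T_K = 298, x = 0.05)
  new_corp <- solubility_corpus(new_rec)
  d_new <- build_design_matrix(new_corp, schema = d$schema)
  su_block <- startsWith(d$schema$name, "solute=")
  expect_equal(unname(rowSums(d_new$X[, su_block, drop = FALSE])), 0)
  expect_equal(unname(d_new$X[1, "solvent=methanol"]), 1)
  # numeric descriptors still flow through
  expect_false(d_new$X[1, "Tm_K"] == 0 && d_new$X[1, "dHfus_kJ_mol"] == 0)
})

test_that("standardization uses population spread fitted on fit_rows only", {
  X <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "T_K"))
  schema <- tibble::tibble(name = "T_K", kind = "continuous", monotone = 1L,
                           center = NA_real_, spread = NA_real_)
  sc <- fit_apply_scaler(X, schema)
  expect_equal(sc$X[, 1], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(round(unname(sc$X[3, 1]), 4), 1.2247)
  expect_equal(mean(sc$X[, 1]), 0)

  # constant column guard
  Xc <- matrix(rep(5, 4), ncol = 1, dimnames = list(NULL, "T_K"))
  expect_equal(unname(fit_apply_scaler(Xc, schema)$X[, 1]), rep(0, 4))

  # prediction rows scaled with training statistics
  X2 <- matrix(c(1, 2, 3, 10), ncol = 1, dimnames = list(NULL, "T_K"))
  sc2 <- fit_apply_scaler(X2, schema, fit_rows = 1:3)
  expect_equal(sc2$X[1:3, 1], sc$X[, 1])
  expect_equal(sc2$schema$center[1], 2)
})

test_that("design matrix has the documented layout and ln-x target", {
  corp <- generate_corpus(small_config())
  d <- build_design_matrix(corp)
  n_solutes <- length(unique(corp$records$solute))
  n_solvents <- length(unique(corp$records$solvent))
  expect_equal(ncol(d$X), n_solutes + n_solvents + 9)
  expect_equal(d$y, log(corp$records$x))
  expect_true(all(d$y <= 0))
  expect_equal(sum(d$schema$monotone), 1)
  expect_equal(d$schema$name[d$schema$monotone == 1], "T_K")
  expect_false(anyNA(d$X))
  # dCp column equals direct recomputation row-wise (undo scaling first)
  j <- which(d$schema$name == "dCp_J_K_mol")
  raw_dcp <- d$X[, j] * d$schema$spread[j] + d$schema$center[j]
  expected <- purrr::pmap_dbl(corp$records, function(solute, solvent, T_K, x) {
    delta_cp(as.list(corp$solutes[corp$solutes$name == solute, ]), T_K)
  })
  expect_equal(raw_dcp, expected, tolerance = 1e-10)
})

test_that("two records differing only in T differ only in T and dCp columns", {
  rec <- tibble::tibble(solute = "fenofibrate", solvent = "acetone",
                        T_K = c(290, 310), x = c(0.01, 0.02))
  corp <- solubility_corpus(rec)
  X <- solboost:::raw_feature_matrix(corp, feature_schema(corp))
  diff_cols <- colnames(X)[X[1, ] != X[2, ]]
  expect_setequal(diff_cols, c("T_K", "dCp_J_K_mol"))
})

test_that("rebuilding with a stored schema is deterministic and round-trips", {
  corp <- toy_corpus()
  d <- build_design_matrix(corp)
  d2 <- build_design_matrix(corp, schema = d$schema)
  expect_identical(d$X, d2$X)
  f <- withr::local_tempfile(fileext = ".json")
  write_schema(d$schema, f)
  expect_equal(read_schema(f), d$schema)
})

test_that("standardization preserves ordering of the temperature column", {
  corp <- generate_corpus(small_config())
  d <- build_design_matrix(corp)
  raw_T <- corp$records$T_K
  expect_equal(order(d$X[, "T_K"]), order(raw_T))
})
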