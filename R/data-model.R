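#' Normalize a compound or solvent name
#'
#' Names are matched case-insensitively with leading/trailing whitespace
#' stripped and internal runs of whitespace collapsed, so that prose
#' spellings ("Methanol ") resolve to table spellings ("methanol").
#'
#' @param x Character vector of names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_name(c("Methanol ", "Butyl  Paraben"))
normalize_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

record_cols <- c("solute", "solvent", "T_K", "x")

#' Read solubility records from a delimited text file
#'
#' The file must carry the header `solute,solvent,T_K,x`: solute and solvent
#' names, absolute temperature in kelvin, and mole-fraction solubility in
#' (0, 1]. Decimal separator is `.`; encoding UTF-8.
#'
#' @param path Path to the records file.
#' @param delim Field delimiter (default comma).
#' @return A tibble with columns `solute`, `solvent`, `T_K`, `x`, one row per
#'   data row in file order.
#' @seealso [write_records()], [solubility_corpus()]
#' @export
read_records <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("records file does not exist: ", path))
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           comment = "#", progress = FALSE)
  missing <- setdiff(record_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("records file is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  raw <- raw[record_cols]
  t_num <- suppressWarnings(as.numeric(raw$T_K))
  x_num <- suppressWarnings(as.numeric(raw$x))
  bad <- which(is.na(t_num) | is.na(x_num))
  if (length(bad) > 0) {
    # +1 for the header line
    abort(paste0("non-numeric T_K or x at line ", bad[1] + 1L, " of ", path))
  }
  rec <- tibble::tibble(solute = raw$solute, solvent = raw$solvent,
                        T_K = t_num, x = x_num)
  check_records(rec)
  rec
}

check_records <- function(records) {
  if (any(!nzchar(trimws(records$solute))) || any(!nzchar(trimws(records$solvent)))) {
    abort("solute and solvent names must be non-empty")
  }
  if (any(records$T_K <= 0)) {
    abort("temperatures must be positive (kelvin)")
  }
  bad_x <- which(records$x <= 0 | records$x > 1)
  if (length(bad_x) > 0) {
    abort(paste0("mole fraction x must lie in (0, 1]; offending value ",
                 format(records$x[bad_x[1]]), " for (",
                 records$solute[bad_x[1]], ", ", records$solvent[bad_x[1]], ", ",
                 format(records$T_K[bad_x[1]]), " K)"))
  }
  key <- paste(normalize_name(records$solute), normalize_name(records$solvent),
               records$T_K, sep = " | ")
  dup <- duplicated(key)
  if (any(dup)) {
    abort(paste0("duplicate (solute, solvent, T) triple(s): ",
                 paste(unique(key[dup]), collapse = "; ")))
  }
  invisible(records)
}

#' Write solubility records to a delimited text file
#'
#' Inverse of [read_records()]: a valid record table round-trips
#' field-for-field.
#'
#' @param records Tibble with columns `solute`, `solvent`, `T_K`, `x`.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, delim = ",") {
  readr::write_delim(records[record_cols], path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Packaged solute descriptor table
#'
#' Thermodynamic descriptors for the five model compounds: melting point
#' `Tm_K` (K), enthalpy of fusion at the melting point `dHfus_kJ_mol`
#' (kJ/mol), the two heat-capacity-difference parameters `q_J_K_mol`
#' (J/K/mol) and `r_J_K2_mol` (J/K^2/mol), and the Hansen solubility
#' parameter `hansen_MPa05` (MPa^0.5). The butamben row is flagged
#' `provisional`: its source rendering is typographically ambiguous and the
#' shipped values beyond the melting point are a best-effort reading meant to
#' be overridden by a user-supplied descriptor file where better values are
#' available.
#'
#' @return A tibble, one row per solute.
#' @export
solute_descriptors <- function() {
  load_solute_descriptors(system.file("extdata", "solute_descriptors.csv",
                                      package = "solboost", mustWork = TRUE))
}

#' Packaged solvent descriptor table
#'
#' Dielectric constants (dimensionless) and normal boiling points (K) of the
#' nine study solvents.
#'
#' @return A tibble, one row per solvent.
#' @export
solvent_descriptors <- function() {
  load_solvent_descriptors(system.file("extdata", "solvent_descriptors.csv",
                                       package = "solboost", mustWork = TRUE))
}

#' Load descriptor tables from delimited files
#'
#' Readers for user-supplied descriptor tables following the packaged
#' headers: `name,Tm_K,dHfus_kJ_mol,q_J_K_mol,r_J_K2_mol,hansen_MPa05` for
#' solutes and `name,dielectric,bp_K` for solvents. Names are normalized with
#' [normalize_name()]; extra columns are carried through untouched.
#'
#' @param path Path to the descriptor file.
#' @return A tibble keyed by normalized `name`.
#' @export
load_solute_descriptors <- function(path) {
  d <- read_descriptor_file(path, c("name", "Tm_K", "dHfus_kJ_mol",
                                    "q_J_K_mol", "r_J_K2_mol", "hansen_MPa05"))
  stopifnot(all(d$Tm_K > 0), all(d$dHfus_kJ_mol > 0), all(d$q_J_K_mol > 0))
  d
}

#' @rdname load_solute_descriptors
#' @export
load_solvent_descriptors <- function(path) {
  d <- read_descriptor_file(path, c("name", "dielectric", "bp_K"))
  stopifnot(all(d$dielectric > 1), all(d$bp_K > 0))
  d
}

read_descriptor_file <- function(path, required) {
  if (!file.exists(path)) {
    abort(paste0("descriptor file does not exist: ", path))
  }
  d <- readr::read_csv(path, col_types = readr::cols(name = readr::col_character()),
                       progress = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    abort(paste0("descriptor file ", path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  d$name <- normalize_name(d$name)
  if (anyDuplicated(d$name)) {
    abort("duplicate descriptor names after normalization")
  }
  d
}

#' Assemble a solubility corpus
#'
#' Binds a record table to solute and solvent descriptor tables and enforces
#' the corpus invariants: every record's compound resolves (after name
#' normalization) to a descriptor row, and no (solute, solvent, T) triple is
#' duplicated. Record names are rewritten to their normalized form so that
#' grouping and joins are exact.
#'
#' @param records Tibble of records (see [read_records()]).
#' @param solutes Solute descriptor tibble; default the packaged table.
#' @param solvents Solvent descriptor tibble; default the packaged table.
#' @param validate If `FALSE`, invariants are not enforced (useful to build a
#'   deliberately broken corpus for [validate_corpus()]).
#' @return An object of class `sb_corpus`: a list with elements `records`,
#'   `solutes`, `solvents`.
#' @export
#' @examples
#' rec <- tibble::tibble(solute = "butyl paraben", solvent = "methanol",
#'                       T_K = c(283, 293), x = c(0.1, 0.15))
#' corp <- solubility_corpus(rec)
#' nrow(corp$records)
solubility_corpus <- function(records, solutes = solute_descriptors(),
                              solvents = solvent_descriptors(), validate = TRUE) {
  records <- tibble::as_tibble(records)[record_cols]
  records$solute <- normalize_name(records$solute)
  records$solvent <- normalize_name(records$solvent)
  out <- structure(list(records = records, solutes = solutes, solvents = solvents),
                   class = "sb_corpus")
  if (validate) {
    check_records(records)
    miss_su <- setdiff(unique(records$solute), solutes$name)
    if (length(miss_su) > 0) {
      abort(paste0("no solute descriptors for: ", paste(miss_su, collapse = ", ")))
    }
    miss_sv <- setdiff(unique(records$solvent), solvents$name)
    if (length(miss_sv) > 0) {
      abort(paste0("no solvent descriptors for: ", paste(miss_sv, collapse = ", ")))
    }
  }
  out
}

#' @export
print.sb_corpus <- function(x, ...) {
  np <- nrow(dplyr::distinct(x$records, .data$solute, .data$solvent))
  cat("<sb_corpus> ", nrow(x$records), " records, ", np, " solute-solvent pairs, ",
      length(unique(x$records$solute)), " solutes, ",
      length(unique(x$records$solvent)), " solvents\n", sep = "")
  invisible(x)
}

#' Summarize a corpus and flag invariant breaches
#'
#' Report-only: counts records per (solute, solvent) pair with the pair's
#' temperature range, and lists invariant breaches (missing descriptors,
#' out-of-range mole fractions, duplicate triples) without mutating the data.
#'
#' @param corpus An `sb_corpus` (possibly built with `validate = FALSE`).
#' @return An object of class `sb_validation`: list with tibbles `groups`
#'   (solute, solvent, n, T_min, T_max) and `breaches` (kind, detail).
#' @export
validate_corpus <- function(corpus) {
  rec <- corpus$records
  if (nrow(rec) == 0) {
    return(structure(list(
      groups = tibble::tibble(solute = character(), solvent = character(),
                              n = integer(), T_min = double(), T_max = double()),
      breaches = tibble::tibble(kind = character(), detail = character())),
      class = "sb_validation"))
  }
  groups <- rec |>
    dplyr::group_by(.data$solute, .data$solvent) |>
    dplyr::summarise(n = dplyr::n(), T_min = min(.data$T_K), T_max = max(.data$T_K),
                     .groups = "drop") |>
    dplyr::arrange(.data$solute, .data$solvent)
  breaches <- tibble::tibble(kind = character(), detail = character())
  add <- function(kind, detail) {
    breaches <<- dplyr::bind_rows(breaches, tibble::tibble(kind = kind, detail = detail))
  }
  for (s in setdiff(unique(rec$solute), corpus$solutes$name)) {
    add("missing_solute_descriptor", s)
  }
  for (s in setdiff(unique(rec$solvent), corpus$solvents$name)) {
    add("missing_solvent_descriptor", s)
  }
  bad_x <- which(rec$x <= 0 | rec$x > 1)
  for (i in bad_x) {
    add("x_out_of_range", paste0(rec$solute[i], " | ", rec$solvent[i], " | ",
                                 rec$T_K[i], " K: x = ", format(rec$x[i])))
  }
  if (any(rec$T_K <= 0)) add("nonpositive_temperature", paste(sum(rec$T_K <= 0), "row(s)"))
  key <- paste(rec$solute, rec$solvent, rec$T_K, sep = " | ")
  for (k in unique(key[duplicated(key)])) add("duplicate_triple", k)
  structure(list(groups = groups, breaches = breaches), class = "sb_validation")
}

#' @export
print.sb_validation <- function(x, ...) {
  cat("<sb_validation> ", nrow(x$groups), " solute-solvent group(s), ",
      nrow(x$breaches), " breach(es)\n", sep = "")
  if (nrow(x$groups) > 0) print(x$groups, n = 10)
  if (nrow(x$breaches) > 0) {
    cat("breaches:\n")
    print(x$breaches)
  }
  invisible(x)
}
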