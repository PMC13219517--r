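#' Heat-capacity difference between liquid and solid solute
#'
#' The difference between the heat capacities of the supercooled liquid and
#' the solid phase of the solute is modelled as linear in temperature,
#' `dCp(T) = q + r * (T - Tm)`, with `q` (J/K/mol) its value at the melting
#' point and `r` (J/K^2/mol) its slope.
#'
#' @param solute A single descriptor row (list, one-row data frame, or a
#'   name looked up in the packaged table) carrying `q_J_K_mol`,
#'   `r_J_K2_mol`, `Tm_K`.
#' @param T_K Temperature(s) in kelvin; vectorized.
#' @return dCp in J/K/mol, same length as `T_K`.
#' @export
#' @examples
#' delta_cp("butyl paraben", 340.5) # equals q at the melting point
delta_cp <- function(solute, T_K) {
  solute <- resolve_solute(solute)
  stopifnot(all(T_K > 0))
  solute$q_J_K_mol + solute$r_J_K2_mol * (T_K - solute$Tm_K)
}

resolve_solute <- function(solute, table = solute_descriptors()) {
  if (is.character(solute) && length(solute) == 1) {
    nm <- normalize_name(solute)
    row <- table[table$name == nm, ]
    if (nrow(row) != 1) abort(paste0("unknown solute: ", solute))
    return(as.list(row))
  }
  solute <- as.list(solute)
  needed <- c("q_J_K_mol", "r_J_K2_mol", "Tm_K")
  if (!all(needed %in% names(solute))) {
    abort(paste0("solute descriptor must carry ", paste(needed, collapse = ", ")))
  }
  solute
}

continuous_cols <- c("T_K", "dHfus_kJ_mol", "Tm_K", "q_J_K_mol", "r_J_K2_mol",
                     "hansen_MPa05", "dielectric", "bp_K", "dCp_J_K_mol")

#' Build the feature schema for a corpus
#'
#' Fixes the design-matrix column order: one 0/1 indicator per solute name
#' and per solvent name present in the corpus records (each block in
#' lexicographic order), followed by the continuous block `T_K`, `dHfus`,
#' `Tm`, `q`, `r`, `hansen`, `dielectric`, `bp`, `dCp(T)`. Exactly one
#' column, raw temperature `T_K`, carries the `+1` monotone flag; indicator
#' columns are never standardized. Scaler statistics are filled in by
#' [fit_apply_scaler()].
#'
#' @param corpus An `sb_corpus`.
#' @return A `feature_schema`: tibble with columns `name`, `kind`
#'   (`"indicator"` or `"continuous"`), `monotone` (0 or +1), `center`,
#'   `spread` (NA until fitted).
#' @export
feature_schema <- function(corpus) {
  solute_levels <- sort(unique(corpus$records$solute))
  solvent_levels <- sort(unique(corpus$records$solvent))
  ind <- c(paste0("solute=", solute_levels), paste0("solvent=", solvent_levels))
  schema <- tibble::tibble(
    name = c(ind, continuous_cols),
    kind = c(rep("indicator", length(ind)), rep("continuous", length(continuous_cols))),
    monotone = as.integer(c(rep(0L, length(ind)), ifelse(continuous_cols == "T_K", 1L, 0L))),
    center = NA_real_,
    spread = NA_real_
  )
  class(schema) <- c("feature_schema", class(schema))
  schema
}

schema_levels <- function(schema, block) {
  pre <- paste0(block, "=")
  sub(pre, "", schema$name[startsWith(schema$name, pre)], fixed = TRUE)
}

raw_feature_matrix <- function(corpus, schema) {
  rec <- corpus$records
  n <- nrow(rec)
  su <- corpus$solutes[match(rec$solute, corpus$solutes$name), ]
  sv <- corpus$solvents[match(rec$solvent, corpus$solvents$name), ]
  if (anyNA(su$name)) {
    abort(paste0("no solute descriptors for: ",
                 paste(unique(rec$solute[is.na(su$name)]), collapse = ", ")))
  }
  if (anyNA(sv$name)) {
    abort(paste0("no solvent descriptors for: ",
                 paste(unique(rec$solvent[is.na(sv$name)]), collapse = ", ")))
  }
  X <- matrix(0, nrow = n, ncol = nrow(schema), dimnames = list(NULL, schema$name))
  # indicator blocks; a name outside the schema's levels leaves its block all-zero
  for (lev in schema_levels(schema, "solute")) {
    X[, paste0("solute=", lev)] <- as.numeric(rec$solute == lev)
  }
  for (lev in schema_levels(schema, "solvent")) {
    X[, paste0("solvent=", lev)] <- as.numeric(rec$solvent == lev)
  }
  X[, "T_K"] <- rec$T_K
  X[, "dHfus_kJ_mol"] <- su$dHfus_kJ_mol
  X[, "Tm_K"] <- su$Tm_K
  X[, "q_J_K_mol"] <- su$q_J_K_mol
  X[, "r_J_K2_mol"] <- su$r_J_K2_mol
  X[, "hansen_MPa05"] <- su$hansen_MPa05
  X[, "dielectric"] <- sv$dielectric
  X[, "bp_K"] <- sv$bp_K
  X[, "dCp_J_K_mol"] <- su$q_J_K_mol + su$r_J_K2_mol * (rec$T_K - su$Tm_K)
  X
}

#' Standardize continuous columns of a feature matrix
#'
#' Replaces each continuous column by `(value - center) / spread`, with
#' center and spread computed on `fit_rows` only (prediction rows are scaled
#' with training statistics). Spread is the population standard deviation; a
#' constant column (zero spread) maps to zeros. Indicator columns are left
#' untouched. Standardization with positive spread is order-preserving, so
#' the monotone flag on scaled temperature is equivalent to one on raw
#' temperature.
#'
#' @param X Numeric matrix whose columns follow `schema`.
#' @param schema A `feature_schema`; if its scaler statistics are already
#'   filled they are reused and `fit_rows` is ignored.
#' @param fit_rows Row indices on which to compute the statistics (default
#'   all rows).
#' @return List with elements `X` (scaled matrix) and `schema` (statistics
#'   filled in).
#' @export
fit_apply_scaler <- function(X, schema, fit_rows = seq_len(nrow(X))) {
  cont <- which(schema$kind == "continuous")
  fitted <- !anyNA(schema$center[cont])
  if (!fitted) {
    if (length(fit_rows) == 0) abort("fit_rows must be non-empty")
    for (j in cont) {
      v <- X[fit_rows, j]
      schema$center[j] <- mean(v)
      schema$spread[j] <- sqrt(mean((v - mean(v))^2))
    }
  }
  for (j in cont) {
    s <- schema$spread[j]
    X[, j] <- if (s > 0) (X[, j] - schema$center[j]) / s else 0
  }
  list(X = X, schema = schema)
}

#' Build a design matrix for training or prediction
#'
#' Turns a corpus into the numeric matrix the booster consumes: indicator
#' blocks for solute and solvent names, the raw-temperature column, the
#' solute melting/heat-capacity/Hansen descriptors, the solvent dielectric
#' constant and boiling point, and the derived `dCp(T)` column. The target is
#' `ln x`. Without `schema` (training path) the schema is fit on the corpus,
#' including the scaler statistics; with `schema` (prediction path) it is
#' reused verbatim, and a solute or solvent name absent from the schema's
#' indicator levels encodes as all-zero in its block — this is what makes
#' prediction for an entirely new compound possible, with information flowing
#' through its numeric descriptors.
#'
#' @param corpus An `sb_corpus`.
#' @param schema Optional fitted `feature_schema` from a previous call.
#' @return An object of class `sb_design`: list with `X` (scaled matrix),
#'   `y` (ln x), `schema`, and `keys` (tibble solute/solvent/T_K).
#' @export
#' @examples
#' corp <- generate_corpus(generator_config(seed = 1))
#' d <- build_design_matrix(corp)
#' dim(d$X)
build_design_matrix <- function(corpus, schema = NULL) {
  fit <- is.null(schema)
  if (fit) schema <- feature_schema(corpus)
  X <- raw_feature_matrix(corpus, schema)
  sc <- fit_apply_scaler(X, schema)
  structure(list(X = sc$X, y = log(corpus$records$x), schema = sc$schema,
                 keys = corpus$records[c("solute", "solvent", "T_K")]),
            class = "sb_design")
}

#' @export
print.sb_design <- function(x, ...) {
  cat("<sb_design> ", nrow(x$X), " rows x ", ncol(x$X), " features (",
      sum(x$schema$kind == "indicator"), " indicators), target ln x in [",
      format(min(x$y), digits = 4), ", ", format(max(x$y), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Persist and restore a feature schema
#'
#' The schema travels beside the model file as a small JSON document holding
#' name, kind, monotone flag and scaler statistics per column; reading it
#' back is the identity.
#'
#' @param schema A `feature_schema`.
#' @param path File path.
#' @return `read_schema` returns the `feature_schema`; `write_schema` returns
#'   `path` invisibly.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(list(format = "solboost/schema", version = 1L,
                            columns = as.data.frame(schema)),
                       path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "solboost/schema")) {
    abort(paste0("not a schema file: ", path))
  }
  schema_from_list(doc$columns)
}

schema_from_list <- function(cols) {
  cols <- as.data.frame(cols)
  schema <- tibble::tibble(name = as.character(cols$name),
                           kind = as.character(cols$kind),
                           monotone = as.integer(cols$monotone),
                           center = as.numeric(cols$center),
                           spread = as.numeric(cols$spread))
  class(schema) <- c("feature_schema", class(schema))
  schema
}

schema_digest <- function(schema) {
  f <- tempfile()
  on.exit(unlink(f))
  # 15 significant digits: stable across text serialization of doubles
  writeLines(paste(schema$name, schema$kind, schema$monotone,
                   sprintf("%.15g", schema$center), sprintf("%.15g", schema$spread),
                   sep = "\t"), f)
  unname(tools::md5sum(f))
}
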