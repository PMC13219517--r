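check_eval_pair <- function(x_exp, x_calc) {
  if (length(x_exp) != length(x_calc)) {
    abort("x_exp and x_calc must have equal length")
  }
  if (length(x_exp) == 0) abort("empty evaluation pair")
  if (any(x_exp <= 0) || any(x_calc <= 0)) {
    abort("mole fractions must be strictly positive for logarithmic metrics")
  }
  invisible(NULL)
}

#' Root mean squared logarithmic error
#'
#' Two conventions are provided. The `"paper"` variant (the default, used in
#' all reports) places N outside the square root,
#' `sqrt(sum((ln x_exp - ln x_calc)^2)) / N`; the `"conventional"` variant is
#' `sqrt(sum((ln x_exp - ln x_calc)^2) / N)`. They differ by exactly a
#' factor `sqrt(N)`.
#'
#' @param x_exp Experimental mole fractions (> 0).
#' @param x_calc Calculated mole fractions (> 0).
#' @param variant `"paper"` or `"conventional"`.
#' @return The RMSLE value.
#' @export
#' @examples
#' rmsle(c(exp(1), exp(2)), c(1, 1))                  # sqrt(5)/2
#' rmsle(c(exp(1), exp(2)), c(1, 1), "conventional")  # sqrt(5/2)
rmsle <- function(x_exp, x_calc, variant = c("paper", "conventional")) {
  variant <- match.arg(variant)
  check_eval_pair(x_exp, x_calc)
  ss <- sum((log(x_exp) - log(x_calc))^2)
  n <- length(x_exp)
  switch(variant, paper = sqrt(ss) / n, conventional = sqrt(ss / n))
}

#' Mean absolute percentage deviation
#'
#' `100 * mean(|x_calc - x_exp| / x_exp)`, on the mole-fraction (linear)
#' scale, directly comparable to the relative scatter of experimental
#' solubility measurements.
#'
#' @inheritParams rmsle
#' @return MAPD in percent.
#' @export
#' @examples
#' mapd(c(0.1, 0.2), c(0.12, 0.15)) # 22.5
mapd <- function(x_exp, x_calc) {
  if (length(x_exp) != length(x_calc)) abort("x_exp and x_calc must have equal length")
  if (any(x_exp <= 0)) abort("x_exp must be strictly positive for MAPD")
  100 * mean(abs(x_calc - x_exp) / x_exp)
}

#' Coefficient of determination on log solubility
#'
#' `1 - SS_res / SS_tot` computed on `ln x`.
#'
#' @param observed Observed `ln x` values.
#' @param predicted Predicted `ln x` values.
#' @return R squared.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("observed and predicted must have equal length")
  }
  if (length(observed) < 2) abort("R squared needs at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) abort("R squared undefined: observed values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Per-system evaluation report
#'
#' Groups predictions by (solute, solvent) system and computes, per system,
#' the RMSLE in both conventions, MAPD, the record count and the temperature
#' range; then per-solute averages (arithmetic mean over that solute's
#' systems) and the grand average (mean over solutes of the solute
#' averages). Row order is deterministic: solute then solvent,
#' lexicographic.
#'
#' @param predictions Tibble with columns `solute`, `solvent`, `T_K`, `x`
#'   (experimental) and `x_pred` (calculated), e.g. a corpus's records joined
#'   with [predict.sb_booster()] output.
#' @return An object of class `sb_report`: list of tibbles `systems`,
#'   `solute_means`, `overall`.
#' @export
per_system_report <- function(predictions) {
  needed <- c("solute", "solvent", "T_K", "x", "x_pred")
  missing <- setdiff(needed, names(predictions))
  if (length(missing) > 0) {
    abort(paste0("predictions table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  systems <- predictions |>
    dplyr::group_by(.data$solute, .data$solvent) |>
    dplyr::summarise(rmsle_paper = rmsle(.data$x, .data$x_pred, "paper"),
                     rmsle_conventional = rmsle(.data$x, .data$x_pred, "conventional"),
                     mapd_pct = mapd(.data$x, .data$x_pred),
                     n = dplyr::n(),
                     T_min = min(.data$T_K), T_max = max(.data$T_K),
                     .groups = "drop") |>
    dplyr::arrange(.data$solute, .data$solvent)
  solute_means <- systems |>
    dplyr::group_by(.data$solute) |>
    dplyr::summarise(rmsle_paper = mean(.data$rmsle_paper),
                     rmsle_conventional = mean(.data$rmsle_conventional),
                     mapd_pct = mean(.data$mapd_pct),
                     n_systems = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$solute)
  overall <- tibble::tibble(
    rmsle_paper = mean(solute_means$rmsle_paper),
    rmsle_conventional = mean(solute_means$rmsle_conventional),
    mapd_pct = mean(solute_means$mapd_pct),
    n_solutes = nrow(solute_means),
    n_systems = nrow(systems),
    n_records = nrow(predictions))
  structure(list(systems = systems, solute_means = solute_means, overall = overall),
            class = "sb_report")
}

#' @export
print.sb_report <- function(x, ...) {
  cat("<sb_report> ", x$overall$n_systems, " system(s), ", x$overall$n_solutes,
      " solute(s); grand average RMSLE ", format(x$overall$rmsle_paper, digits = 4),
      " (paper form), MAPD ", format(x$overall$mapd_pct, digits = 4), "%\n", sep = "")
  print(x$systems, n = 15)
  invisible(x)
}

#' @export
tidy.sb_report <- function(x, ...) x$systems

#' @export
glance.sb_report <- function(x, ...) x$overall

#' Write / read a per-system report as delimited text
#'
#' The file mirrors the report's per-system table (solute, solvent, RMSLE in
#' both conventions, MAPD %, N, T range); solute averages and the grand
#' average are recomputed on read, so the round-trip is the identity.
#'
#' @param report An `sb_report`.
#' @param path File path.
#' @param predictions_path Unused placeholder for future scatter output.
#' @return `read_report` returns an `sb_report`-shaped list rebuilt from the
#'   per-system rows; `write_report` returns `path` invisibly.
#' @export
write_report <- function(report, path, predictions_path = NULL) {
  readr::write_csv(report$systems, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  systems <- readr::read_csv(path, col_types = readr::cols(
    solute = readr::col_character(), solvent = readr::col_character(),
    .default = readr::col_double()), comment = "#", progress = FALSE)
  systems$n <- as.integer(systems$n)
  solute_means <- systems |>
    dplyr::group_by(.data$solute) |>
    dplyr::summarise(rmsle_paper = mean(.data$rmsle_paper),
                     rmsle_conventional = mean(.data$rmsle_conventional),
                     mapd_pct = mean(.data$mapd_pct),
                     n_systems = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$solute)
  overall <- tibble::tibble(
    rmsle_paper = mean(solute_means$rmsle_paper),
    rmsle_conventional = mean(solute_means$rmsle_conventional),
    mapd_pct = mean(solute_means$mapd_pct),
    n_solutes = nrow(solute_means),
    n_systems = nrow(systems),
    n_records = sum(systems$n))
  structure(list(systems = systems, solute_means = solute_means, overall = overall),
            class = "sb_report")
}
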