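#' Heat-capacity-corrected ideal log solubility
#'
#' Closed form of the ideal-solubility integral with the linear
#' heat-capacity difference `dCp(T') = q + r (T' - Tm)` (see [delta_cp()]):
#'
#' `ln x_id = -(dHfus/R) (1/T - 1/Tm)
#'            - (1/R) [ (q - r Tm) ln(Tm/T) + r (Tm - T) ]
#'            + (1/(R T)) [ q (Tm - T) - r (Tm - T)^2 / 2 ]`
#'
#' with `dHfus` in J/mol and `R` the molar gas constant. At the melting point
#' this is 0 (`x_id = 1`); with `q = r = 0` it reduces to the van't Hoff
#' form. Ideal solubility increases monotonically with temperature over the
#' working range of the packaged descriptors.
#'
#' @inheritParams delta_cp
#' @return `ln x_id`, same length as `T_K`.
#' @export
#' @examples
#' ideal_log_solubility("butyl paraben", 298.15)
ideal_log_solubility <- function(solute, T_K) {
  solute <- resolve_solute(solute)
  Tm <- solute$Tm_K
  if (any(T_K <= 0) || any(T_K > Tm)) {
    abort(paste0("temperature must lie in (0, Tm]; Tm = ", Tm, " K"))
  }
  dH <- solute$dHfus_kJ_mol * 1000 # J/mol inside thermodynamic formulas
  q <- solute$q_J_K_mol
  r <- solute$r_J_K2_mol
  dT <- Tm - T_K
  -(dH / .R_GAS) * (1 / T_K - 1 / Tm) -
    (1 / .R_GAS) * ((q - r * Tm) * log(Tm / T_K) + r * dT) +
    (1 / (.R_GAS * T_K)) * (q * dT - r * dT^2 / 2)
}

#' Per-solute activity anchors
#'
#' Each solute is assigned a "preferred" solvent environment: a dielectric
#' anchor and a boiling-point anchor drawn once, uniformly over the solvent
#' table's ranges, from a seeded stream (solutes processed in lexicographic
#' order, so the draw is reproducible and independent of record order).
#'
#' @param solutes Solute descriptor tibble.
#' @param solvents Solvent descriptor tibble.
#' @param seed Integer seed.
#' @return Tibble `name`, `eps_star`, `bp_star` plus the normalizing ranges
#'   `eps_range`, `bp_range` as attributes-free columns (constant).
#' @export
activity_anchors <- function(solutes, solvents, seed = 42L) {
  nm <- sort(solutes$name)
  eps_lim <- range(solvents$dielectric)
  bp_lim <- range(solvents$bp_K)
  withr::with_seed(as.integer(seed), {
    eps_star <- runif(length(nm), eps_lim[1], eps_lim[2])
    bp_star <- runif(length(nm), bp_lim[1], bp_lim[2])
  })
  tibble::tibble(name = nm, eps_star = eps_star, bp_star = bp_star,
                 eps_range = diff(eps_lim), bp_range = diff(bp_lim))
}

#' Activity-coefficient penalty of the synthetic generator
#'
#' A deliberately simple nonnegative log activity coefficient standing in
#' for solution non-ideality: `ln gamma = kappa * m * (Tm / T)` where the
#' descriptor mismatch `m = 0.5 |eps - eps*| / d_eps + 0.5 |bp - bp*| / d_bp`
#' measures how far the solvent's dielectric constant and boiling point sit
#' from the solute's anchors. It is zero for `kappa = 0` or a perfectly
#' matched solvent, and strictly decreasing in temperature otherwise, so the
#' generated `ln x = ln x_id - ln gamma` stays monotone increasing in T and
#' `x <= x_id <= 1` without clamping.
#'
#' @param solute Solute descriptor row (or name).
#' @param solvent Solvent descriptor row (one row of the solvent table).
#' @param T_K Temperature(s), kelvin.
#' @param kappa Activity strength (>= 0), dimensionless.
#' @param anchors Output of [activity_anchors()].
#' @return `ln gamma >= 0`, same length as `T_K`.
#' @export
activity_correction <- function(solute, solvent, T_K, kappa, anchors) {
  stopifnot(kappa >= 0)
  solute <- resolve_solute(solute)
  a <- anchors[anchors$name == normalize_name(solute$name), ]
  if (nrow(a) != 1) abort(paste0("no anchors for solute: ", solute$name))
  m <- 0.5 * abs(solvent$dielectric - a$eps_star) / a$eps_range +
    0.5 * abs(solvent$bp_K - a$bp_star) / a$bp_range
  kappa * m * (solute$Tm_K / T_K)
}

#' Synthetic-corpus generator configuration
#'
#' Defaults emulate the study corpus the model is designed for: the five
#' packaged solutes and nine packaged solvents, the 30 solute-solvent
#' systems of the packaged system list, 8 evenly spaced temperatures per
#' pair in 278-323 K, an activity strength that spreads the generated mole
#' fractions over several orders of magnitude, and relative (log-scale)
#' measurement noise.
#'
#' @param solutes Solute descriptor tibble.
#' @param solvents Solvent descriptor tibble.
#' @param systems Tibble `solute`, `solvent` of pairs to generate; default
#'   the packaged 30-system list restricted to `solutes`/`solvents`.
#' @param n_temperatures Grid points per pair.
#' @param t_min,t_max Temperature grid limits (K); must stay below every
#'   solute melting point.
#' @param kappa Activity strength (>= 0).
#' @param sigma Noise standard deviation on `ln x` (>= 0).
#' @param seed Integer seed controlling anchors and noise.
#' @return A list of class `sb_generator_config`.
#' @export
generator_config <- function(solutes = solute_descriptors(),
                             solvents = solvent_descriptors(),
                             systems = NULL,
                             n_temperatures = 8L, t_min = 278, t_max = 323,
                             kappa = 3, sigma = 0.1, seed = 42L) {
  solutes$name <- normalize_name(solutes$name)
  solvents$name <- normalize_name(solvents$name)
  if (is.null(systems)) {
    systems <- readr::read_csv(system.file("extdata", "default_systems.csv",
                                           package = "solboost", mustWork = TRUE),
                               col_types = "cc", progress = FALSE)
    systems <- systems[systems$solute %in% solutes$name &
                         systems$solvent %in% solvents$name, ]
  } else {
    systems <- tibble::as_tibble(systems)
    systems$solute <- normalize_name(systems$solute)
    systems$solvent <- normalize_name(systems$solvent)
  }
  stopifnot(kappa >= 0, sigma >= 0, is.finite(kappa), is.finite(sigma),
            t_min > 0, t_max >= t_min, n_temperatures >= 1)
  if (t_max >= min(solutes$Tm_K[solutes$name %in% systems$solute])) {
    abort("temperature grid must stay strictly below every solute melting point")
  }
  structure(list(solutes = solutes, solvents = solvents, systems = systems,
                 n_temperatures = as.integer(n_temperatures),
                 t_min = t_min, t_max = t_max, kappa = kappa, sigma = sigma,
                 seed = as.integer(seed)),
            class = "sb_generator_config")
}

#' Generate a synthetic solubility corpus
#'
#' One record per (solute, solvent, temperature) grid point with
#' `ln x = ln x_id(T) - ln gamma(T) + noise`, `noise ~ N(0, sigma^2)`, and
#' `x` clamped into (0, 1] (the clamp is a numerical guard only: the noise-
#' free construction already satisfies `x <= 1`). With `sigma = 0` every
#' pair's solubility is strictly increasing in temperature; the whole corpus
#' is reproducible from the seed.
#'
#' @param config An `sb_generator_config`.
#' @return An `sb_corpus`.
#' @export
#' @examples
#' corp <- generate_corpus(generator_config(seed = 1))
#' corp
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sb_generator_config"))
  anchors <- activity_anchors(config$solutes, config$solvents, config$seed)
  grid_T <- if (config$n_temperatures == 1) {
    (config$t_min + config$t_max) / 2
  } else {
    seq(config$t_min, config$t_max, length.out = config$n_temperatures)
  }
  sys <- dplyr::arrange(config$systems, .data$solute, .data$solvent)
  records <- purrr::pmap_dfr(sys, function(solute, solvent) {
    su <- as.list(config$solutes[config$solutes$name == solute, ])
    sv <- config$solvents[config$solvents$name == solvent, ]
    if (length(su$name) != 1 || nrow(sv) != 1) {
      abort(paste0("system (", solute, ", ", solvent, ") lacks descriptors"))
    }
    ln_x <- ideal_log_solubility(su, grid_T) -
      activity_correction(su, sv, grid_T, config$kappa, anchors)
    tibble::tibble(solute = solute, solvent = solvent, T_K = grid_T, ln_x = ln_x)
  })
  if (config$sigma > 0) {
    noise <- withr::with_seed(round_seed(config$seed, 777L),
                              rnorm(nrow(records), sd = config$sigma))
    records$ln_x <- records$ln_x + noise
  }
  records$x <- pmin(exp(records$ln_x), 1)
  solubility_corpus(records[c("solute", "solvent", "T_K", "x")],
                    config$solutes, config$solvents)
}
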