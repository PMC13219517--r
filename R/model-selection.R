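new_split_plan <- function(train, test, strategy, seed = NA_integer_, held = NULL) {
  structure(list(train = sort(train), test = sort(test), strategy = strategy,
                 seed = seed, held = held),
            class = "sb_split")
}

#' @export
print.sb_split <- function(x, ...) {
  cat("<sb_split> strategy ", x$strategy,
      if (!is.null(x$held)) paste0(" (held: ", x$held, ")"), ": ",
      length(x$train), " train / ", length(x$test), " test rows\n", sep = "")
  invisible(x)
}

#' Stratified random train/test holdout
#'
#' Splits the corpus into training and test rows while keeping a consistent
#' distribution of solvents and temperatures across the two sets: records are
#' stratified by solvent, each stratum is sorted by temperature, and the test
#' rows are taken by systematic sampling (evenly spaced positions with a
#' seeded random start) within the stratum. Each stratum contributes
#' `floor(train_fraction * n)` training rows (at least 1 when the stratum has
#' two or more rows); a singleton stratum goes entirely to training with a
#' warning.
#'
#' @param corpus An `sb_corpus`.
#' @param train_fraction Fraction of rows for training, in (0, 1).
#' @param seed Integer seed.
#' @return An `sb_split` plan with `train` and `test` row indices
#'   partitioning the corpus records.
#' @export
random_holdout <- function(corpus, train_fraction = 0.8, seed = 42L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  rec <- corpus$records
  n <- nrow(rec)
  test <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (sv in sort(unique(rec$solvent))) {
      idx <- which(rec$solvent == sv)
      idx <- idx[order(rec$T_K[idx])]
      ns <- length(idx)
      if (ns == 1) {
        warn(paste0("solvent stratum '", sv, "' has a single record; assigned to training"))
        next
      }
      n_tr <- max(1L, floor(train_fraction * ns))
      n_te <- ns - n_tr
      if (n_te == 0) next
      step <- ns / n_te
      u <- runif(1)
      pos <- floor((seq_len(n_te) - 1 + u) * step) + 1L
      test <- c(test, idx[pos])
    }
  })
  new_split_plan(setdiff(seq_len(n), test), test, "random80", as.integer(seed))
}

#' Leave-one-group-out split
#'
#' Every record of the held group (a solute, a solvent, or a solute-solvent
#' pair) goes to the test set; all remaining records form the training set.
#' When grouping by solute, the training corpus contains no record of the
#' held compound, so a schema fit on it carries no indicator column for that
#' compound — external prediction then flows entirely through the numeric
#' descriptors.
#'
#' @param corpus An `sb_corpus`.
#' @param group_by `"solute"`, `"solvent"`, or `"pair"`.
#' @param held Name of the held group; for `"pair"`, `"solute/solvent"`.
#' @return An `sb_split` plan.
#' @export
leave_one_group_out <- function(corpus, group_by = c("solute", "solvent", "pair"),
                                held) {
  group_by <- match.arg(group_by)
  rec <- corpus$records
  key <- switch(group_by,
                solute = rec$solute,
                solvent = rec$solvent,
                pair = paste(rec$solute, rec$solvent, sep = "/"))
  held_norm <- if (group_by == "pair") {
    paste(normalize_name(strsplit(held, "/", fixed = TRUE)[[1]]), collapse = "/")
  } else {
    normalize_name(held)
  }
  test <- which(key == held_norm)
  if (length(test) == 0) {
    abort(paste0("unknown ", group_by, " group: '", held, "'"))
  }
  new_split_plan(setdiff(seq_len(nrow(rec)), test), test,
                 strategy = switch(group_by, solute = "loso", solvent = "losvo",
                                   pair = "pair-grouped"),
                 held = held_norm)
}

#' Subset a corpus by a split plan
#'
#' @param corpus An `sb_corpus`.
#' @param plan An `sb_split`.
#' @return A list of two `sb_corpus` objects, `train` and `test`.
#' @export
split_corpus <- function(corpus, plan) {
  take <- function(idx) {
    solubility_corpus(corpus$records[idx, ], corpus$solutes, corpus$solvents)
  }
  list(train = take(plan$train), test = take(plan$test))
}

#' k-fold partition of row indices
#'
#' Seeded shuffle followed by assignment into `k` disjoint folds whose sizes
#' differ by at most one.
#'
#' @param n Number of rows.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A list of `k` integer vectors partitioning `1:n`.
#' @export
kfold_indices <- function(n, k = 5L, seed = 42L) {
  stopifnot(k >= 2)
  if (n < k) abort(paste0("cannot make ", k, " folds from ", n, " rows"))
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  purrr::map2(starts, ends, function(a, b) sort(perm[a:b]))
}

#' Grid-search hyperparameter optimization with k-fold cross-validation
#'
#' Evaluates every combination in the Cartesian product of the supplied
#' parameter value lists by k-fold cross-validation of the booster on the
#' design matrix, recording per-fold and mean validation scores. The default
#' scorer is the literal root-mean-squared-logarithmic-error on the
#' validation fold (square root of the summed squared ln-errors divided by
#' N); lower is better. The best combination attains the optimal mean score,
#' ties breaking to the first combination in deterministic grid order.
#'
#' @param design An `sb_design` (training rows only).
#' @param grid Named list of parameter value vectors, e.g.
#'   `list(max_depth = c(3, 4), learning_rate = c(0.05, 0.1))`. Names must be
#'   [boost_params()] arguments.
#' @param k Number of CV folds.
#' @param seed Seed for the fold shuffle (also the booster seed unless the
#'   grid sets one).
#' @param scorer Function `(y, y_pred) -> score`, lower better.
#' @param base_params Baseline `sb_boost_params` the grid overrides.
#' @return An object of class `sb_grid_search`: list with `table` (one row
#'   per combination with fold scores and `mean_score`), `best_index` and
#'   `best_params`.
#' @export
#' @examples
#' corp <- generate_corpus(generator_config(seed = 7))
#' d <- build_design_matrix(corp)
#' gs <- grid_search(d, list(max_depth = c(2, 3)), k = 3,
#'                   base_params = boost_params(n_estimators = 10))
#' gs$table
grid_search <- function(design, grid, k = 5L, seed = 42L, scorer = NULL,
                        base_params = boost_params(seed = seed)) {
  if (length(grid) == 0) abort("grid must be non-empty")
  bad <- setdiff(names(grid), names(boost_params()))
  if (length(bad) > 0) {
    abort(paste0("unknown booster parameter(s) in grid: ", paste(bad, collapse = ", ")))
  }
  if (is.null(scorer)) {
    scorer <- function(y, y_pred) sqrt(sum((y - y_pred)^2)) / length(y)
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  folds <- kfold_indices(nrow(design$X), k, seed)
  n_all <- seq_len(nrow(design$X))
  fold_scores <- matrix(NA_real_, nrow = nrow(combos), ncol = k,
                        dimnames = list(NULL, paste0("fold", seq_len(k))))
  for (ci in seq_len(nrow(combos))) {
    params <- do.call(boost_params, modifyList(unclass(base_params),
                                               as.list(combos[ci, , drop = FALSE])))
    for (fi in seq_len(k)) {
      val <- folds[[fi]]
      tr <- setdiff(n_all, val)
      sub <- structure(list(X = design$X[tr, , drop = FALSE], y = design$y[tr],
                            schema = design$schema, keys = design$keys[tr, ]),
                       class = "sb_design")
      fit <- fit_booster(sub, params)
      pred <- predict(fit, design$X[val, , drop = FALSE])
      fold_scores[ci, fi] <- scorer(design$y[val], pred)
    }
  }
  table <- dplyr::bind_cols(tibble::as_tibble(combos),
                            tibble::as_tibble(fold_scores)) |>
    dplyr::mutate(mean_score = rowMeans(fold_scores))
  best_index <- which.min(table$mean_score)
  best_params <- do.call(boost_params, modifyList(unclass(base_params),
                                                  as.list(combos[best_index, , drop = FALSE])))
  structure(list(table = table, best_index = best_index, best_params = best_params,
                 k = k, seed = as.integer(seed)),
            class = "sb_grid_search")
}

#' @export
print.sb_grid_search <- function(x, ...) {
  cat("<sb_grid_search> ", nrow(x$table), " combination(s), ", x$k, "-fold CV; best mean score ",
      format(x$table$mean_score[x$best_index], digits = 5), " at row ", x$best_index, "\n",
      sep = "")
  print(x$table, n = 10)
  invisible(x)
}

#' @export
tidy.sb_grid_search <- function(x, ...) x$table

#' @export
glance.sb_grid_search <- function(x, ...) {
  dplyr::bind_cols(x$table[x$best_index, ], tibble::tibble(k = x$k, seed = x$seed))
}
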