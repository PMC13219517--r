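#' Booster hyperparameters
#'
#' Constructor for the gradient-boosting hyperparameter set. Defaults are the
#' optimized configuration used throughout the package: 300 trees of depth 4,
#' learning rate 0.05, row and column subsampling at 0.7, squared-error
#' objective, `gamma = 0`, `reg_alpha = 0`, `reg_lambda = 1`,
#' `min_child_weight = 1`, seed 42.
#'
#' @param n_estimators Number of boosting rounds (trees).
#' @param max_depth Maximum tree depth (levels of splits below the root).
#' @param learning_rate Shrinkage factor applied to every tree's output.
#' @param subsample Fraction of rows drawn (without replacement) per tree.
#' @param colsample_bytree Fraction of columns drawn per tree.
#' @param gamma Minimum split gain (complexity penalty per split).
#' @param reg_alpha L1 regularization on leaf weights.
#' @param reg_lambda L2 regularization on leaf weights.
#' @param min_child_weight Minimum hessian sum required in each child.
#' @param seed Integer seed for the deterministic sampling streams.
#' @return A list of class `sb_boost_params`.
#' @export
boost_params <- function(n_estimators = 300L, max_depth = 4L, learning_rate = 0.05,
                         subsample = 0.7, colsample_bytree = 0.7, gamma = 0,
                         reg_alpha = 0, reg_lambda = 1, min_child_weight = 1,
                         seed = 42L) {
  p <- list(n_estimators = as.integer(n_estimators), max_depth = as.integer(max_depth),
            learning_rate = learning_rate, subsample = subsample,
            colsample_bytree = colsample_bytree, gamma = gamma,
            reg_alpha = reg_alpha, reg_lambda = reg_lambda,
            min_child_weight = min_child_weight, seed = as.integer(seed))
  stopifnot(p$n_estimators >= 1L, p$max_depth >= 1L,
            p$learning_rate > 0, p$learning_rate <= 1,
            p$subsample > 0, p$subsample <= 1,
            p$colsample_bytree > 0, p$colsample_bytree <= 1,
            p$gamma >= 0, p$reg_alpha >= 0, p$reg_lambda >= 0,
            p$min_child_weight >= 0)
  structure(p, class = "sb_boost_params")
}

soft_threshold <- function(G, alpha) {
  ifelse(G > alpha, G - alpha, ifelse(G < -alpha, G + alpha, 0))
}

#' Regularized leaf weight
#'
#' The second-order Newton step for a leaf: `w = -softthreshold(G, alpha) /
#' (H + lambda)`, clipped into the `[lower, upper]` interval carried down by
#' the monotone-constraint bound propagation.
#'
#' @param G Gradient sum over the leaf's rows.
#' @param H Hessian sum over the leaf's rows.
#' @param alpha,lambda L1 and L2 regularization.
#' @param lower,upper Weight bounds.
#' @return The leaf weight (vectorized over `G`/`H`).
#' @export
leaf_weight <- function(G, H, alpha = 0, lambda = 1, lower = -Inf, upper = Inf) {
  w <- -soft_threshold(G, alpha) / (H + lambda)
  pmin(pmax(w, lower), upper)
}

#' Split gain
#'
#' Gain of splitting a node with children statistics `(GL, HL)` and
#' `(GR, HR)`:
#' `0.5 * (GL^2/(HL+lambda) + GR^2/(HR+lambda) - (GL+GR)^2/(HL+HR+lambda)) - gamma`.
#'
#' @param GL,HL Left-child gradient and hessian sums.
#' @param GR,HR Right-child gradient and hessian sums.
#' @param lambda L2 regularization.
#' @param gamma Complexity penalty subtracted from the gain.
#' @return The gain (vectorized).
#' @export
split_gain <- function(GL, HL, GR, HR, lambda = 1, gamma = 0) {
  0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
           (GL + GR)^2 / (HL + HR + lambda)) - gamma
}

#' Exact greedy split search with monotone feasibility
#'
#' Scans every available column, sorting the node's rows by value and
#' evaluating every boundary between distinct values (threshold at the
#' midpoint). A candidate is discarded when a child's hessian sum falls below
#' `min_child_weight`, when its gain is not positive, or — for a column
#' flagged `+1` — when the candidate left-child weight exceeds the
#' right-child weight (weights computed with the node's current bounds).
#' Ties in gain break to the lowest column index, then the lowest threshold.
#'
#' @param X Feature matrix.
#' @param rows Row indices of the node.
#' @param cols Candidate column indices.
#' @param g,h Gradient and hessian vectors (full length).
#' @param params `sb_boost_params`.
#' @param monotone Integer vector of per-column monotone flags (0 or +1).
#' @param lower,upper Current weight bounds of the node.
#' @return `NULL` when no valid split exists, else a list with `col`,
#'   `threshold`, `gain`, and the candidate child weights `wL`, `wR`.
#' @export
find_best_split <- function(X, rows, cols, g, h, params, monotone,
                            lower = -Inf, upper = Inf) {
  if (length(rows) < 2) return(NULL)
  gr <- g[rows]
  hr <- h[rows]
  G <- sum(gr)
  H <- sum(hr)
  lam <- params$reg_lambda
  best <- NULL
  for (j in sort(cols)) {
    v <- X[rows, j]
    ord <- order(v)
    vs <- v[ord]
    cg <- cumsum(gr[ord])
    ch <- cumsum(hr[ord])
    nb <- which(vs[-length(vs)] < vs[-1])
    if (length(nb) == 0) next
    GL <- cg[nb]; HL <- ch[nb]
    GR <- G - GL; HR <- H - HL
    ok <- HL >= params$min_child_weight & HR >= params$min_child_weight
    if (!any(ok)) next
    wL <- leaf_weight(GL, HL, params$reg_alpha, lam, lower, upper)
    wR <- leaf_weight(GR, HR, params$reg_alpha, lam, lower, upper)
    if (is.finite(lower) || is.finite(upper)) {
      # bounds may clip candidate weights; gain follows the clipped weights
      # (identical to split_gain() when the bounds are infinite)
      negloss <- function(G, H, w) -(2 * G * w + (H + lam) * w^2)
      wP <- leaf_weight(G, H, params$reg_alpha, lam, lower, upper)
      gains <- 0.5 * (negloss(GL, HL, wL) + negloss(GR, HR, wR) -
                        negloss(G, H, wP)) - params$gamma
    } else {
      gains <- split_gain(GL, HL, GR, HR, lam, params$gamma)
    }
    if (monotone[j] > 0) ok <- ok & (wL <= wR)
    ok <- ok & (gains > 0)
    if (!any(ok)) next
    # ties (within fp noise) break to the lowest threshold, then lowest column
    idx <- which(ok)
    i <- idx[which(gains[idx] > max(gains[idx]) - 1e-12)[1]]
    if (is.null(best) || gains[i] > best$gain + 1e-12) {
      best <- list(col = j, threshold = (vs[nb[i]] + vs[nb[i] + 1]) / 2,
                   gain = gains[i], wL = wL[i], wR = wR[i])
    }
  }
  best
}

#' Grow a single regression tree
#'
#' Recursive exact greedy construction to `max_depth`. When a split is made
#' on a `+1`-flagged column, the parent's weight interval is divided at
#' `mid = (wL + wR) / 2`: the left child's upper bound becomes `mid` and the
#' right child's lower bound becomes `mid`, which guarantees the monotone
#' property globally (every left-descendant leaf weight stays below every
#' right-descendant leaf weight), not just per split. Leaves take
#' [leaf_weight()] under their inherited bounds.
#'
#' @inheritParams find_best_split
#' @return A tree: nested list of `list(split, threshold, left, right)` nodes
#'   and `list(leaf)` terminals.
#' @export
grow_tree <- function(X, rows, cols, g, h, params, monotone) {
  stopifnot(length(rows) >= 1)
  build <- function(rows, depth, lower, upper) {
    s <- if (depth < params$max_depth) {
      find_best_split(X, rows, cols, g, h, params, monotone, lower, upper)
    }
    if (is.null(s)) {
      return(list(leaf = leaf_weight(sum(g[rows]), sum(h[rows]),
                                     params$reg_alpha, params$reg_lambda,
                                     lower, upper)))
    }
    go_left <- X[rows, s$col] < s$threshold
    if (monotone[s$col] > 0) {
      mid <- (s$wL + s$wR) / 2
      left <- build(rows[go_left], depth + 1L, lower, min(upper, mid))
      right <- build(rows[!go_left], depth + 1L, max(lower, mid), upper)
    } else {
      left <- build(rows[go_left], depth + 1L, lower, upper)
      right <- build(rows[!go_left], depth + 1L, lower, upper)
    }
    list(split = s$col, threshold = s$threshold, left = left, right = right)
  }
  build(rows, 0L, -Inf, Inf)
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (length(idx) == 0) return(invisible())
    if (!is.null(node$leaf)) {
      out[idx] <<- node$leaf
      return(invisible())
    }
    go <- X[idx, node$split] < node$threshold
    rec(node$left, idx[go])
    rec(node$right, idx[!go])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

round_seed <- function(seed, m) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(m)) %% 2147483629)
}

#' Fit the monotone gradient-boosted ensemble
#'
#' Second-order gradient boosting under the squared-error objective: the base
#' score is the training-target mean; each round fits a tree to the gradients
#' `g = yhat - y` with unit hessians on a per-round row/column subsample
#' (without replacement, drawn from a deterministic stream derived from
#' `(seed, round)`), then updates all predictions by `learning_rate` times
#' the tree output. The schema's monotone flags are enforced during tree
#' construction, so model predictions are globally nondecreasing in the
#' temperature feature.
#'
#' @param design An `sb_design` from [build_design_matrix()].
#' @param params An `sb_boost_params` (default [boost_params()]).
#' @return An object of class `sb_booster`.
#' @export
#' @examples
#' corp <- generate_corpus(generator_config(seed = 1))
#' d <- build_design_matrix(corp)
#' fit <- fit_booster(d, boost_params(n_estimators = 20))
#' glance(fit)
fit_booster <- function(design, params = boost_params()) {
  X <- design$X
  y <- design$y
  n <- nrow(X)
  p <- ncol(X)
  if (n == 0) abort("cannot fit on an empty design matrix")
  monotone <- design$schema$monotone
  base <- mean(y)
  pred <- rep(base, n)
  n_rows <- max(1L, floor(params$subsample * n))
  n_cols <- min(p, ceiling(params$colsample_bytree * p))
  trees <- vector("list", params$n_estimators)
  for (m in seq_len(params$n_estimators)) {
    g <- pred - y
    h <- rep(1, n)
    if (n_rows < n || n_cols < p) {
      withr::with_seed(round_seed(params$seed, m), {
        rows <- if (n_rows < n) sort(sample.int(n, n_rows)) else seq_len(n)
        cols <- if (n_cols < p) sort(sample.int(p, n_cols)) else seq_len(p)
      })
    } else {
      rows <- seq_len(n)
      cols <- seq_len(p)
    }
    tree <- grow_tree(X, rows, cols, g, h, params, monotone)
    pred <- pred + params$learning_rate * predict_tree(tree, X)
    trees[[m]] <- tree
  }
  structure(list(base_score = base, trees = trees, params = params,
                 schema = design$schema, train_rmse = sqrt(mean((pred - y)^2))),
            class = "sb_booster")
}

#' @export
print.sb_booster <- function(x, ...) {
  cat("<sb_booster> ", length(x$trees), " trees, depth <= ", x$params$max_depth,
      ", learning rate ", x$params$learning_rate,
      ", base score ", format(x$base_score, digits = 5),
      ", train RMSE (ln x) ", format(x$train_rmse, digits = 4), "\n", sep = "")
  invisible(x)
}

check_matrix_schema <- function(X, schema) {
  nm <- colnames(X)
  if (is.null(nm) || length(nm) != nrow(schema) || any(nm != schema$name)) {
    off <- if (is.null(nm)) {
      "unnamed columns"
    } else if (length(nm) != nrow(schema)) {
      paste0(length(nm), " columns supplied, ", nrow(schema), " expected")
    } else {
      paste0("column '", nm[which(nm != schema$name)[1]], "' where '",
             schema$name[which(nm != schema$name)[1]], "' was expected")
    }
    abort(paste0("feature matrix does not conform to the model schema: ", off))
  }
  invisible(X)
}

#' Predict log solubility with a fitted booster
#'
#' Prediction is `base_score + learning_rate * sum_m tree_m(row)` and is
#' deterministic. For a corpus the design matrix is rebuilt under the model's
#' stored schema, so solutes or solvents unseen in training encode as
#' all-zero indicator blocks and are predicted through their numeric
#' descriptors.
#'
#' @param object An `sb_booster`.
#' @param newdata An `sb_corpus`, an `sb_design` built with this model's
#'   schema, or a numeric matrix whose columns match the schema.
#' @param ... Unused.
#' @return For a corpus, a tibble `solute, solvent, T_K, ln_x_pred, x_pred`;
#'   otherwise a numeric vector of predicted `ln x`.
#' @export
predict.sb_booster <- function(object, newdata, ...) {
  if (inherits(newdata, "sb_corpus")) {
    d <- build_design_matrix(newdata, schema = object$schema)
    ln_pred <- predict(object, d)
    return(dplyr::mutate(d$keys, ln_x_pred = ln_pred, x_pred = exp(ln_pred)))
  }
  X <- if (inherits(newdata, "sb_design")) newdata$X else as.matrix(newdata)
  check_matrix_schema(X, object$schema)
  pred <- rep(object$base_score, nrow(X))
  for (tree in object$trees) {
    pred <- pred + object$params$learning_rate * predict_tree(tree, X)
  }
  pred
}

#' @export
tidy.sb_booster <- function(x, ...) {
  stats_of <- function(node, depth = 0L) {
    if (!is.null(node$leaf)) {
      return(list(n_leaves = 1L, depth = depth, abs_weight = abs(node$leaf)))
    }
    l <- stats_of(node$left, depth + 1L)
    r <- stats_of(node$right, depth + 1L)
    list(n_leaves = l$n_leaves + r$n_leaves, depth = max(l$depth, r$depth),
         abs_weight = l$abs_weight + r$abs_weight)
  }
  purrr::imap_dfr(x$trees, function(tr, i) {
    s <- stats_of(tr)
    tibble::tibble(tree = i, n_leaves = s$n_leaves, depth = s$depth,
                   abs_leaf_weight = s$abs_weight)
  })
}

#' @export
glance.sb_booster <- function(x, ...) {
  tibble::tibble(n_trees = length(x$trees), max_depth = x$params$max_depth,
                 learning_rate = x$params$learning_rate,
                 base_score = x$base_score, train_rmse_ln = x$train_rmse)
}

tree_to_list <- function(node) {
  if (!is.null(node$leaf)) return(list(leaf = node$leaf))
  list(split = node$split, threshold = node$threshold,
       left = tree_to_list(node$left), right = tree_to_list(node$right))
}

tree_from_list <- function(node) {
  if (!is.null(node$leaf)) return(list(leaf = as.numeric(node$leaf)))
  list(split = as.integer(node$split), threshold = as.numeric(node$threshold),
       left = tree_from_list(node$left), right = tree_from_list(node$right))
}

#' Persist and restore a fitted booster
#'
#' The model file is a versioned, self-describing JSON document embedding the
#' hyperparameters, the feature schema with its scaler statistics and digest,
#' the base score and every tree. Loading verifies the embedded schema digest
#' and fails loudly on mismatch.
#'
#' @param model An `sb_booster`.
#' @param path File path.
#' @return `read_model` returns the `sb_booster`; `write_model` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(format = "solboost/model", version = 1L,
              base_score = model$base_score,
              params = unclass(model$params),
              schema = as.data.frame(model$schema),
              schema_digest = schema_digest(model$schema),
              train_rmse = model$train_rmse,
              trees = purrr::map(model$trees, tree_to_list))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "solboost/model")) {
    abort(paste0("not a solboost model file: ", path))
  }
  schema <- schema_from_list(purrr::map_dfr(doc$schema, tibble::as_tibble))
  if (!identical(schema_digest(schema), doc$schema_digest)) {
    abort("model file schema digest mismatch: file corrupted or edited")
  }
  params <- do.call(boost_params, doc$params)
  structure(list(base_score = as.numeric(doc$base_score),
                 trees = purrr::map(doc$trees, tree_from_list),
                 params = params, schema = schema,
                 train_rmse = as.numeric(doc$train_rmse)),
            class = "sb_booster")
}
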