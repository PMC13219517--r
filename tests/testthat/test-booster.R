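toy_column <- function(values = c(1, 2, 3, 4)) {
  matrix(values, ncol = 1, dimnames = list(NULL, "T_K"))
}

test_that("leaf weight is the clipped soft-thresholded Newton step", {
  expect_equal(leaf_weight(2, 3, alpha = 0, lambda = 1), -0.5)
  expect_equal(leaf_weight(0, 3), 0)
  expect_equal(leaf_weight(2, 3, alpha = 5, lambda = 1), 0)
  expect_equal(leaf_weight(2, 3, alpha = 0, lambda = 1, lower = -0.2), -0.2)
  expect_equal(leaf_weight(-2, 3, alpha = 1, lambda = 1), 0.25)
})

test_that("split gain matches the regularized second-order formula", {
  expect_equal(split_gain(-2, 1, 2, 1, lambda = 0, gamma = 0), 4)
  expect_equal(split_gain(-2, 1, 2, 1, lambda = 0, gamma = 4), 0)
  expect_equal(split_gain(1, 1, 1, 1, lambda = 0, gamma = 0), 0)
})

test_that("exact greedy split scan finds the textbook optimum", {
  X <- toy_column()
  g <- c(-1, -1, 1, 1)
  h <- rep(1, 4)
  p <- boost_params(reg_lambda = 0)
  s <- find_best_split(X, 1:4, 1, g, h, p, monotone = 0L)
  expect_equal(s$col, 1)
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gain, 2)
})

test_that("a +1 flag rejects order-violating splits and infeasible child weights", {
  X <- toy_column()
  p <- boost_params(reg_lambda = 0)
  # decreasing response (gradients g = yhat - y rise along the column): every
  # candidate gives child weights (1, -1), left > right, so no valid split
  s <- find_best_split(X, 1:4, 1, c(-1, -1, 1, 1), rep(1, 4), p, monotone = 1L)
  expect_null(s)
  # the same gradients are splittable without the constraint
  expect_false(is.null(find_best_split(X, 1:4, 1, c(-1, -1, 1, 1), rep(1, 4), p,
                                       monotone = 0L)))
  # an increasing response passes the constraint untouched
  s_up <- find_best_split(X, 1:4, 1, c(1, 1, -1, -1), rep(1, 4), p, monotone = 1L)
  expect_equal(s_up$threshold, 2.5)
  # min_child_weight = 3 is infeasible on 4 unit-hessian rows
  p3 <- boost_params(reg_lambda = 0, min_child_weight = 3)
  expect_null(find_best_split(X, 1:4, 1, c(-1, -1, 1, 1), rep(1, 4), p3,
                              monotone = 0L))
})

test_that("split search agrees with exhaustive enumeration on random instances", {
  withr::local_seed(99)
  p <- boost_params(reg_lambda = 1, min_child_weight = 1)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    ncol_ <- sample(1:4, 1)
    X <- matrix(sample(1:6, n * ncol_, replace = TRUE), nrow = n,
                dimnames = list(NULL, paste0("c", seq_len(ncol_))))
    g <- round(rnorm(n), 2)
    h <- rep(1, n)
    mine <- find_best_split(X, 1:n, seq_len(ncol_), g, h, p,
                            monotone = rep(0L, ncol_))
    oracle <- oracle_best_split(X, 1:n, seq_len(ncol_), g, h, p)
    if (is.null(oracle)) {
      expect_null(mine)
    } else {
      expect_equal(mine$gain, oracle$gain, tolerance = 1e-10)
      expect_equal(mine$col, oracle$col)
      expect_equal(mine$threshold, oracle$threshold)
    }
  }
})

test_that("grow_tree produces the stump oracle and single leaves", {
  X <- toy_column()
  p1 <- boost_params(max_depth = 1, learning_rate = 1, reg_lambda = 0)
  # residuals y - 0 with y = (1,1,-1,-1); gradients g = pred - y = -y
  tree <- grow_tree(X, 1:4, 1, g = c(-1, -1, 1, 1), h = rep(1, 4),
                    params = p1, monotone = 0L)
  expect_equal(tree$threshold, 2.5)
  expect_equal(tree$left$leaf, 1)
  expect_equal(tree$right$leaf, -1)
  # constant gradients admit no gain anywhere: single leaf -G/(H+lambda)
  leafy <- grow_tree(X, 1:4, 1, g = rep(2, 4), h = rep(1, 4),
                     params = boost_params(), monotone = 0L)
  expect_null(leafy$split)
  expect_equal(leafy$leaf, -8 / 5)
})

test_that("depth-1 lr-1 single-round fit reproduces per-leaf target means", {
  X <- toy_column()
  y <- c(3, 3, 7, 7)
  d <- structure(list(X = X, y = y,
                      schema = tibble::tibble(name = "T_K", kind = "continuous",
                                              monotone = 0L, center = 0, spread = 1),
                      keys = tibble::tibble(i = 1:4)),
                 class = "sb_design")
  fit <- fit_booster(d, boost_params(n_estimators = 1, max_depth = 1,
                                     learning_rate = 1, subsample = 1,
                                     colsample_bytree = 1, reg_lambda = 0))
  expect_equal(predict(fit, X), y)
  # constant target: zero residuals, every prediction equals the constant
  dc <- d; dc$y <- rep(4, 4)
  fitc <- fit_booster(dc, boost_params(n_estimators = 5, subsample = 1,
                                       colsample_bytree = 1))
  expect_equal(predict(fitc, X), rep(4, 4))
  expect_true(all(purrr::map_lgl(fitc$trees, ~ is.null(.x$split) && .x$leaf == 0)))
})

test_that("fits are deterministic and training loss is nonincreasing without sampling", {
  corp <- generate_corpus(small_config())
  d <- build_design_matrix(corp)
  p <- boost_params(n_estimators = 40)
  f1 <- fit_booster(d, p)
  f2 <- fit_booster(d, p)
  expect_identical(f1$trees, f2$trees)
  expect_identical(predict(f1, d$X), predict(f2, d$X))

  pns <- boost_params(n_estimators = 60, subsample = 1, colsample_bytree = 1)
  fit <- fit_booster(d, pns)
  pred <- rep(fit$base_score, nrow(d$X))
  losses <- numeric(length(fit$trees))
  for (m in seq_along(fit$trees)) {
    pred <- pred + pns$learning_rate * solboost:::predict_tree(fit$trees[[m]], d$X)
    losses[m] <- mean((pred - d$y)^2)
  }
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("predictions are nondecreasing along a temperature grid", {
  corp <- generate_corpus(small_config(seed = 3))
  d <- build_design_matrix(corp)
  fit <- fit_booster(d, boost_params(n_estimators = 60))
  jT <- which(d$schema$name == "T_K")
  jD <- which(d$schema$name == "dCp_J_K_mol")
  for (i in c(1, 50, 120)) {
    row <- d$X[i, , drop = FALSE]
    grid <- row[rep(1, 60), , drop = FALSE]
    grid[, jT] <- seq(min(d$X[, jT]) - 1, max(d$X[, jT]) + 1, length.out = 60)
    preds <- predict(fit, grid)
    expect_true(all(diff(preds) >= -1e-12))
  }
  # zero-tree model predicts the base score everywhere
  fit0 <- fit
  fit0$trees <- list()
  expect_equal(predict(fit0, d$X), rep(fit$base_score, nrow(d$X)))
})

test_that("monotone bound propagation holds on randomized trees", {
  withr::local_seed(7)
  p <- boost_params(max_depth = 4, reg_lambda = 1)
  for (rep_i in 1:30) {
    n <- sample(10:30, 1)
    X <- cbind(T_K = runif(n), f2 = runif(n), f3 = runif(n))
    g <- rnorm(n)
    tree <- grow_tree(X, 1:n, 1:3, g, rep(1, n), p, monotone = c(1L, 0L, 0L))
    base <- X[sample.int(n, 1), , drop = FALSE]
    grid <- base[rep(1, 25), , drop = FALSE]
    grid[, 1] <- seq(-0.5, 1.5, length.out = 25)
    out <- solboost:::predict_tree(tree, grid)
    expect_true(all(diff(out) >= -1e-12))
  }
})

test_that("schema mismatch at prediction time names the offending column", {
  corp <- toy_corpus()
  d <- build_design_matrix(corp)
  fit <- fit_booster(d, boost_params(n_estimators = 3))
  Xbad <- d$X
  colnames(Xbad)[2] <- "mystery"
  expect_error(predict(fit, Xbad), "mystery")
  expect_error(predict(fit, d$X[, -1]), "columns")
})

test_that("model serialization round-trips and detects corruption", {
  corp <- toy_corpus()
  d <- build_design_matrix(corp)
  fit <- fit_booster(d, boost_params(n_estimators = 5))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  expect_equal(back$trees, fit$trees)
  expect_equal(back$base_score, fit$base_score)
  expect_equal(predict(back, d$X), predict(fit, d$X))
  expect_equal(unclass(back$params), unclass(fit$params))

  txt <- readLines(f)
  writeLines(sub("\"T_K\"", "\"T_k\"", txt, fixed = TRUE), f)
  expect_error(read_model(f), "digest")
})

test_that("tidy and glance expose ensemble structure", {
  corp <- toy_corpus()
  d <- build_design_matrix(corp)
  fit <- fit_booster(d, boost_params(n_estimators = 4, max_depth = 2))
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_true(all(td$depth <= 2))
  gl <- glance(fit)
  expect_equal(gl$n_trees, 4)
  expect_true(gl$train_rmse_ln >= 0)
})
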