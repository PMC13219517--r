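# shared in-code fixtures; everything is built at test time

toy_records <- function() {
  tibble::tibble(
    solute = rep(c("butyl paraben", "risperidone"), each = 3),
    solvent = rep(c("methanol", "ethanol"), each = 3),
    T_K = rep(c(283, 293, 303), 2),
    x = c(0.10, 0.15, 0.22, 0.001, 0.002, 0.004))
}

toy_corpus <- function() solubility_corpus(toy_records())

# unconstrained exhaustive split oracle: enumerate every (column, boundary)
# candidate and apply the same feasibility rules as the implementation
oracle_best_split <- function(X, rows, cols, g, h, params) {
  best <- NULL
  for (j in sort(cols)) {
    vals <- sort(unique(X[rows, j]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      left <- rows[X[rows, j] < thr]
      right <- rows[X[rows, j] >= thr]
      GL <- sum(g[left]); HL <- sum(h[left])
      GR <- sum(g[right]); HR <- sum(h[right])
      if (HL < params$min_child_weight || HR < params$min_child_weight) next
      gain <- split_gain(GL, HL, GR, HR, params$reg_lambda, params$gamma)
      if (gain <= 0) next
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(col = j, threshold = thr, gain = gain)
      }
    }
  }
  best
}

# small noise-free generator configuration used across booster tests
small_config <- function(seed = 1, ...) {
  generator_config(seed = seed, sigma = 0, ...)
}

expect_partition <- function(plan, n) {
  expect_length(intersect(plan$train, plan$test), 0)
  expect_setequal(c(plan$train, plan$test), seq_len(n))
}
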