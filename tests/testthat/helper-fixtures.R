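# Small fixtures shared across test files; everything is generated in code.

# quick spec for cheap runs
tiny_spec <- function(...) {
  args <- list(grid_shape = c(6, 6, 6), n_areas = 27, n_per_class = 10,
               active_areas = 1:3, effect_size = 2, noise_sd = 1,
               smooth_sigma = 0, jitter_max = 0, outlier_rate = 0, seed = 1)
  args[names(list(...))] <- list(...)
  do.call(synth_spec, args)
}

# random logistic instance with group structure
random_instance <- function(n = 20, d = 6, G = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  w_true <- rnorm(d)
  y <- ifelse(X %*% w_true + rnorm(n) > 0, 1L, -1L)
  if (all(y == y[1])) y[1] <- -y[1]
  m <- sort(rep_len(seq_len(G), d))
  list(X = X, y = y, m = m)
}

# full sparse-group objective recomputed naively (independent of package code)
naive_objective <- function(w, X, y, m, ls, lg) {
  p <- 1 / (1 + exp(-y * as.vector(X %*% w)))
  f <- -mean(log(p))
  gn <- vapply(unique(m), function(g) sqrt(sum(w[m == g]^2)), numeric(1))
  f + ls * sum(abs(w)) + lg * sum(gn)
}
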