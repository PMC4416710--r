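test_that("logistic probabilities follow the model exactly", {
  expect_equal(unname(predict_proba(c(1, 2, 3), c(0, 0, 0))[, "p_pos"]), 0.5)
  # x'w = ln 3 -> P(+1) = 0.75
  expect_equal(unname(predict_proba(c(log(3), 0), c(1, 5))[, "p_pos"]), 0.75)
  set.seed(2)
  x <- rnorm(7); w <- rnorm(7)
  p <- predict_proba(x, w)
  expect_equal(unname(p[, "p_pos"]), 1 / (1 + exp(-sum(x * w))))
  expect_equal(unname(p[, "p_pos"] + p[, "p_neg"]), 1)
  expect_equal(log(p[, "p_pos"] / p[, "p_neg"]), sum(x * w),
               ignore_attr = TRUE)
  expect_error(predict_proba(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("negative mean log likelihood has its closed-form anchors", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4); y <- rep(c(-1, 1), 5)
  expect_identical(neg_mean_loglik(rep(0, 4), X, y), log(2))
  # separable data: f decreases to 0 as the margin is scaled up
  ysep <- ifelse(X[, 1] > 0, 1, -1)
  wsep <- c(1, 0, 0, 0)
  f1 <- neg_mean_loglik(wsep, X, ysep)
  f10 <- neg_mean_loglik(10 * wsep, X, ysep)
  f100 <- neg_mean_loglik(100 * wsep, X, ysep)
  expect_true(f1 > f10 && f10 > f100)
  expect_lt(f100, 0.02)
  # term-by-term summation oracle
  w <- rnorm(4)
  oracle <- -mean(log(1 / (1 + exp(-y * as.vector(X %*% w)))))
  expect_equal(neg_mean_loglik(w, X, y), oracle, tolerance = 1e-12)
  expect_error(neg_mean_loglik(w, X[0, , drop = FALSE], integer(0)), "empty")
})

test_that("objective decomposes into loss, L1 and group terms", {
  set.seed(4)
  X <- matrix(rnorm(20), 10, 2); y <- rep(c(-1, 1), 5)
  w <- c(1, -2)
  f <- neg_mean_loglik(w, X, y)
  expect_equal(as.numeric(sgl_objective(w, X, y, c(1, 2), penalty_config(1, 0))),
               f + 3)
  w2 <- c(3, 4)
  expect_equal(as.numeric(sgl_objective(w2, X, y, c(1, 1), penalty_config(0, 1))),
               neg_mean_loglik(w2, X, y) + 5)
  # random case vs naive recomputation
  inst <- random_instance(15, 8, 3, seed = 11)
  wr <- rnorm(8)
  expect_equal(as.numeric(sgl_objective(wr, inst$X, inst$y, inst$m,
                                        penalty_config(0.3, 0.7))),
               naive_objective(wr, inst$X, inst$y, inst$m, 0.3, 0.7),
               tolerance = 1e-12)
})

test_that("prox operator solves its defining minimization", {
  m1 <- c(1, 1)
  expect_equal(prox_sgl(c(3, -4), 1, penalty_config(0, 0), m1), c(3, -4))
  expect_equal(prox_sgl(c(3, 4), 1, penalty_config(0, 1), m1), c(2.4, 3.2))
  # numerical-minimization oracle on random 10-dim, 3-group instances
  pobj <- function(z, v, t, ls, lg, m, eps = 1e-16) {
    sum((z - v)^2) / (2 * t) + ls * sum(sqrt(z^2 + eps)) +
      lg * sum(sqrt(rowsum(z^2, m)[, 1] + eps))
  }
  for (s in 1:20) {
    set.seed(s)
    v <- rnorm(10) * 2
    t <- runif(1, 0.2, 2); ls <- runif(1, 0, 0.8); lg <- runif(1, 0, 1.2)
    m <- sort(rep_len(1:3, 10))
    z <- prox_sgl(v, t, penalty_config(ls, lg), m)
    best <- Inf
    for (start in list(v, 0 * v, z + rnorm(10) * 0.05)) {
      o <- optim(start, pobj, v = v, t = t, ls = ls, lg = lg, m = m,
                 method = "BFGS", control = list(maxit = 3000, reltol = 1e-15))
      best <- min(best, o$value)
    }
    expect_lte(pobj(z, v, t, ls, lg, m), best + 1e-6)
  }
})

test_that("penalty thresholds force the exact zero solution", {
  inst <- random_instance(30, 8, 2, seed = 21)
  g0 <- -as.vector(crossprod(inst$X, inst$y)) / (2 * nrow(inst$X))
  lam_s0 <- max(abs(g0))
  fit_s <- sgl_fit(inst$X, inst$y, inst$m, penalty_config(lam_s0 * 1.0001, 0))
  expect_identical(fit_s$weights, rep(0, 8))
  expect_length(fit_s$support, 0)
  lam_g0 <- max(sqrt(rowsum(g0^2, inst$m)[, 1]))
  fit_g <- sgl_fit(inst$X, inst$y, inst$m, penalty_config(0, lam_g0 * 1.0001))
  expect_identical(fit_g$weights, rep(0, 8))
  # just below the threshold the solution is nonzero
  fit_b <- sgl_fit(inst$X, inst$y, inst$m, penalty_config(lam_s0 * 0.9, 0))
  expect_gt(length(fit_b$support), 0)
})

test_that("L1 special case agrees with glmnet to high precision", {
  skip_if_not_installed("glmnet")
  for (s in 1:5) {
    inst <- random_instance(40, 10, 2, seed = s)
    lam <- 0.02 + 0.03 * s / 5
    fit <- sgl_fit(inst$X, inst$y, inst$m, penalty_config(lam, 0),
                   tol = 1e-12, max_iter = 50000)
    g <- glmnet::glmnet(inst$X, factor(inst$y), family = "binomial",
                        lambda = lam, standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
    wg <- as.vector(stats::coef(g))[-1]
    obj <- function(w) naive_objective(w, inst$X, inst$y, inst$m, lam, 0)
    expect_lt(abs(obj(fit$weights) - obj(wg)), 1e-6 * max(1, obj(wg)))
  }
})

test_that("fits satisfy KKT optimality and match a generic solver", {
  smoothed <- function(w, X, y, ls, lg, m, eps = 1e-14) {
    p <- 1 / (1 + exp(-y * as.vector(X %*% w)))
    -mean(log(p)) + ls * sum(sqrt(w^2 + eps)) +
      lg * sum(sqrt(rowsum(w^2, m)[, 1] + eps))
  }
  for (s in 1:10) {
    inst <- random_instance(25, 6, 2, seed = 100 + s)
    g0 <- -as.vector(crossprod(inst$X, inst$y)) / (2 * nrow(inst$X))
    # penalties drawn below the zero thresholds so solutions are nonzero
    ls <- runif(1, 0.1, 0.5) * max(abs(g0))
    lg <- runif(1, 0.1, 0.5) * max(sqrt(rowsum(g0^2, inst$m)[, 1]))
    fit <- sgl_fit(inst$X, inst$y, inst$m, penalty_config(ls, lg),
                   tol = 1e-12, max_iter = 50000)
    expect_lt(sgl_kkt_violation(fit, inst$X, inst$y, inst$m), 1e-5)
    best <- Inf
    for (r in 1:3) {
      set.seed(r)
      o <- optim(rnorm(6) * 0.3, smoothed, X = inst$X, y = inst$y, ls = ls,
                 lg = lg, m = inst$m, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
      best <- min(best, o$value)
    }
    ours <- naive_objective(fit$weights, inst$X, inst$y, inst$m, ls, lg)
    expect_lte(ours, best + 1e-6 * max(1, best))
  }
})

test_that("group penalty with singleton groups equals the L1 penalty", {
  inst <- random_instance(30, 6, 2, seed = 31)
  singletons <- seq_len(6)
  lam <- 0.05
  f_l1 <- sgl_fit(inst$X, inst$y, singletons, penalty_config(lam, 0),
                  tol = 1e-12, max_iter = 50000)
  f_gr <- sgl_fit(inst$X, inst$y, singletons, penalty_config(0, lam),
                  tol = 1e-12, max_iter = 50000)
  expect_equal(f_gr$weights, f_l1$weights, tolerance = 1e-6)
})

test_that("solver trace is monotone and never exceeds J(0) = ln 2", {
  inst <- random_instance(30, 12, 3, seed = 41)
  fit <- sgl_fit(inst$X, inst$y, inst$m, penalty_config(0.02, 0.05))
  expect_true(all(diff(fit$trace) <= 0))
  expect_lte(fit$objective_value, log(2))
  expect_equal(fit$objective_value,
               naive_objective(fit$weights, inst$X, inst$y, inst$m, 0.02, 0.05),
               tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("objective is convex along random chords", {
  inst <- random_instance(20, 8, 2, seed = 51)
  pen <- penalty_config(0.1, 0.2)
  for (s in 1:10) {
    set.seed(s)
    w1 <- rnorm(8); w2 <- rnorm(8); a <- runif(1)
    J <- function(w) as.numeric(sgl_objective(w, inst$X, inst$y, inst$m, pen))
    expect_lte(J(a * w1 + (1 - a) * w2), a * J(w1) + (1 - a) * J(w2) + 1e-12)
  }
})

test_that("classification follows the discriminant rule with tie to healthy", {
  w <- c(1, -1)
  expect_identical(sgl_classify(c(1.05, 1), w), 1L)   # x'w = 0.05 > 0
  expect_identical(sgl_classify(c(1, 1), w), -1L)     # tie -> healthy
  set.seed(6)
  X <- matrix(rnorm(40), 20, 2)
  s <- as.vector(X %*% w)
  expect_identical(sgl_classify(X, w), ifelse(s > 0, 1L, -1L))
})

test_that("regularization path is warm-start consistent and sparsifies", {
  ds <- generate_synth(tiny_spec(grid_shape = c(4, 4, 2), n_areas = 4,
                                 n_per_class = 15, effect_size = 1.5))
  pp <- preprocess_pipeline(ds$features)
  X <- pp$features$values; y <- pp$features$labels
  g0 <- -as.vector(crossprod(X, y)) / (2 * nrow(X))
  lam_max <- max(abs(g0))
  grid <- data.frame(lambda_s = exp(seq(log(0.02), log(lam_max * 1.1),
                                        length.out = 8)),
                     lambda_g = 0)
  fits <- sgl_path(X, y, pp$groups, grid, tol = 1e-10)
  gs <- attr(fits, "grid")
  expect_true(all(diff(gs$lambda_s) <= 0))      # strongest penalty first
  expect_length(fits[[1]]$support, 0)           # above threshold: empty
  nnz <- vapply(fits, function(f) length(f$support), integer(1))
  expect_gt(nnz[length(fits)], nnz[1])          # endpoint sparsity ordering
  # warm-started results match cold starts
  for (i in c(3, length(fits))) {
    cold <- sgl_fit(X, y, pp$groups,
                    penalty_config(gs$lambda_s[i], gs$lambda_g[i]),
                    tol = 1e-10)
    expect_lt(abs(cold$objective_value - fits[[i]]$objective_value), 1e-6)
  }
})

test_that("optional intercept and group-size weighting behave sanely", {
  inst <- random_instance(40, 6, 2, seed = 61)
  y_imb <- inst$y; y_imb[1:30] <- 1L  # imbalanced labels
  fit_i <- sgl_fit(inst$X, y_imb, inst$m, penalty_config(0.05, 0),
                   intercept = TRUE)
  expect_true(is.finite(fit_i$b) && fit_i$b != 0)
  fit_w <- sgl_fit(inst$X, inst$y, inst$m, penalty_config(0, 0.1),
                   group_size_weights = TRUE, tol = 1e-10)
  # equal group sizes: sqrt-size weighting is a uniform rescale of lambda_g
  fit_u <- sgl_fit(inst$X, inst$y, inst$m, penalty_config(0, 0.1 * sqrt(3)),
                   tol = 1e-10)
  expect_equal(fit_w$weights, fit_u$weights, tolerance = 1e-5)
  expect_error(sgl_fit(matrix(c(1, NA, 1, 2), 2), c(-1, 1), c(1, 1),
                       penalty_config(0.1, 0)), "non-finite")
})
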