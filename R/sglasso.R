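#' Penalty configuration for sparse / group / sparse-group LASSO
#'
#' `lambda_s` weights the L1 (voxel-wise) penalty, `lambda_g` the sum of
#' per-group Euclidean norms (area-wise penalty). `lambda_g = 0` gives the
#' standard sparse LASSO, `lambda_s = 0` the group LASSO, both positive the
#' sparse-group LASSO.
#'
#' @param lambda_s,lambda_g nonnegative penalty weights.
#' @return object of class `penalty_config`.
#' @export
penalty_config <- function(lambda_s, lambda_g) {
  if (lambda_s < 0 || lambda_g < 0) stopf("penalty weights must be >= 0")
  structure(list(lambda_s = lambda_s, lambda_g = lambda_g),
            class = "penalty_config")
}

# normalize groups argument to an integer membership vector
group_membership <- function(groups, d) {
  m <- if (inherits(groups, "group_structure")) groups$membership else as.integer(groups)
  if (length(m) != d) stopf("group membership length %d != %d features", length(m), d)
  m
}

#' Class probabilities of the logistic model
#'
#' P(y | x; w) = 1 / (1 + exp(-y x'w)), so the log odds ratio
#' log P(+1|x) / P(-1|x) equals x'w exactly.
#'
#' @param x feature vector, or an n x d matrix of feature vectors.
#' @param w weight vector (length d).
#' @return matrix with columns `p_pos`, `p_neg` (one row per input vector).
#' @export
predict_proba <- function(x, w) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(w)) stopf("dim mismatch: %d features vs %d weights",
                                  ncol(x), length(w))
  s <- as.vector(x %*% w)
  p <- plogis(s)
  cbind(p_pos = p, p_neg = 1 - p)
}

#' Negative mean log likelihood f(w)
#'
#' f(w) = -(1/n) sum_i log P(y_i | x_i; w); f(0) = log 2 exactly.
#'
#' @param w weight vector.
#' @param X n x d feature matrix.
#' @param y labels in -1/+1.
#' @return scalar f(w) >= 0.
#' @export
neg_mean_loglik <- function(w, X, y) {
  if (length(y) == 0L || nrow(X) == 0L) stopf("empty data")
  m <- y * as.vector(X %*% w)
  mean(log1pexp(-m))
}

# gradient of f at w: -(1/n) X' (y * sigma(-y Xw))
grad_negmll <- function(w, X, y) {
  m <- y * as.vector(X %*% w)
  -as.vector(crossprod(X, y * plogis(-m))) / nrow(X)
}

#' Penalized objective J(w)
#'
#' J(w) = f(w) + lambda_s ||w||_1 + lambda_g sum_g ||w_g||_2 over the group
#' partition. Every group is weighted equally (no sqrt-group-size factor)
#' unless `group_size_weights = TRUE`.
#'
#' @param w weight vector.
#' @param X,y data.
#' @param groups [group_structure()] or membership vector.
#' @param penalty [penalty_config()].
#' @param group_size_weights multiply each group penalty by sqrt(group size).
#' @return J(w), with attribute `parts` giving loss, l1 and group terms.
#' @export
sgl_objective <- function(w, X, y, groups, penalty, group_size_weights = FALSE) {
  m <- group_membership(groups, length(w))
  loss <- neg_mean_loglik(w, X, y)
  l1 <- penalty$lambda_s * sum(abs(w))
  gn <- sqrt(rowsum(w^2, m)[, 1])
  if (group_size_weights) gn <- gn * sqrt(tabulate(m))
  l2 <- penalty$lambda_g * sum(gn)
  structure(loss + l1 + l2, parts = c(loss = loss, l1 = l1, group = l2))
}

#' Proximal operator of the sparse-group penalty
#'
#' Returns the minimizer of `(1/2t)||z - v||^2 + lambda_s ||z||_1 +
#' lambda_g sum_g ||z_g||_2`: elementwise soft-thresholding by `t*lambda_s`
#' followed by per-group shrinkage by `max(1 - t*lambda_g / ||u_g||_2, 0)`.
#'
#' @param v input vector.
#' @param t step size > 0.
#' @param penalty [penalty_config()].
#' @param groups group membership.
#' @param gw optional per-group penalty multipliers (sqrt group size).
#' @return the prox vector, same length as `v`.
#' @export
prox_sgl <- function(v, t, penalty, groups, gw = NULL) {
  stopifnot(t > 0)
  m <- group_membership(groups, length(v))
  u <- sign(v) * pmax(abs(v) - t * penalty$lambda_s, 0)
  if (penalty$lambda_g > 0) {
    gn <- sqrt(rowsum(u^2, m)[, 1])
    lamg <- t * penalty$lambda_g * (if (is.null(gw)) 1 else gw)
    scale <- ifelse(gn > lamg, 1 - lamg / gn, 0)
    u <- u * as.vector(scale)[match(m, sort(unique(m)))]
  }
  unname(u)
}

# largest squared singular value of X via power iteration (deterministic start)
spectral_norm_sq <- function(X) {
  v <- rep(1 / sqrt(ncol(X)), ncol(X))
  for (i in 1:60) {
    u <- as.vector(X %*% v)
    v2 <- as.vector(crossprod(X, u))
    nv <- sqrt(sum(v2^2))
    if (nv == 0) return(0)
    v <- v2 / nv
  }
  sum((X %*% v)^2)
}

#' Fit penalized logistic regression by monotone FISTA
#'
#' Minimizes J(w) = f(w) + lambda_s ||w||_1 + lambda_g sum_g ||w_g||_2 with
#' an accelerated proximal-gradient method: backtracking line search started
#' from the Lipschitz estimate ||X||_2^2 / (4n), Nesterov momentum, and a
#' monotone safeguard (if the accelerated step increases J, a plain proximal
#' step from the current iterate is taken and momentum restarts), so the
#' recorded objective trace is non-increasing. Convergence is declared when
#' the relative objective change or relative weight change drops below
#' `tol`. No intercept is fitted by default (features are expected to be
#' voxel-wise standardized with balanced classes); an optional unpenalized
#' intercept is available via `intercept = TRUE`.
#'
#' @param X n x d matrix (standardized features recommended).
#' @param y labels in -1/+1.
#' @param groups [group_structure()] or membership vector.
#' @param penalty [penalty_config()].
#' @param w0 warm-start weights (default all zero).
#' @param max_iter,tol solver controls.
#' @param intercept fit an unpenalized intercept (stored as `b`).
#' @param group_size_weights multiply group penalties by sqrt(group size).
#' @param zero_tol magnitude below which a weight does not count as support.
#' @param L optional precomputed Lipschitz estimate (reused along a path).
#' @return object of class `sgl_fit`: `weights` (vector `w`), `b`, `support`,
#'   `group_support`, `penalty`, `objective_value`, `n_iter`, `converged`,
#'   `trace` (per-iteration objective, non-increasing).
#' @export
sgl_fit <- function(X, y, groups, penalty, w0 = NULL, max_iter = 2000L,
                    tol = 1e-8, intercept = FALSE,
                    group_size_weights = FALSE, zero_tol = 1e-8, L = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y))) stopf("non-finite values in data")
  n <- nrow(X); d <- ncol(X)
  m <- group_membership(groups, d)
  if (penalty$lambda_s == 0 && penalty$lambda_g == 0 && d > n)
    warning("unpenalized logistic fit with d > n is not well defined")
  gw <- if (group_size_weights) sqrt(tabulate(m)) else rep(1, max(m))
  if (intercept) X <- cbind(X, 1)
  dd <- ncol(X)
  if (is.null(L)) L <- spectral_norm_sq(X) / (4 * n)
  w_start <- if (is.null(w0)) rep(0, dd) else {
    if (length(w0) == d && intercept) c(w0, 0) else w0
  }
  if (length(w_start) != dd) stopf("w0 has wrong length")
  res <- sgl_fista_cpp(X, as.numeric(y), m - 1L, penalty$lambda_s,
                       penalty$lambda_g, gw, w_start,
                       as.integer(max_iter), tol, L, d)
  w <- as.vector(res$w)
  wp <- w[seq_len(d)]
  b <- if (intercept) w[dd] else 0
  it <- res$n_iter
  converged <- res$converged
  J_w <- res$objective
  trace <- as.vector(res$trace)
  support <- which(abs(wp) > zero_tol)
  structure(list(weights = wp, b = b,
                 support = support,
                 group_support = sort(unique(m[support])),
                 penalty = penalty,
                 objective_value = J_w, n_iter = it, converged = converged,
                 trace = trace, zero_tol = zero_tol),
            class = "sgl_fit")
}

#' @export
print.sgl_fit <- function(x, ...) {
  cat(sprintf(
    "sgl_fit: lambda_s=%.4g lambda_g=%.4g | J=%.6g | %d/%d nonzero weights in %d groups | %s in %d iter\n",
    x$penalty$lambda_s, x$penalty$lambda_g, x$objective_value,
    length(x$support), length(x$weights), length(x$group_support),
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Discriminant rule
#'
#' Predicts +1 (patient) iff x'w > 0, otherwise -1; the tie x'w = 0 maps to
#' -1 (healthy), the conservative diagnosis.
#'
#' @param x feature vector or matrix of rows.
#' @param w weight vector or `sgl_fit`.
#' @return vector of -1/+1 labels.
#' @export
sgl_classify <- function(x, w) {
  if (inherits(w, "sgl_fit")) { b <- w$b; w <- w$weights } else b <- 0
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  s <- as.vector(x %*% w) + b
  ifelse(s > 0, 1L, -1L)
}

#' Regularization path with warm starts
#'
#' Fits the model over a grid of penalty configurations, ordered from
#' strongest to weakest penalty, warm-starting each fit at the previous
#' solution. At any `lambda_s >= max|grad f(0)|` (with `lambda_g = 0`) or
#' `lambda_g >= max_g ||grad f(0)_g||_2` (with `lambda_s = 0`) the exact
#' solution is w = 0.
#'
#' @param X,y,groups as in [sgl_fit()].
#' @param grid data.frame with columns `lambda_s`, `lambda_g` (or a
#'   [lambda_grid()] object).
#' @param ... passed to [sgl_fit()].
#' @return list of `sgl_fit`, in the order of the (sorted) grid; the grid
#'   used is attached as attribute `grid`.
#' @export
sgl_path <- function(X, y, groups, grid, ...) {
  if (inherits(grid, "lambda_grid")) grid <- grid$values
  ord <- order(-grid$lambda_g, -grid$lambda_s)
  grid_sorted <- grid[ord, , drop = FALSE]
  L <- spectral_norm_sq(as.matrix(X)) / (4 * nrow(X))
  fits <- vector("list", nrow(grid_sorted))
  w0 <- NULL
  for (i in seq_len(nrow(grid_sorted))) {
    pen <- penalty_config(grid_sorted$lambda_s[i], grid_sorted$lambda_g[i])
    fits[[i]] <- sgl_fit(X, y, groups, pen, w0 = w0, L = L, ...)
    w0 <- fits[[i]]$weights
  }
  attr(fits, "grid") <- grid_sorted
  fits
}

#' Check KKT optimality of a fit
#'
#' For the convex objective J, a weight vector is optimal iff
#' 0 is in grad f(w) + lambda_s d||w||_1 + lambda_g d(sum_g ||w_g||_2).
#' Returns the maximum violation over all subgradient conditions:
#' for a wholly zero group g, `|| S(-grad_g, lambda_s) ||_2 <= lambda_g`
#' (S = soft-threshold); within an active group, `-grad_j = lambda_s
#' sign(w_j) + lambda_g w_j / ||w_g||` for nonzero w_j and
#' `|-grad_j| <= lambda_s` for zero w_j.
#'
#' @param fit an `sgl_fit` (or weight vector).
#' @param X,y,groups,penalty problem data (penalty taken from the fit if
#'   omitted).
#' @param active_tol magnitude above which a weight counts as active.
#' @return maximum KKT violation (0 at an exact optimum).
#' @export
sgl_kkt_violation <- function(fit, X, y, groups, penalty = NULL,
                              active_tol = 1e-7) {
  w <- if (inherits(fit, "sgl_fit")) fit$weights else fit
  penalty <- penalty %||% fit$penalty
  m <- group_membership(groups, length(w))
  r <- -grad_negmll(w, X, y)
  viol <- 0
  for (g in unique(m)) {
    j <- which(m == g)
    wg <- w[j]; rg <- r[j]
    if (all(abs(wg) <= active_tol)) {
      sg <- sign(rg) * pmax(abs(rg) - penalty$lambda_s, 0)
      viol <- max(viol, sqrt(sum(sg^2)) - penalty$lambda_g)
    } else {
      ng <- sqrt(sum(wg^2))
      for (k in seq_along(j)) {
        if (abs(wg[k]) > active_tol) {
          viol <- max(viol, abs(rg[k] - penalty$lambda_s * sign(wg[k]) -
                                  penalty$lambda_g * wg[k] / ng))
        } else {
          viol <- max(viol, abs(rg[k]) - penalty$lambda_s)
        }
      }
    }
  }
  max(viol, 0)
}
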