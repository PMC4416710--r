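#' Regularization-parameter grids
#'
#' Log-spaced penalty grids per algorithm. The `"paper"` preset uses the
#' study's published grids: sLASSO 200 values of lambda_s in
#' \[0.01, 0.2512\]; gLASSO 100 values of lambda_g in \[0.1, 0.6310\];
#' sgLASSO 200 combinations of 20 lambda_s in \[1e-6, 0.1\] by 10 lambda_g
#' in \[0.0631, 0.3162\]. The `"demo"` preset spans the same ranges with 20
#' points per algorithm (5 x 4 for sgLASSO) for reduced-scale runs.
#'
#' @param algorithm `"slasso"`, `"glasso"` or `"sglasso"`.
#' @param preset `"paper"` or `"demo"`.
#' @return object of class `lambda_grid` with fields `algorithm` and
#'   `values` (data.frame of `lambda_s`, `lambda_g`).
#' @export
lambda_grid <- function(algorithm = c("slasso", "glasso", "sglasso"),
                        preset = c("paper", "demo")) {
  algorithm <- match.arg(algorithm)
  preset <- match.arg(preset)
  logspace <- function(a, b, n) exp(seq(log(a), log(b), length.out = n))
  values <- switch(algorithm,
    slasso = data.frame(
      lambda_s = logspace(0.01, 0.2512, if (preset == "paper") 200L else 20L),
      lambda_g = 0),
    glasso = data.frame(
      lambda_s = 0,
      lambda_g = logspace(0.1, 0.6310, if (preset == "paper") 100L else 20L)),
    sglasso = {
      ns <- if (preset == "paper") 20L else 5L
      ng <- if (preset == "paper") 10L else 4L
      expand.grid(lambda_s = logspace(1e-6, 0.1, ns),
                  lambda_g = logspace(0.0631, 0.3162, ng))
    })
  structure(list(algorithm = algorithm, preset = preset, values = values),
            class = "lambda_grid")
}

#' Mean log likelihood of assigned probabilities
#'
#' mu_logL = (1/n) sum_i log P(y_i | x_i; w), the model-selection criterion.
#' Probabilities are clipped at 1e-12 before the log so separable fits do
#' not produce -Inf.
#'
#' @param p probabilities assigned to the true labels.
#' @return scalar <= 0.
#' @export
mean_loglik <- function(p) {
  if (!length(p)) stopf("empty probability vector")
  mean(log(pmax(p, 1e-12)))
}

#' Confusion counts
#'
#' @param truth,pred label vectors in -1/+1 (+1 = patient).
#' @return object of class `confusion_counts` (tp, fn, tn, fp).
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(list(tp = sum(truth == 1 & pred == 1),
                 fn = sum(truth == 1 & pred == -1),
                 tn = sum(truth == -1 & pred == -1),
                 fp = sum(truth == -1 & pred == 1)),
            class = "confusion_counts")
}

#' Classification performance criteria
#'
#' Sensitivity = TP/(TP+FN), Specificity = TN/(TN+FP), Accuracy =
#' (TP+TN)/n, Precision = TP/(TP+FP), Recall = Sensitivity, and Fscore =
#' TP / (TP + (FN+FP)/2), the harmonic mean of precision and recall.
#' A metric whose denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param counts a [confusion_counts()] or list with tp, fn, tn, fp.
#' @return named list of the six criteria.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    rat <- function(num, den) if (den > 0) num / den else NA_real_
    sens <- rat(tp, tp + fn)
    spec <- rat(tn, tn + fp)
    acc <- rat(tp + tn, tp + fn + tn + fp)
    prec <- rat(tp, tp + fp)
    fs <- rat(tp, tp + (fn + fp) / 2)
    list(sensitivity = sens, specificity = spec, accuracy = acc,
         precision = prec, recall = sens, fscore = fs)
  })
}

#' Normalized discriminative scores
#'
#' The log odds ratio log(P(+1|x)/P(-1|x)) = x'w of every pooled test
#' subject, normalized by the maximum absolute value over the pool, so all
#' scores lie in \[-1, 1\] with |score| = 1 attained at the pool maximum.
#'
#' @param raw_scores pooled x'w values.
#' @param truth true labels.
#' @param pred predicted labels (default: discriminant rule on raw scores).
#' @return data.frame of class `score_set` with `score`, `truth`, `pred`.
#' @export
discriminative_scores <- function(raw_scores, truth,
                                  pred = ifelse(raw_scores > 0, 1L, -1L)) {
  mx <- max(abs(raw_scores))
  structure(data.frame(score = if (mx > 0) raw_scores / mx else raw_scores,
                       truth = truth, pred = pred),
            class = c("score_set", "data.frame"))
}

#' Stratified k-fold assignment
#'
#' Controls and patients are split separately into k folds whose per-class
#' sizes differ by at most one; deterministic given the seed.
#'
#' @param labels -1/+1 class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id (1..k) per subject.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (any(table(labels) < k))
    stopf("each class needs at least k=%d members; use a smaller k", k)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in c(-1L, 1L)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  fold
}

#' Inner-loop selection of the optimal penalty
#'
#' For each grid point, models are fitted on each inner training fold (warm
#' started along the regularization path) and the probabilities assigned to
#' the true labels of the held-out inner-fold subjects are pooled; the grid
#' point maximizing the pooled mean log likelihood is returned. Ties are
#' broken toward the sparser model (larger lambda_s, then larger lambda_g)
#' and flagged in the result. Grid points yielding non-finite objectives
#' are excluded with a warning.
#'
#' @param X,y,groups training data (TrainingData1).
#' @param grid a [lambda_grid()] or data.frame.
#' @param k inner folds.
#' @param seed fold-shuffling seed.
#' @param ... passed to [sgl_fit()].
#' @return list: `penalty` (optimal [penalty_config()]), `mu_logL` per grid
#'   point (in sorted-grid order), `grid`, `tie` flag.
#' @export
inner_select <- function(X, y, groups, grid, k = 10L, seed = 1L, ...) {
  if (inherits(grid, "lambda_grid")) grid <- grid$values
  fold <- make_folds(y, k, seed)
  npts <- nrow(grid)
  logp <- vector("list", npts)  # pooled log-probabilities per grid point
  grid_sorted <- NULL
  for (f in seq_len(k)) {
    tr <- fold != f
    fits <- sgl_path(X[tr, , drop = FALSE], y[tr], groups, grid, ...)
    grid_sorted <- attr(fits, "grid")
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    for (i in seq_len(npts)) {
      s <- as.vector(Xte %*% fits[[i]]$weights) + fits[[i]]$b
      p <- plogis(yte * s)
      logp[[i]] <- c(logp[[i]], log(pmax(p, 1e-12)))
    }
  }
  mu <- vapply(logp, mean, numeric(1))
  bad <- !is.finite(mu)
  if (any(bad)) {
    warning(sprintf("excluding %d diverged grid point(s)", sum(bad)))
    mu[bad] <- -Inf
  }
  # mu_logL differences below numerical resolution count as ties
  best <- which(mu >= max(mu) - 1e-9)
  tie <- length(best) > 1L
  if (tie) {
    o <- order(-grid_sorted$lambda_s[best], -grid_sorted$lambda_g[best])
    best <- best[o]
  }
  best <- best[1L]
  list(penalty = penalty_config(grid_sorted$lambda_s[best],
                                grid_sorted$lambda_g[best]),
       mu_logL = mu, grid = grid_sorted, tie = tie)
}

#' Nested stratified 10-fold cross-validation
#'
#' The full model-selection-and-evaluation procedure: per repeat, subjects
#' are split into k stratified outer folds; for each outer fold, an inner
#' k-fold cross-validation on the outer training data alone selects the
#' penalty maximizing the pooled mean log likelihood; the model is refitted
#' on the full outer training set at that penalty and the held-out fold is
#' scored. Fold shuffling differs per repeat; every random draw derives from
#' `seed`. Inner folds never touch the outer test subjects (provenance is
#' recorded per fold and can be audited with [check_no_leakage()]).
#'
#' Per repeat, metrics are computed from the pooled confusion counts of all
#' outer folds; the report aggregates mean and SD over repeats. Both the
#' mean log likelihood (mu_logL) and its exponential exp(mu_logL) ("mean
#' likelihood") are reported. Discriminative scores are pooled over all
#' test predictions of the run and normalized by the pooled maximum.
#'
#' @param X n x d standardized feature matrix.
#' @param y labels in -1/+1.
#' @param groups a [group_structure()] or membership vector.
#' @param grid a [lambda_grid()].
#' @param k folds (outer and inner).
#' @param n_repeats shuffled repetitions of the whole procedure.
#' @param seed master seed.
#' @param keep_models keep every refitted outer model (needed for stability
#'   analysis).
#' @param ... passed to [sgl_fit()].
#' @return object of class `cv_report`: `records` (per repeat x outer fold:
#'   chosen penalty, test ids, probabilities, predictions, provenance),
#'   `models` (if kept), `metrics_by_repeat` data.frame, `summary` (mean and
#'   sd of each criterion over repeats), `scores` ([discriminative_scores()]
#'   over the pooled run), `n_subjects`, `seed`.
#' @export
nested_cv <- function(X, y, groups, grid, k = 10L, n_repeats = 5L, seed = 1L,
                      keep_models = TRUE, ...) {
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X)
  records <- list()
  models <- list()
  mets <- NULL
  pooled_scores <- numeric(0); pooled_truth <- integer(0)
  pooled_pred <- integer(0); pooled_subject <- integer(0)
  for (r in seq_len(n_repeats)) {
    outer_fold <- make_folds(y, k, derive_seed(seed, r, 1L))
    rep_truth <- integer(0); rep_pred <- integer(0); rep_logp <- numeric(0)
    for (f in seq_len(k)) {
      tr <- outer_fold != f
      sel <- inner_select(X[tr, , drop = FALSE], y[tr], groups, grid,
                          k = k, seed = derive_seed(seed, r, f, 2L), ...)
      fit <- sgl_fit(X[tr, , drop = FALSE], y[tr], groups, sel$penalty, ...)
      Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
      s <- as.vector(Xte %*% fit$weights) + fit$b
      pred <- ifelse(s > 0, 1L, -1L)
      p_true <- plogis(yte * s)
      rec <- list(repeat_id = r, fold = f, penalty = sel$penalty,
                  tie = sel$tie,
                  test_idx = which(!tr),
                  provenance = list(train_idx = which(tr),
                                    test_idx = which(!tr),
                                    inner_pool_idx = which(tr)),
                  raw_scores = s, p_true = p_true, pred = pred, truth = yte,
                  converged = fit$converged)
      records[[length(records) + 1L]] <- rec
      if (keep_models) models[[length(models) + 1L]] <- fit
      rep_truth <- c(rep_truth, yte); rep_pred <- c(rep_pred, pred)
      rep_logp <- c(rep_logp, log(pmax(p_true, 1e-12)))
      pooled_scores <- c(pooled_scores, s)
      pooled_truth <- c(pooled_truth, yte)
      pooled_pred <- c(pooled_pred, pred)
      pooled_subject <- c(pooled_subject, which(!tr))
    }
    cm <- classification_metrics(confusion_counts(rep_truth, rep_pred))
    mets <- rbind(mets, data.frame(repeat_id = r, as.data.frame(cm),
                                   mu_logL = mean(rep_logp),
                                   likelihood = exp(mean(rep_logp))))
  }
  scores <- discriminative_scores(pooled_scores, pooled_truth, pooled_pred)
  scores$subject <- pooled_subject
  scores$repeat_id <- rep(seq_len(n_repeats), each = n)
  num <- setdiff(names(mets), "repeat_id")
  summ <- data.frame(metric = num,
                     mean = vapply(num, function(v) mean(mets[[v]]), numeric(1)),
                     sd = vapply(num, function(v) sd(mets[[v]]), numeric(1)),
                     row.names = NULL)
  structure(list(records = records, models = if (keep_models) models,
                 metrics_by_repeat = mets, summary = summ, scores = scores,
                 n_subjects = n, k = k, n_repeats = n_repeats, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d repeats of nested %d-fold CV on %d subjects\n",
              x$n_repeats, x$k, x$n_subjects))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Audit a cross-validation report for train/test leakage
#'
#' Asserts, per outer-fold record, that the subjects used for inner-loop
#' penalty selection are exactly the outer training subjects and are
#' disjoint from the outer test subjects, and that within each repeat every
#' subject is scored exactly once.
#'
#' @param report a `cv_report`.
#' @return TRUE invisibly; stops with a message on any violation.
#' @export
check_no_leakage <- function(report) {
  for (rec in report$records) {
    pv <- rec$provenance
    if (length(intersect(pv$inner_pool_idx, pv$test_idx)))
      stopf("leakage: inner selection saw outer test subjects (repeat %d fold %d)",
            rec$repeat_id, rec$fold)
    if (!setequal(pv$inner_pool_idx, pv$train_idx))
      stopf("provenance mismatch in repeat %d fold %d", rec$repeat_id, rec$fold)
  }
  for (r in unique(vapply(report$records, `[[`, numeric(1), "repeat_id"))) {
    idx <- unlist(lapply(report$records,
                         function(z) if (z$repeat_id == r) z$test_idx))
    if (!setequal(idx, seq_len(report$n_subjects)) ||
        length(idx) != report$n_subjects)
      stopf("repeat %d does not score every subject exactly once", r)
  }
  invisible(TRUE)
}

#' Rank-sum comparison of two algorithms' per-repeat metrics
#'
#' Convenience wrapper around the two-sided Wilcoxon rank-sum test applied
#' to a per-repeat metric column of two cross-validation reports.
#'
#' @param report_a,report_b `cv_report` objects.
#' @param metric column of `metrics_by_repeat` to compare.
#' @return the `htest` from [stats::wilcox.test()].
#' @export
compare_algorithms <- function(report_a, report_b, metric = "fscore") {
  stats::wilcox.test(report_a$metrics_by_repeat[[metric]],
                     report_b$metrics_by_repeat[[metric]], exact = FALSE)
}
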