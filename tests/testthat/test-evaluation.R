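test_that("lambda grids honor the published endpoints and algorithm structure", {
  gs <- lambda_grid("slasso", "paper")
  expect_equal(nrow(gs$values), 200)
  expect_equal(range(gs$values$lambda_s), c(0.01, 0.2512))
  expect_true(all(gs$values$lambda_g == 0))
  gg <- lambda_grid("glasso", "paper")
  expect_equal(nrow(gg$values), 100)
  expect_equal(range(gg$values$lambda_g), c(0.1, 0.6310))
  expect_true(all(gg$values$lambda_s == 0))
  gsg <- lambda_grid("sglasso", "paper")
  expect_equal(nrow(gsg$values), 200)
  expect_equal(range(gsg$values$lambda_s), c(1e-6, 0.1))
  expect_equal(range(gsg$values$lambda_g), c(0.0631, 0.3162))
  # log-spacing: constant ratio between consecutive values
  r <- diff(log(gs$values$lambda_s))
  expect_lt(diff(range(r)), 1e-12)
  expect_equal(nrow(lambda_grid("slasso", "demo")$values), 20)
})

test_that("mean log likelihood matches its closed forms and summation oracle", {
  expect_equal(mean_loglik(rep(0.5, 8)), log(0.5))
  expect_equal(mean_loglik(rep(1, 3)), 0)
  set.seed(7)
  p <- runif(20, 0.1, 1)
  expect_equal(mean_loglik(p), sum(log(p)) / 20, tolerance = 1e-12)
  expect_lte(mean_loglik(p), 0)
  # clipping keeps separable fits finite
  expect_true(is.finite(mean_loglik(c(0, 1))))
})

test_that("performance criteria follow their defining formulas", {
  perfect <- classification_metrics(list(tp = 31, fn = 0, tn = 31, fp = 0))
  expect_true(all(unlist(perfect) == 1))
  m <- classification_metrics(list(tp = 10, fn = 5, tn = 20, fp = 5))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$fscore, 10 / 15)
  # harmonic-mean identity and formula oracle on random counts
  set.seed(8)
  for (i in 1:10) {
    ct <- as.list(rmultinom(1, 60, c(0.3, 0.2, 0.3, 0.2))[, 1])
    names(ct) <- c("tp", "fn", "tn", "fp")
    mm <- classification_metrics(ct)
    expect_equal(mm$sensitivity, ct$tp / (ct$tp + ct$fn))
    expect_equal(mm$specificity, ct$tn / (ct$tn + ct$fp))
    if (!is.na(mm$precision) && !is.na(mm$recall) &&
        (mm$precision + mm$recall) > 0)
      expect_equal(mm$fscore,
                   2 * mm$precision * mm$recall / (mm$precision + mm$recall),
                   tolerance = 1e-12)
  }
  # undefined metric is NA, not zero
  expect_true(is.na(classification_metrics(list(tp = 0, fn = 0, tn = 5,
                                                fp = 0))$sensitivity))
})

test_that("discriminative scores are normalized by the pool maximum", {
  one <- discriminative_scores(3.2, 1L)
  expect_equal(one$score, 1)
  pair <- discriminative_scores(c(2.5, -2.5), c(1L, -1L))
  expect_equal(pair$score, c(1, -1))
  set.seed(9)
  raw <- rnorm(50)
  ss <- discriminative_scores(raw, sample(c(-1L, 1L), 50, TRUE))
  expect_true(all(abs(ss$score) <= 1))
  expect_equal(max(abs(ss$score)), 1)
  expect_equal(sum(abs(abs(ss$score) - 1) < 1e-15), 1)  # unique up to ties
  expect_equal(which.max(abs(ss$score)), which.max(abs(raw)))
})

test_that("folds are stratified, balanced and reproducible", {
  y <- rep(c(-1L, 1L), each = 31)
  f <- make_folds(y, k = 10, seed = 3)
  for (cl in c(-1L, 1L)) {
    sizes <- tabulate(f[y == cl], 10)
    expect_true(all(sizes %in% c(3, 4)))   # 31 into 10 folds
  }
  expect_identical(make_folds(y, 10, 3), f)
  expect_false(identical(make_folds(y, 10, 4), f))
  # leave-one-out degenerate case: singleton folds per class
  y2 <- rep(c(-1L, 1L), each = 4)
  f2 <- make_folds(y2, k = 4, seed = 1)
  expect_true(all(tabulate(f2[y2 == 1], 4) == 1))
  expect_error(make_folds(y2, k = 5), "smaller k")
})

test_that("inner selection maximizes pooled mean log likelihood", {
  ds <- generate_synth(tiny_spec(grid_shape = c(4, 4, 2), n_areas = 4,
                                 n_per_class = 10, effect_size = 2))
  pp <- preprocess_pipeline(ds$features)
  X <- pp$features$values; y <- pp$features$labels
  # single-point grid returns that point
  sel1 <- inner_select(X, y, pp$groups,
                       data.frame(lambda_s = 0.1, lambda_g = 0), k = 5)
  expect_equal(sel1$penalty$lambda_s, 0.1)
  # duplicated grid point: deterministic tie-break, tie flagged
  sel2 <- inner_select(X, y, pp$groups,
                       data.frame(lambda_s = c(0.1, 0.1), lambda_g = 0), k = 5)
  expect_true(sel2$tie)
  expect_equal(sel2$penalty$lambda_s, 0.1)
  # the returned point attains the maximum of the reported curve
  grid <- data.frame(lambda_s = 0, lambda_g = c(0.1, 0.2, 0.4))
  sel3 <- inner_select(X, y, pp$groups, grid, k = 5, seed = 2)
  best_mu <- max(sel3$mu_logL)
  chosen <- which(sel3$grid$lambda_g == sel3$penalty$lambda_g &
                    sel3$grid$lambda_s == sel3$penalty$lambda_s)
  expect_equal(sel3$mu_logL[chosen], best_mu)
})

test_that("nested CV scores every subject exactly once per repeat", {
  ds <- generate_synth(tiny_spec(grid_shape = c(4, 4, 2), n_areas = 4,
                                 n_per_class = 6, effect_size = 2))
  pp <- preprocess_pipeline(ds$features)
  grid <- data.frame(lambda_s = c(0.05, 0.15), lambda_g = 0)
  rep1 <- nested_cv(pp$features$values, pp$features$labels, pp$groups, grid,
                    k = 2, n_repeats = 1, seed = 7)
  expect_true(check_no_leakage(rep1))
  counts <- with(rep1$records[[1]], length(truth))
  n_scored <- sum(vapply(rep1$records, function(r) length(r$pred), integer(1)))
  expect_equal(n_scored, rep1$n_subjects)
  cm <- confusion_counts(
    unlist(lapply(rep1$records, `[[`, "truth")),
    unlist(lapply(rep1$records, `[[`, "pred")))
  expect_equal(cm$tp + cm$fn + cm$tn + cm$fp, rep1$n_subjects)
  expect_equal(cm$tp + cm$fn, 6)   # all patients accounted for
  # scores pooled over the run are normalized to [-1, 1] with max 1
  expect_true(all(abs(rep1$scores$score) <= 1))
  expect_equal(max(abs(rep1$scores$score)), 1)
})

test_that("nested CV is deterministic given the master seed", {
  ds <- generate_synth(tiny_spec(grid_shape = c(4, 4, 2), n_areas = 4,
                                 n_per_class = 6, effect_size = 2))
  pp <- preprocess_pipeline(ds$features)
  grid <- data.frame(lambda_s = c(0.05, 0.15), lambda_g = 0)
  r1 <- nested_cv(pp$features$values, pp$features$labels, pp$groups, grid,
                  k = 3, n_repeats = 2, seed = 5, keep_models = FALSE)
  r2 <- nested_cv(pp$features$values, pp$features$labels, pp$groups, grid,
                  k = 3, n_repeats = 2, seed = 5, keep_models = FALSE)
  expect_identical(r1$metrics_by_repeat, r2$metrics_by_repeat)
  r3 <- nested_cv(pp$features$values, pp$features$labels, pp$groups, grid,
                  k = 3, n_repeats = 2, seed = 6, keep_models = FALSE)
  expect_false(identical(r1$metrics_by_repeat$accuracy,
                         r3$metrics_by_repeat$accuracy))
})

test_that("reported aggregates equal pooled-confusion metrics per repeat", {
  ds <- generate_synth(tiny_spec(grid_shape = c(4, 4, 2), n_areas = 4,
                                 n_per_class = 8, effect_size = 2))
  pp <- preprocess_pipeline(ds$features)
  grid <- data.frame(lambda_s = c(0.05, 0.15), lambda_g = 0)
  rep2 <- nested_cv(pp$features$values, pp$features$labels, pp$groups, grid,
                    k = 4, n_repeats = 3, seed = 2, keep_models = FALSE)
  for (r in 1:3) {
    recs <- Filter(function(z) z$repeat_id == r, rep2$records)
    cm <- confusion_counts(unlist(lapply(recs, `[[`, "truth")),
                           unlist(lapply(recs, `[[`, "pred")))
    expect_equal(rep2$metrics_by_repeat$accuracy[r],
                 classification_metrics(cm)$accuracy)
  }
  expect_equal(rep2$summary$mean[rep2$summary$metric == "accuracy"],
               mean(rep2$metrics_by_repeat$accuracy))
  # likelihood column is exp(mu_logL)
  expect_equal(rep2$metrics_by_repeat$likelihood,
               exp(rep2$metrics_by_repeat$mu_logL))
})
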