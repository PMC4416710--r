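#' Selection-frequency summary over cross-validated models
#'
#' Aggregates all fitted models of a cross-validation run (e.g. the 1000
#' models of 100 repeats x 10 outer folds) into per-voxel and per-area
#' selection statistics. A voxel is "selected" in a model iff its weight
#' magnitude exceeds the support tolerance; an area is selected iff any
#' member voxel is. Per-voxel mean positive and mean negative weights pool
#' the signed weights over the models in which the voxel was selected;
#' per-area means pool all positive (negative) selected voxel-weights
#' across models within the area and are additionally reported normalized
#' by the largest per-area mean of the same sign. Non-converged models are
#' excluded from the denominator and counted separately.
#'
#' @param models list of [sgl_fit()] objects, or a `cv_report` with kept
#'   models.
#' @param groups a [group_structure()] or membership vector.
#' @param zero_tol support threshold on |w|.
#' @return object of class `selection_summary`: `voxel` and `area`
#'   data.frames, `n_models`, `n_excluded`, `support_size_mean`,
#'   `support_size_sd`, `n_selected_once` (union size),
#'   `n_areas_selected_once`, `max_occurrence`.
#' @export
summarize_selection <- function(models, groups, zero_tol = 1e-8) {
  if (inherits(models, "cv_report")) {
    if (is.null(models$models))
      stopf("cv_report was run with keep_models = FALSE")
    models <- models$models
  }
  stopifnot(length(models) >= 1L)
  d <- length(models[[1]]$weights)
  m <- group_membership(groups, d)
  conv <- vapply(models, function(f) isTRUE(f$converged), logical(1))
  n_excluded <- sum(!conv)
  models <- models[conv]
  n_models <- length(models)
  if (!n_models) stopf("no converged models to summarize")
  if (!all(vapply(models, function(f) length(f$weights) == d, logical(1))))
    stopf("models have inconsistent feature dimension")

  count <- numeric(d)
  pos_sum <- numeric(d); pos_n <- numeric(d)
  neg_sum <- numeric(d); neg_n <- numeric(d)
  support_sizes <- integer(n_models)
  G <- max(m)
  area_count <- numeric(G)
  area_pos_count <- numeric(G); area_neg_count <- numeric(G)
  for (fit in models) {
    w <- fit$weights
    sel <- abs(w) > zero_tol
    count <- count + sel
    pos <- sel & w > 0; neg <- sel & w < 0
    pos_sum <- pos_sum + ifelse(pos, w, 0); pos_n <- pos_n + pos
    neg_sum <- neg_sum + ifelse(neg, w, 0); neg_n <- neg_n + neg
    gsel <- unique(m[sel])
    area_count[gsel] <- area_count[gsel] + 1
    gpos <- unique(m[pos]); gneg <- unique(m[neg])
    area_pos_count[gpos] <- area_pos_count[gpos] + 1
    area_neg_count[gneg] <- area_neg_count[gneg] + 1
  }
  support_sizes <- vapply(models, function(f) sum(abs(f$weights) > zero_tol),
                          integer(1))
  voxel <- data.frame(
    feature = seq_len(d), area = m,
    count = count, frequency = count / n_models,
    pos_n = pos_n, neg_n = neg_n,
    mean_pos_weight = ifelse(pos_n > 0, pos_sum / pos_n, NA_real_),
    mean_neg_weight = ifelse(neg_n > 0, neg_sum / neg_n, NA_real_),
    mean_weight = ifelse(count > 0, (pos_sum + neg_sum) / count, 0))
  area_pos_mean <- as.vector(rowsum(pos_sum, m)[, 1]) /
    pmax(as.vector(rowsum(pos_n, m)[, 1]), 1)
  area_neg_mean <- as.vector(rowsum(neg_sum, m)[, 1]) /
    pmax(as.vector(rowsum(neg_n, m)[, 1]), 1)
  area_pos_mean[rowsum(pos_n, m)[, 1] == 0] <- NA_real_
  area_neg_mean[rowsum(neg_n, m)[, 1] == 0] <- NA_real_
  norm_by_max <- function(v) {
    mx <- suppressWarnings(max(abs(v), na.rm = TRUE))
    if (is.finite(mx) && mx > 0) v / mx else v
  }
  gnames <- if (inherits(groups, "group_structure")) groups$group_names
            else sprintf("group%03d", seq_len(G))
  area <- data.frame(
    area = seq_len(G), name = gnames,
    frequency = area_count / n_models,
    frequency_pos = area_pos_count / n_models,
    frequency_neg = area_neg_count / n_models,
    mean_pos_weight = area_pos_mean,
    mean_neg_weight = area_neg_mean,
    norm_pos_weight = norm_by_max(area_pos_mean),
    norm_neg_weight = norm_by_max(area_neg_mean))
  structure(list(voxel = voxel, area = area, n_models = n_models,
                 n_excluded = n_excluded,
                 support_size_mean = mean(support_sizes),
                 support_size_sd = sd(support_sizes),
                 n_selected_once = sum(count > 0),
                 n_areas_selected_once = sum(area_count > 0),
                 max_occurrence = if (any(count > 0)) max(count) / n_models else 0,
                 zero_tol = zero_tol),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf(
    "selection_summary over %d models (%d excluded as non-converged)\n",
    x$n_models, x$n_excluded))
  cat(sprintf("  #selected voxels per model: %.2f +/- %.2f\n",
              x$support_size_mean, x$support_size_sd))
  cat(sprintf("  #voxels (#areas) selected at least once: %d (%d)\n",
              x$n_selected_once, x$n_areas_selected_once))
  cat(sprintf("  max occurrence of same voxel: %.1f%%\n",
              100 * x$max_occurrence))
  cat(sprintf("  #voxels with > 80%% occurrence: %d\n",
              sum(x$voxel$frequency > 0.8)))
  invisible(x)
}

#' Items selected more often than a frequency threshold
#'
#' Filters the voxel- or area-level table to entries with selection
#' frequency strictly greater than `threshold` (the study's ">80%" rule),
#' sorted by frequency then mean absolute weight, descending.
#'
#' @param summary a [summarize_selection()] result.
#' @param threshold frequency cut (strict inequality).
#' @param level `"voxel"` or `"area"`.
#' @return the filtered, sorted data.frame.
#' @export
frequent_set <- function(summary, threshold = 0.8,
                         level = c("voxel", "area")) {
  level <- match.arg(level)
  tab <- summary[[level]]
  tab <- tab[tab$frequency > threshold, , drop = FALSE]
  mw <- pmax(abs(ifelse(is.na(tab$mean_pos_weight), 0, tab$mean_pos_weight)),
             abs(ifelse(is.na(tab$mean_neg_weight), 0, tab$mean_neg_weight)))
  tab[order(-tab$frequency, -mw), , drop = FALSE]
}

#' Write mean selected weights into volume space
#'
#' Builds a volume whose voxels carry the mean signed weight (over the
#' models in which the voxel was selected), restricted to voxels whose
#' selection frequency strictly exceeds `threshold`, and optionally to one
#' sign. Unselected or sub-threshold voxels are zero.
#'
#' @param summary a [summarize_selection()] result.
#' @param voxel_index the feature matrix's `voxel_index` (needs `i`,`j`,`k`).
#' @param grid_shape volume extents.
#' @param sign `"both"`, `"positive"` or `"negative"`.
#' @param threshold frequency cut (strict; 0 keeps all ever-selected).
#' @param task restrict to columns of this task tag (default: first task).
#' @return numeric 3D array.
#' @export
weight_map <- function(summary, voxel_index, grid_shape,
                       sign = c("both", "positive", "negative"),
                       threshold = 0.8, task = NULL) {
  sign <- match.arg(sign)
  stopifnot(nrow(voxel_index) == nrow(summary$voxel))
  task <- task %||% voxel_index$task[1]
  vol <- array(0, dim = grid_shape)
  vx <- summary$voxel
  keep <- vx$frequency > threshold & voxel_index$task == task
  val <- switch(sign,
    both = vx$mean_weight,
    positive = ifelse(is.na(vx$mean_pos_weight), 0, vx$mean_pos_weight),
    negative = ifelse(is.na(vx$mean_neg_weight), 0, vx$mean_neg_weight))
  idx <- cbind(voxel_index$i + 1L, voxel_index$j + 1L, voxel_index$k + 1L)
  vol[idx[keep, , drop = FALSE]] <- val[keep]
  vol
}

#' Write a selection summary to TSV tables
#'
#' @param summary a [summarize_selection()] result.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_selection_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vp <- file.path(dir, "voxel_selection.tsv")
  ap <- file.path(dir, "area_selection.tsv")
  utils::write.table(summary$voxel, vp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary$area, ap, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(voxel = vp, area = ap))
}
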