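#' Subjects-by-voxels feature matrix
#'
#' The central data container: an `n x d` matrix of per-voxel Z-scores with
#' class labels in \{-1, +1\} (+1 = patient), subject identifiers, and a
#' per-column `voxel_index` mapping each feature back to its atlas area,
#' 0-based volume coordinate `(i, j, k)` and task of origin. The index
#' survives every cleaning step so any fitted weight can be written back
#' into volume space. Cleaning/normalization provenance accumulates in
#' `$meta`.
#'
#' @param values numeric n x d matrix.
#' @param labels length-n vector of -1/+1.
#' @param subject_ids length-n character ids.
#' @param voxel_index data.frame with columns `voxel`, `area`, `i`, `j`, `k`,
#'   `task` (one row per column of `values`).
#' @param meta list of provenance records.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, subject_ids = NULL,
                           voxel_index = NULL, meta = list()) {
  values <- as.matrix(values)
  labels <- as.integer(labels)
  n <- nrow(values); d <- ncol(values)
  if (length(labels) != n) stopf("need one label per row (%d vs %d)", length(labels), n)
  if (!all(labels %in% c(-1L, 1L))) stopf("labels must be -1 or +1")
  subject_ids <- subject_ids %||% sprintf("s%03d", seq_len(n))
  if (length(subject_ids) != n) stopf("need one subject_id per row")
  if (is.null(voxel_index)) {
    voxel_index <- data.frame(voxel = sprintf("v%05d", seq_len(d)),
                              area = rep(1L, d), i = 0L, j = 0L, k = 0L,
                              task = "unspecified", stringsAsFactors = FALSE)
  }
  if (nrow(voxel_index) != d) stopf("voxel_index must have one row per column")
  rownames(values) <- subject_ids
  colnames(values) <- voxel_index$voxel
  structure(list(values = values, labels = labels, subject_ids = subject_ids,
                 voxel_index = voxel_index, meta = meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d subjects x %d voxels (%d patients, %d controls)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1), sum(x$labels == -1)))
  cat(sprintf("tasks: %s; areas represented: %d\n",
              paste(unique(x$voxel_index$task), collapse = ", "),
              length(unique(x$voxel_index$area))))
  if (length(x$meta)) cat("meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Assemble a feature matrix from per-subject volumes
#'
#' Vectorizes each subject volume and stacks them into a subjects x voxels
#' matrix, restricted to voxels with a nonzero atlas label (unlabeled voxels
#' are excluded from analysis). Volumes may be 3D arrays or NIfTI file paths.
#'
#' @param zmaps list of 3D numeric arrays or character paths to NIfTI files,
#'   one per subject, all matching the atlas shape.
#' @param atlas integer label volume (0 = unlabeled) or NIfTI path.
#' @param labels -1/+1 class label per subject.
#' @param subject_ids optional subject identifiers.
#' @param task_tag dataset-of-origin tag for all columns.
#' @return a [feature_matrix()].
#' @export
assemble <- function(zmaps, atlas, labels, subject_ids = NULL,
                     task_tag = "task") {
  if (is.character(atlas)) atlas <- as.array(RNifti::readNifti(atlas))
  atlas <- round(as.array(atlas))
  storage.mode(atlas) <- "integer"
  gs <- dim(atlas)
  vols <- lapply(zmaps, function(z) {
    if (is.character(z)) z <- as.array(RNifti::readNifti(z))
    z <- as.array(z)
    if (!identical(dim(z), gs))
      stopf("volume shape (%s) does not match atlas (%s)",
            paste(dim(z), collapse = "x"), paste(gs, collapse = "x"))
    as.vector(z)
  })
  n <- length(vols)
  if (length(labels) != n) stopf("need one label per subject volume")
  keep <- which(as.vector(atlas) > 0L)
  X <- do.call(rbind, lapply(vols, `[`, keep))
  coords <- arrayInd(keep, gs)
  vi <- data.frame(voxel = sprintf("%s_v%05d", task_tag, keep),
                   area = as.vector(atlas)[keep],
                   i = coords[, 1] - 1L, j = coords[, 2] - 1L,
                   k = coords[, 3] - 1L, task = task_tag,
                   stringsAsFactors = FALSE)
  feature_matrix(X, labels, subject_ids, vi,
                 meta = list(assemble = list(n_voxels_total = prod(gs),
                                             n_unlabeled_dropped = prod(gs) - length(keep))))
}

#' Remove voxels containing outlier Z-scores
#'
#' Z-scores exceeding `threshold` in absolute value are treated as outliers
#' and the whole voxel (column) is discarded for all subjects, keeping the
#' matrix rectangular. The removal report (dropped voxel ids, offending entry
#' count) is stored in `$meta$outliers`.
#'
#' @param fm a [feature_matrix()].
#' @param threshold positive Z magnitude; default 5.
#' @return the filtered `feature_matrix`.
#' @export
filter_outliers <- function(fm, threshold = 5) {
  stopifnot(inherits(fm, "feature_matrix"), threshold > 0)
  bad_entries <- abs(fm$values) > threshold
  bad_cols <- which(colSums(bad_entries) > 0L)
  report <- list(threshold = threshold,
                 n_dropped_voxels = length(bad_cols),
                 n_offending_entries = sum(bad_entries),
                 dropped_voxels = fm$voxel_index$voxel[bad_cols])
  if (length(bad_cols)) {
    fm$values <- fm$values[, -bad_cols, drop = FALSE]
    fm$voxel_index <- fm$voxel_index[-bad_cols, , drop = FALSE]
  }
  fm$meta$outliers <- report
  fm
}

#' Remove voxels that are zero for all subjects
#'
#' @param fm a [feature_matrix()].
#' @return the filtered `feature_matrix`, with the count recorded in
#'   `$meta$zero_columns`.
#' @export
drop_zero_columns <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  zero <- which(colSums(fm$values != 0) == 0L)
  if (length(zero)) {
    fm$values <- fm$values[, -zero, drop = FALSE]
    fm$voxel_index <- fm$voxel_index[-zero, , drop = FALSE]
  }
  fm$meta$zero_columns <- list(n_dropped = length(zero))
  fm
}

#' Voxel-wise standardization
#'
#' Standardizes each column to mean 0, SD 1 using the sample SD (n-1
#' denominator). `mode = "paper"` computes statistics over all subjects (the
#' study's choice; note this leaks test-set statistics into training when
#' followed by cross-validation); `mode = "train-only"` computes them on the
#' rows in `train_idx` and applies them to all rows. Zero-variance columns
#' are dropped with a warning. Per-voxel statistics and the mode are recorded
#' in `$meta$normalization`.
#'
#' @param fm a [feature_matrix()].
#' @param mode `"paper"` or `"train-only"`.
#' @param train_idx row indices defining the training subset (train-only mode).
#' @return the standardized `feature_matrix`.
#' @export
normalize_voxelwise <- function(fm, mode = c("paper", "train-only"),
                                train_idx = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  mode <- match.arg(mode)
  if (nrow(fm$values) < 2L) stopf("need at least 2 subjects to standardize")
  rows <- if (mode == "train-only") {
    if (is.null(train_idx)) stopf("train-only mode requires train_idx")
    train_idx
  } else seq_len(nrow(fm$values))
  mu <- colMeans(fm$values[rows, , drop = FALSE])
  sdv <- apply(fm$values[rows, , drop = FALSE], 2, sd)
  degenerate <- which(sdv == 0)
  if (length(degenerate)) {
    warning(sprintf("dropping %d zero-variance voxel(s)", length(degenerate)))
    fm$values <- fm$values[, -degenerate, drop = FALSE]
    fm$voxel_index <- fm$voxel_index[-degenerate, , drop = FALSE]
    mu <- mu[-degenerate]; sdv <- sdv[-degenerate]
  }
  fm$values <- sweep(sweep(fm$values, 2, mu), 2, sdv, "/")
  fm$meta$normalization <- list(mode = mode, sd_convention = "sample (n-1)",
                                mean = unname(mu), sd = unname(sdv),
                                n_zero_variance_dropped = length(degenerate))
  fm
}

#' Concatenate two tasks' feature matrices column-wise
#'
#' Appends the columns of `fm_b` to `fm_a` for the same subjects (the
#' two-task "combined" design). Groups of the second task are offset past
#' the first task's groups, so the same anatomical area in different tasks
#' forms distinct groups (105 areas per task give 210 groups).
#'
#' @param fm_a,fm_b feature matrices with identical subjects and labels.
#' @return list with the combined `features` and the combined `groups`
#'   ([group_structure]).
#' @export
concat_tasks <- function(fm_a, fm_b) {
  stopifnot(inherits(fm_a, "feature_matrix"), inherits(fm_b, "feature_matrix"))
  if (ncol(fm_b$values) == 0L)
    return(list(features = fm_a, groups = build_groups(fm_a)))
  if (!identical(fm_a$labels, fm_b$labels) ||
      !identical(fm_a$subject_ids, fm_b$subject_ids))
    stopf("subjects/labels of the two tasks do not match")
  if (identical(unique(fm_a$voxel_index$task), unique(fm_b$voxel_index$task)))
    fm_b$voxel_index$task <- paste0(fm_b$voxel_index$task, ".2")
  fm <- feature_matrix(cbind(fm_a$values, fm_b$values), fm_a$labels,
                       fm_a$subject_ids,
                       rbind(fm_a$voxel_index, fm_b$voxel_index),
                       meta = list(concat = list(d_a = ncol(fm_a$values),
                                                 d_b = ncol(fm_b$values))))
  ga <- build_groups(fm_a); gb <- build_groups(fm_b)
  groups <- group_structure(c(ga$membership, gb$membership + ga$n_groups),
                            c(ga$group_names, gb$group_names))
  list(features = fm, groups = groups)
}

#' Partition of features into groups (atlas areas)
#'
#' @param membership integer vector assigning each feature to a group in
#'   `1..n_groups`; every group must be nonempty.
#' @param group_names optional names, one per group.
#' @return object of class `group_structure` with fields `n_groups`,
#'   `membership`, `group_names`.
#' @export
group_structure <- function(membership, group_names = NULL) {
  membership <- as.integer(membership)
  if (anyNA(membership) || any(membership < 1L))
    stopf("membership must be positive integers")
  G <- max(membership)
  if (!all(seq_len(G) %in% membership)) stopf("every group must be nonempty")
  group_names <- group_names %||% sprintf("group%03d", seq_len(G))
  if (length(group_names) != G) stopf("need one name per group")
  structure(list(n_groups = G, membership = membership,
                 group_names = group_names), class = "group_structure")
}

#' @export
print.group_structure <- function(x, ...) {
  cat(sprintf("group_structure: %d features in %d groups (sizes %s)\n",
              length(x$membership), x$n_groups,
              paste(range(tabulate(x$membership)), collapse = "-")))
  invisible(x)
}

#' Build the group structure from a feature matrix's atlas labels
#'
#' One group per distinct (task, atlas area) pair present among surviving
#' columns; areas wholly removed by earlier filters simply do not form
#' groups (their labels are reported in `$meta` of the result's attribute).
#'
#' @param fm a [feature_matrix()].
#' @return a [group_structure()]. Attribute `lost_areas` lists atlas labels
#'   present in no surviving column, per task, when `all_areas` is supplied.
#' @param all_areas optional integer vector of all atlas labels that existed
#'   before filtering, used to report lost areas.
#' @export
build_groups <- function(fm, all_areas = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  key <- paste(fm$voxel_index$task, fm$voxel_index$area, sep = ":")
  # group order: tasks in order of first appearance, areas ascending within
  ord <- order(match(fm$voxel_index$task, unique(fm$voxel_index$task)),
               fm$voxel_index$area)
  levels_key <- unique(key[ord])
  membership <- match(key, levels_key)
  gs <- group_structure(membership, levels_key)
  if (!is.null(all_areas)) {
    present <- unique(fm$voxel_index$area)
    attr(gs, "lost_areas") <- setdiff(all_areas, present)
  }
  gs
}

#' Run the full cleaning pipeline
#'
#' Fixed order: outlier filtering (|Z| > threshold), zero-column removal,
#' voxel-wise standardization, group construction. Assembly from volumes is
#' done beforehand with [assemble()] (or the matrix comes straight from the
#' generator). Re-running on its own output in `"paper"` mode is idempotent.
#'
#' @param fm a [feature_matrix()].
#' @param outlier_threshold Z magnitude above which a voxel is discarded.
#' @param mode normalization mode, see [normalize_voxelwise()].
#' @param train_idx training rows for `"train-only"` mode.
#' @return list with `features` (cleaned matrix) and `groups`.
#' @export
preprocess_pipeline <- function(fm, outlier_threshold = 5,
                                mode = "paper", train_idx = NULL) {
  all_areas <- unique(fm$voxel_index$area)
  fm <- filter_outliers(fm, outlier_threshold)
  fm <- drop_zero_columns(fm)
  fm <- normalize_voxelwise(fm, mode = mode, train_idx = train_idx)
  groups <- build_groups(fm, all_areas = all_areas)
  list(features = fm, groups = groups)
}

#' Write / read a feature matrix as TSV with JSON sidecar
#'
#' The TSV holds one row per subject: `subject_id`, `label`, then one column
#' per voxel. The sidecar (same path with extension `.json`) stores the
#' voxel index and accumulated provenance so the matrix can be round-tripped.
#'
#' @param fm a [feature_matrix()].
#' @param path TSV output path.
#' @return invisibly, `path`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(subject_id = fm$subject_ids, label = fm$labels,
                   fm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(voxel_index = fm$voxel_index, meta = fm$meta),
                       side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  vi <- NULL; meta <- list()
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    vi <- sc$voxel_index
    meta <- sc$meta %||% list()
  }
  feature_matrix(as.matrix(df[, -(1:2), drop = FALSE]), df$label,
                 df$subject_id, vi, meta = meta)
}
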