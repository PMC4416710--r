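#' Specification for a synthetic group-structured activation dataset
#'
#' Defines the conditions under which a toy contrast-map cohort is simulated:
#' a cuboid pseudo-atlas partitions the volume into areas, a subset of areas
#' carries a class effect (patients minus controls), the effect pattern is
#' translated by a small per-subject spatial jitter, spatially smooth Gaussian
#' noise is added to every subject, and a fraction of entries is replaced by
#' large-magnitude outliers (|Z| > 5) mimicking artefactual voxels.
#'
#' Defaults emulate a depression-classification cohort at reduced scale:
#' 62 subjects (31 per class), a 10x10x6 volume (600 voxels) partitioned
#' into 75 areas of 2x2x2 voxels, 6 affected areas, an effect of 1.5 Z
#' units against unit-SD noise with correlation length half the area width,
#' and 1-voxel spatial jitter. Area width equals twice the jitter, so every
#' affected voxel is unstable across subjects while the affected areas
#' remain informative — the regime in which group penalties are expected to
#' be more robust than voxel-wise selection.
#'
#' @param grid_shape integer(3), extents of the toy volume in voxels.
#' @param n_areas number of cuboid pseudo-atlas areas.
#' @param n_per_class subjects per class (controls = -1, patients = +1).
#' @param active_areas integer indices (in 1..n_areas) of areas carrying the
#'   class effect.
#' @param effect_size mean Z-score difference, patients minus controls, added
#'   to active-area voxels.
#' @param smooth_sigma Gaussian correlation length of the noise field, in
#'   voxels; 0 disables smoothing.
#' @param jitter_max maximum per-subject integer translation (voxels) of the
#'   activation pattern, drawn uniformly from \[-jitter_max, jitter_max\]^3.
#' @param noise_sd marginal SD of the additive noise field, in Z units.
#' @param outlier_rate fraction of matrix entries replaced by values of
#'   magnitude in (5.5, 8) with random sign.
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(grid_shape = c(10L, 10L, 6L), n_areas = 75L,
                       n_per_class = 31L, active_areas = 1:6,
                       effect_size = 1.5, smooth_sigma = 0.5,
                       jitter_max = 1L, noise_sd = 1,
                       outlier_rate = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stopf("grid_shape must be three positive integers")
  if (n_areas < 1L || n_areas > prod(grid_shape))
    stopf("n_areas must be in 1..%d (voxel count)", prod(grid_shape))
  if (n_per_class < 2L) stopf("n_per_class must be >= 2")
  active_areas <- as.integer(active_areas)
  if (length(active_areas) && (any(active_areas < 1L) || any(active_areas > n_areas)))
    stopf("active_areas must be a subset of 1..n_areas")
  if (outlier_rate < 0 || outlier_rate > 1) stopf("outlier_rate must be in [0,1]")
  if (jitter_max < 0) stopf("jitter_max must be >= 0")
  if (noise_sd < 0 || smooth_sigma < 0) stopf("noise_sd and smooth_sigma must be >= 0")
  structure(list(grid_shape = grid_shape, n_areas = as.integer(n_areas),
                 n_per_class = as.integer(n_per_class),
                 active_areas = active_areas, effect_size = effect_size,
                 smooth_sigma = smooth_sigma, jitter_max = as.integer(jitter_max),
                 noise_sd = noise_sd, outlier_rate = outlier_rate,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Build a cuboid pseudo-atlas label volume
#'
#' Partitions the volume into `n_areas` contiguous cuboids by factoring
#' `n_areas` into three per-axis slab counts whose cells are as close to
#' cubic as the grid permits, then splitting each axis into nearly equal
#' contiguous slabs. Every voxel receives exactly one label in 1..n_areas.
#' This stands in for an anatomical parcellation such as AAL.
#'
#' @param spec a [synth_spec()].
#' @return integer 3D array of area labels.
#' @export
make_atlas <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  gs <- spec$grid_shape
  na <- spec$n_areas
  # all ordered factor triples (f1,f2,f3) with product na and f_i <= gs_i
  triples <- list()
  for (f1 in seq_len(na)) {
    if (na %% f1 != 0L || f1 > gs[1]) next
    r <- na %/% f1
    for (f2 in seq_len(r)) {
      if (r %% f2 != 0L || f2 > gs[2]) next
      f3 <- r %/% f2
      if (f3 > gs[3]) next
      triples[[length(triples) + 1L]] <- c(f1, f2, f3)
    }
  }
  if (!length(triples))
    stopf("cannot partition grid %s into %d cuboid areas",
          paste(gs, collapse = "x"), na)
  # prefer near-cubic cells: minimize max/min cell extent ratio
  score <- vapply(triples, function(f) {
    cell <- gs / f
    max(cell) / min(cell)
  }, numeric(1))
  f <- triples[[which.min(score)]]
  slab <- function(extent, k) {
    sizes <- rep(extent %/% k, k)
    extra <- extent %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    rep(seq_len(k), times = sizes)
  }
  ix <- slab(gs[1], f[1]); iy <- slab(gs[2], f[2]); iz <- slab(gs[3], f[3])
  lab <- array(0L, dim = gs)
  for (z in seq_len(gs[3])) for (y in seq_len(gs[2]))
    lab[, y, z] <- (iz[z] - 1L) * f[1] * f[2] + (iy[y] - 1L) * f[1] + ix
  storage.mode(lab) <- "integer"
  lab
}

# circular shift of a 3D logical/numeric array by integer offsets
circshift3 <- function(a, shift) {
  d <- dim(a)
  idx <- lapply(1:3, function(k) ((seq_len(d[k]) - 1L - shift[k]) %% d[k]) + 1L)
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# FFT-based circular Gaussian smoothing of a 3D field; the returned field has
# the same marginal variance as the input when the input is white noise.
gauss_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  ker1 <- lapply(d, function(n) {
    x <- seq_len(n) - 1L
    dist <- pmin(x, n - x)
    exp(-dist^2 / (2 * sigma^2))
  })
  ker <- outer(outer(ker1[[1]], ker1[[2]]), ker1[[3]])
  dim(ker) <- d
  ker <- ker / sum(ker)
  sm <- Re(fft(fft(a) * fft(ker), inverse = TRUE)) / prod(d)
  sm / sqrt(sum(ker^2))  # restore unit marginal SD for white-noise input
}

#' Generate a synthetic group-structured dataset
#'
#' Simulates `2 * n_per_class` contrast maps: per-subject spatially smooth
#' Gaussian noise; patients additionally receive `effect_size` on the
#' active-area mask, circularly translated by a per-subject uniform integer
#' jitter; finally a fraction `outlier_rate` of entries is replaced by
#' outliers of magnitude in (5.5, 8). Controls come first (label -1), then
#' patients (+1). Output is bit-reproducible given the spec (including seed).
#'
#' @param spec a [synth_spec()].
#' @param task_tag tag stored per feature column (dataset origin).
#' @return An object of class `synth_dataset`: list with `features` (a
#'   [feature_matrix()]), `atlas` (integer label volume), and `truth`
#'   (list of truly discriminative `areas` and `voxels`, column indices).
#' @export
generate_synth <- function(spec, task_tag = "synthetic-A") {
  stopifnot(inherits(spec, "synth_spec"))
  atlas <- make_atlas(spec)
  gs <- spec$grid_shape
  V <- prod(gs)
  n <- 2L * spec$n_per_class
  labels <- rep(c(-1L, 1L), each = spec$n_per_class)
  subject_ids <- c(sprintf("ctrl%03d", seq_len(spec$n_per_class)),
                   sprintf("pat%03d", seq_len(spec$n_per_class)))
  mask <- array(atlas %in% spec$active_areas, dim = gs)
  X <- matrix(0, n, V)
  with_seed(spec$seed, {
    for (i in seq_len(n)) {
      noise <- array(rnorm(V), dim = gs)
      noise <- gauss_smooth3(noise, spec$smooth_sigma) * spec$noise_sd
      vol <- noise
      if (labels[i] == 1L) {
        shift <- if (spec$jitter_max > 0)
          sample(seq(-spec$jitter_max, spec$jitter_max), 3L, replace = TRUE)
        else c(0L, 0L, 0L)
        vol <- vol + spec$effect_size * circshift3(mask, shift)
      }
      X[i, ] <- as.vector(vol)
    }
    if (spec$outlier_rate > 0) {
      hit <- which(matrix(runif(n * V), n, V) < spec$outlier_rate)
      if (length(hit)) {
        mag <- runif(length(hit), 5.5, 8)
        sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
        X[hit] <- sgn * mag
      }
    }
  })
  coords <- arrayInd(seq_len(V), gs)
  vi <- data.frame(voxel = sprintf("%s_v%05d", task_tag, seq_len(V)),
                   area = as.vector(atlas),
                   i = coords[, 1] - 1L, j = coords[, 2] - 1L,
                   k = coords[, 3] - 1L,
                   task = task_tag, stringsAsFactors = FALSE)
  keep <- vi$area > 0L
  fm <- feature_matrix(X[, keep, drop = FALSE], labels, subject_ids,
                       vi[keep, , drop = FALSE])
  truth_vox <- which(as.vector(mask)[keep])
  structure(list(features = fm, atlas = atlas,
                 truth = list(areas = sort(spec$active_areas),
                              voxels = truth_vox),
                 spec = spec),
            class = "synth_dataset")
}

#' Generate two independent synthetic tasks with shared labels
#'
#' Emulates a two-task design (e.g. semantic and phonological runs of the
#' same cohort): two datasets are drawn independently but share subjects and
#' labels, and their feature matrices are concatenated column-wise so the
#' same pseudo-anatomical area appears as a distinct group per task.
#'
#' @param spec_a,spec_b specs for the two tasks; must agree in `n_per_class`.
#' @return list with `features` (combined [feature_matrix()]), `groups`
#'   (combined [group_structure]), the two component datasets, and pooled
#'   `truth` (per-task area/voxel indices).
#' @export
generate_synth_pair <- function(spec_a, spec_b = NULL) {
  if (is.null(spec_b)) {
    spec_b <- spec_a
    spec_b$seed <- derive_seed(spec_a$seed, 2L)
  }
  if (spec_a$n_per_class != spec_b$n_per_class)
    stopf("both specs must have the same n_per_class")
  a <- generate_synth(spec_a, task_tag = "synthetic-A")
  b <- generate_synth(spec_b, task_tag = "synthetic-B")
  b$features$labels <- a$features$labels
  b$features$subject_ids <- a$features$subject_ids
  cc <- concat_tasks(a$features, b$features)
  list(features = cc$features, groups = cc$groups, task_a = a, task_b = b,
       truth = list(areas_a = a$truth$areas, areas_b = b$truth$areas))
}

#' Write a synthetic dataset to disk
#'
#' Writes the atlas as integer NIfTI, the feature matrix as TSV (rows =
#' subjects; first two columns `subject_id`, `label`; remaining columns
#' named by voxel id), and a JSON sidecar with the generating spec and the
#' ground-truth support.
#'
#' @param dataset a `synth_dataset` from [generate_synth()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_synth <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atlas_path <- file.path(dir, "atlas.nii.gz")
  RNifti::writeNifti(dataset$atlas, atlas_path, datatype = "int16")
  feat_path <- file.path(dir, "features.tsv")
  write_feature_matrix(dataset$features, feat_path)
  side_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(spec = unclass(dataset$spec), truth = dataset$truth),
    side_path, auto_unbox = TRUE, digits = NA)
  invisible(c(atlas = atlas_path, features = feat_path, sidecar = side_path))
}
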