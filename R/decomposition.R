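# 3D-to-2D decomposition: RGB-like images built from three MRI slices, so
# that 3-channel 2D classifiers can read volumetric data. Four schemes:
#   A: R/G/B = sagittal slices n, n+gap, n+2*gap
#   B: coronal, same indices
#   C: transaxial, same indices
#   D: R = sagittal(n), G = coronal(n+gap), B = transaxial(n+2*gap)
# Slice indices are 0-based internally; user-facing n is 1-based.

.orient_axis <- c(sagittal = 1L, coronal = 2L, transaxial = 3L)

#' Decomposition configuration
#'
#' @param approach One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param gap Non-negative slice-index distance between the three bands
#'   (gap 1 means adjacent slices).
#' @param stride Step between consecutive anchor slices. Default: 1 when
#'   `gap = 0`, otherwise `2 * gap + 1` so consecutive RGB-like images use
#'   non-overlapping slice triplets.
#' @param n_start First anchor slice, 1-based (default 1: the first slice).
#' @param scale Per-volume min-max scaling of intensities to `[0, 1]` before
#'   composition (default `TRUE`), so backends see bounded inputs.
#' @return A `decomp_config` list.
#' @export
decomp_config <- function(approach = "A", gap = 0L, stride = NULL,
                          n_start = 1L, scale = TRUE) {
  approach <- match.arg(toupper(approach), c("A", "B", "C", "D"))
  gap <- as.integer(gap)
  if (gap < 0L) stop("gap must be non-negative")
  if (is.null(stride)) stride <- if (gap == 0L) 1L else 2L * gap + 1L
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  n_start <- as.integer(n_start)
  if (n_start < 1L) stop("n_start is 1-based and must be >= 1")
  structure(list(approach = approach, gap = gap, stride = stride,
                 n_start = n_start, scale = isTRUE(scale)),
            class = "decomp_config")
}

#' Extract a single anatomical slice
#'
#' @param v An [mri_volume()].
#' @param orientation `"sagittal"`, `"coronal"` or `"transaxial"`.
#' @param index Slice index, 1-based.
#' @return A 2D numeric matrix (the plane at that index).
#' @export
extract_slice <- function(v, orientation = c("sagittal", "coronal",
                                             "transaxial"), index) {
  stopifnot(inherits(v, "mri_volume"))
  orientation <- match.arg(orientation)
  ax <- .orient_axis[[orientation]]
  index <- as.integer(index)
  if (index < 1L || index > v$shape[ax])
    stop("slice index ", index, " out of range 1..", v$shape[ax],
         " for ", orientation)
  switch(ax,
         v$voxels[index, , ],
         v$voxels[, index, ],
         v$voxels[, , index])
}

.axes_used <- function(approach) {
  switch(approach,
         A = c(1L, 1L, 1L), B = c(2L, 2L, 2L), C = c(3L, 3L, 3L),
         D = c(1L, 2L, 3L))
}

.pad_to <- function(m, target) {
  if (all(dim(m) == target)) return(m)
  out <- matrix(0, target[1], target[2])
  off <- (target - dim(m)) %/% 2L
  out[off[1] + seq_len(nrow(m)), off[2] + seq_len(ncol(m))] <- m
  out
}

#' Compose one RGB-like image from a volume
#'
#' Stacks three slices as the R, G and B bands per the configured approach.
#' The band slice indices are `n`, `n + gap`, `n + 2 * gap` (1-based). With
#' `gap = 0` the three bands of approaches A-C are identical. For approach D
#' on non-cubic volumes the three planes differ in shape; bands are
#' zero-padded symmetrically to the element-wise maximum shape (a no-op on
#' cubic volumes).
#'
#' @param v An [mri_volume()].
#' @param cfg A [decomp_config()].
#' @param n Anchor slice index, 1-based.
#' @return An `rgb_like` list: `bands` (array height x width x 3),
#'   `approach`, `gap`, `n`, `subject_id`, `key`.
#' @export
compose_rgb <- function(v, cfg, n) {
  stopifnot(inherits(v, "mri_volume"), inherits(cfg, "decomp_config"))
  n <- as.integer(n)
  axes <- .axes_used(cfg$approach)
  idx <- n + c(0L, cfg$gap, 2L * cfg$gap)
  for (b in 1:3)
    if (idx[b] < 1L || idx[b] > v$shape[axes[b]])
      stop("band slice index ", idx[b], " out of range on axis ", axes[b],
           " (approach ", cfg$approach, ", gap ", cfg$gap, ", n ", n, ")")
  vox <- v$voxels
  if (cfg$scale) {
    rng <- range(vox)
    vox <- if (rng[2] > rng[1]) (vox - rng[1]) / (rng[2] - rng[1])
           else array(0, dim = dim(vox))
  }
  vv <- v; vv$voxels <- vox
  ors <- names(.orient_axis)[axes]
  bands <- Map(function(o, i) extract_slice(vv, o, i), ors, as.list(idx))
  target <- c(max(vapply(bands, nrow, 1L)), max(vapply(bands, ncol, 1L)))
  bands <- lapply(bands, .pad_to, target = target)
  arr <- array(0, dim = c(target, 3L))
  for (b in 1:3) arr[, , b] <- bands[[b]]
  structure(list(bands = arr, approach = cfg$approach, gap = cfg$gap, n = n,
                 subject_id = v$subject_id,
                 key = sprintf("%s|g%d|n%03d", cfg$approach, cfg$gap, n)),
            class = "rgb_like")
}

#' Anchor slice indices for a decomposition
#'
#' The anchors depend only on the volume shape and `(gap, stride, n_start)`,
#' never on voxel content: n runs from `n_start` in steps of `stride` while
#' every band index `n + 2 * gap` stays within range on every axis the
#' approach uses.
#'
#' @param shape Integer triple.
#' @param cfg A [decomp_config()].
#' @return Integer vector of valid 1-based anchors (possibly empty).
#' @export
decomp_anchors <- function(shape, cfg) {
  axes <- .axes_used(cfg$approach)
  # band b = n + (b-1)*gap must fit the axis it is drawn from
  lim <- min(vapply(1:3, function(b)
    as.integer(shape[axes[b]]) - (b - 1L) * cfg$gap, integer(1)))
  if (lim < cfg$n_start) return(integer(0))
  seq.int(cfg$n_start, lim, by = cfg$stride)
}

#' Decompose a volume into RGB-like images
#'
#' @param v An [mri_volume()].
#' @param cfg A [decomp_config()].
#' @return List of [compose_rgb()] images ordered by anchor `n`. An error is
#'   raised if the volume is too small for a single image.
#' @export
decompose_volume <- function(v, cfg) {
  anchors <- decomp_anchors(v$shape, cfg)
  if (length(anchors) == 0L)
    stop("volume too small for approach ", cfg$approach, " with gap ",
         cfg$gap, ": no valid anchors")
  if (cfg$scale) {                     # scale once per volume, not per image
    rng <- range(v$voxels)
    v$voxels <- if (rng[2] > rng[1]) (v$voxels - rng[1]) / (rng[2] - rng[1])
                else array(0, dim = v$shape)
    cfg$scale <- FALSE
  }
  lapply(anchors, function(n) compose_rgb(v, cfg, n))
}

#' Group a cohort's RGB-like images by slice key
#'
#' Per-slice models are trained only on images of different subjects centered
#' on the same slice (same `(approach, gap, n)` key): co-registration makes
#' those images anatomically comparable. This helper partitions a cohort's
#' images accordingly.
#'
#' @param images List of `rgb_like` images spanning a cohort.
#' @return Named list mapping each key to the list of per-subject images.
#'   Errors if two images under one key have different shapes, or if a
#'   subject appears twice under one key.
#' @export
group_by_slice <- function(images) {
  keys <- vapply(images, function(im) im$key, character(1))
  groups <- split(images, factor(keys, levels = unique(keys)))
  for (g in groups) {
    subj <- vapply(g, function(im) im$subject_id, character(1))
    if (anyDuplicated(subj))
      stop("duplicate subject within slice group ", g[[1]]$key)
    shp <- vapply(g, function(im) dim(im$bands), integer(3))
    if (any(shp != shp[, 1]))
      stop("image shape mismatch within slice group ", g[[1]]$key,
           " (cohort volumes not co-registered?)")
  }
  groups
}

#' Decompose an entire cohort and group by slice
#'
#' @param cohort Cohort list (see [read_cohort()]).
#' @param cfg A [decomp_config()].
#' @return As [group_by_slice()], with one image per subject in every group.
#' @export
decompose_cohort <- function(cohort, cfg) {
  imgs <- unlist(lapply(cohort$volumes, decompose_volume, cfg = cfg),
                 recursive = FALSE)
  group_by_slice(imgs)
}
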