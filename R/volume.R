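#' Construct an MRI volume object
#'
#' A `mri_volume` is the unit of input throughout the package: a 3D voxel
#' grid (gray-matter probability or intensity) with axis-orientation
#' metadata. Axis 1 is sagittal (left-right), axis 2 coronal
#' (posterior-anterior), axis 3 transaxial (inferior-superior), assuming
#' RAS-ordered, already co-registered volumes.
#'
#' @param voxels Numeric 3D array; all values must be finite.
#' @param subject_id Subject identifier string.
#' @param label Optional binary class tag (`NA`, 0 or 1, or a class name).
#' @param space_tag String identifying the common registration space.
#'   Volumes in one cohort must share shape and `space_tag` for slice-wise
#'   analyses to be anatomically meaningful.
#' @return An object of class `mri_volume` with fields `voxels`, `shape`,
#'   `subject_id`, `label`, `space_tag`.
#' @export
mri_volume <- function(voxels, subject_id = "subj", label = NA,
                       space_tag = "MNI152") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array, got ",
         if (is.array(voxels)) paste0(length(dim(voxels)), "-D") else class(voxels)[1])
  if (any(dim(voxels) < 1L)) stop("all three extents must be >= 1")
  if (!all(is.finite(voxels)))
    stop("voxel values must be finite (NaN/Inf rejected)")
  storage.mode(voxels) <- "double"
  structure(
    list(voxels = voxels, shape = dim(voxels),
         subject_id = as.character(subject_id), label = label,
         space_tag = as.character(space_tag)),
    class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<mri_volume> %s  %d x %d x %d  space=%s  label=%s\n",
              x$subject_id, x$shape[1], x$shape[2], x$shape[3],
              x$space_tag, as.character(x$label)))
  invisible(x)
}

#' @export
dim.mri_volume <- function(x) x$shape

#' Read a volume from a NIfTI-1 file
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`), validates that it
#' is a finite 3D grid, and returns a [mri_volume()]. The header `descrip`
#' field, when set by [write_volume()], carries the registration-space tag.
#' Trailing singleton dimensions (e.g. a degenerate 4th time axis of length
#' 1) are dropped; genuinely 2D or 4D data are rejected.
#'
#' @param path Path to the NIfTI-1 file.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @param label Optional class tag attached to the volume.
#' @return An [mri_volume()].
#' @export
read_volume <- function(path, subject_id = NULL, label = NA) {
  nii <- read_nifti(path)
  dd <- nii$dim                     # drop trailing singleton (e.g. time) dims

  while (length(dd) > 3L && dd[length(dd)] == 1L) dd <- dd[-length(dd)]
  if (length(dd) != 3L)
    stop("expected a 3-D volume, file has effective dimensionality ",
         length(dd), " (dims: ", paste(nii$dim, collapse = "x"), ")")
  vox <- array(nii$data, dim = dd)
  if (!all(is.finite(vox)))
    stop("volume contains non-finite voxels (NaN/Inf rejected): ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  tag <- if (nzchar(nii$descrip)) nii$descrip else "unknown"
  mri_volume(vox, subject_id = subject_id, label = label, space_tag = tag)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v An [mri_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "mri_volume"))
  write_nifti(v$voxels, path, descrip = v$space_tag)
  invisible(path)
}

#' Crop a volume to its central slices
#'
#' Reduces each axis to its `k` central indices, focusing the analysis on the
#' inner cerebral structures (including the hippocampal region). On each axis
#' the window starts at `floor((extent - k) / 2)` (0-based); when
#' `extent - k` is odd the extra voxel is dropped from the high-index side.
#' The standard post-registration 121 x 145 x 121 volume cropped to the 100
#' central slices yields a 100 x 100 x 100 volume.
#'
#' @param v An [mri_volume()].
#' @param k Number of central slices to keep on every axis (default 100).
#' @return A cropped [mri_volume()]; no interpolation is performed, the
#'   output is a contiguous sub-grid of the input.
#' @export
crop_inner <- function(v, k = 100L) {
  stopifnot(inherits(v, "mri_volume"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (any(v$shape < k))
    stop("k = ", k, " exceeds an axis extent (shape ",
         paste(v$shape, collapse = "x"), ")")
  start <- (v$shape - k) %/% 2L            # 0-based window start per axis
  idx <- lapply(start, function(s) seq.int(s + 1L, s + k))
  out <- v
  out$voxels <- v$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out$shape <- dim(out$voxels)
  out
}

#' Central-crop window mask
#'
#' Logical mask marking the `k`-central-slice window of [crop_inner()] inside
#' a volume of the given shape. Used by the synthetic generator to localize
#' class effects in the "inner" region.
#'
#' @param shape Integer triple.
#' @param k Central-slice count.
#' @return Logical 3D array of dimension `shape`.
#' @export
inner_mask <- function(shape, k = 100L) {
  k <- as.integer(k)
  if (any(shape < k)) stop("k exceeds an axis extent")
  start <- (as.integer(shape) - k) %/% 2L
  m <- array(FALSE, dim = shape)
  m[start[1] + seq_len(k), start[2] + seq_len(k), start[3] + seq_len(k)] <- TRUE
  m
}

#' Write a cohort manifest
#'
#' A manifest is a headered CSV with columns `subject_id,path,label` listing
#' the volumes of one classification task.
#'
#' @param entries Data frame with columns `subject_id`, `path`, `label`.
#' @param path Output CSV path.
#' @param task Character pair naming the two classes (attached as a comment
#'   is not portable, so the task is implied by the label set).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path, task = NULL) {
  stopifnot(all(c("subject_id", "path", "label") %in% names(entries)))
  if (anyDuplicated(entries$subject_id))
    stop("subject_ids must be unique in a manifest")
  utils::write.csv(entries[, c("subject_id", "path", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path Manifest CSV path.
#' @return Data frame with columns `subject_id`, `path`, `label`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns subject_id,path,label")
  if (anyDuplicated(m$subject_id)) stop("duplicate subject_id in manifest")
  if (length(unique(m$label)) != 2L)
    stop("manifest must contain exactly two classes, found: ",
         paste(unique(m$label), collapse = ", "))
  m
}

#' Load a cohort of co-registered volumes
#'
#' Reads every volume listed in a manifest, attaches labels, and enforces the
#' co-registration contract: all volumes must share shape and space tag.
#' Labels are recoded to 0/1 by sorted class-name order unless already 0/1.
#'
#' @param manifest Path to a manifest CSV, or a data frame as returned by
#'   [read_manifest()]. Relative volume paths are resolved against the
#'   manifest's directory.
#' @return A list with elements `volumes` (list of [mri_volume()]),
#'   `labels` (0/1 integer vector), `classes` (the two class names, class 0
#'   first), `subject_ids`.
#' @export
read_cohort <- function(manifest) {
  base <- "."
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  classes <- sort(unique(as.character(manifest$label)))
  if (length(classes) != 2L) stop("cohort must have exactly two classes")
  labels <- as.integer(as.character(manifest$label) == classes[2])
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$path), manifest$path,
                  file.path(base, manifest$path))
  vols <- Map(read_volume, paths, manifest$subject_id, labels)
  names(vols) <- manifest$subject_id
  shp <- vapply(vols, function(v) v$shape, integer(3))
  if (any(shp != shp[, 1]))
    stop("cohort volumes do not share a common shape (co-registration contract)")
  tags <- vapply(vols, function(v) v$space_tag, character(1))
  if (length(unique(tags)) != 1L)
    stop("cohort volumes do not share a common space tag: ",
         paste(unique(tags), collapse = ", "))
  list(volumes = unname(vols), labels = labels, classes = classes,
       subject_ids = manifest$subject_id)
}

#' Flatten a cohort's voxels into a feature matrix
#'
#' Produces the subjects x features matrix consumed by the feature-reduction
#' and SVM stages: one row per subject, one column per voxel in array order.
#'
#' @param cohort A cohort list as returned by [read_cohort()] or
#'   [make_cohort()].
#' @param crop_k Optional central-slice count; when non-`NULL` each volume is
#'   passed through [crop_inner()] first.
#' @return A `feature_matrix` list: `X` (subjects x D), `y` (0/1),
#'   `feature_ids` (voxel coordinate strings "i_j_k"), `subject_ids`.
#' @export
cohort_features <- function(cohort, crop_k = NULL) {
  vols <- cohort$volumes
  if (!is.null(crop_k)) vols <- lapply(vols, crop_inner, k = crop_k)
  shp <- vols[[1]]$shape
  X <- t(vapply(vols, function(v) as.numeric(v$voxels),
                numeric(prod(shp))))
  g <- expand.grid(i = seq_len(shp[1]), j = seq_len(shp[2]),
                   k = seq_len(shp[3]))
  ids <- paste(g$i, g$j, g$k, sep = "_")
  feature_matrix(X, cohort$labels, feature_ids = ids,
                 subject_ids = cohort$subject_ids)
}
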