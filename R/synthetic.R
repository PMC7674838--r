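# Synthetic brain-like cohorts: a smooth gray-matter-like template shared by
# all subjects (emulating co-registration to a common space), additive
# lightly-smoothed Gaussian subject noise, and a class-dependent localized
# intensity reduction emulating atrophy. The default effect region is the
# central-crop window, mirroring the clinical observation that the inner
# cerebral structures (hippocampus included) are affected earliest.

# Separable Gaussian smoothing with edge renormalization (dividing by the
# smoothed all-ones field), so the infinite-width limit tends to a constant.
gauss_smooth <- function(arr, width) {
  if (width <= 0) return(arr)
  r <- max(1L, ceiling(3 * width))
  kern <- stats::dnorm(seq(-r, r), sd = width)
  kern <- kern / sum(kern)
  sm1 <- function(a) {
    for (ax in 1:3) {
      out <- array(0, dim = dim(a))
      for (o in seq(-r, r)) {
        wgt <- kern[o + r + 1L]
        d <- dim(a)[ax]
        src <- intersect(seq_len(d), seq_len(d) - o)
        dst <- src + o
        if (length(src) == 0L) next
        if (ax == 1) { out[dst, , ] <- out[dst, , ] + wgt * a[src, , ] }
        else if (ax == 2) { out[, dst, ] <- out[, dst, ] + wgt * a[, src, ] }
        else { out[, , dst] <- out[, , dst] + wgt * a[, , src] }
      }
      a <- out
    }
    a
  }
  sm1(arr) / sm1(array(1, dim = dim(arr)))
}

#' Generate a smooth brain-like template volume
#'
#' Superposes randomly placed intensity blobs, smooths them, and rescales to
#' `[0, 1]`: a stand-in for a gray-matter probability map in a common
#' registration space. Deterministic per seed.
#'
#' @param shape Integer triple, every extent at least 8.
#' @param smooth Gaussian smoothing width in voxels (default 2).
#' @param n_blobs Number of blobs (default 25).
#' @param seed Integer seed.
#' @return An [mri_volume()] with `subject_id = "template"`.
#' @export
make_template <- function(shape = c(40L, 48L, 40L), smooth = 2, n_blobs = 25L,
                          seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape < 8L)) stop("every extent must be >= 8")
  arr <- with_seed(seed, {
    a <- array(0, dim = shape)
    centers <- cbind(sample.int(shape[1], n_blobs, replace = TRUE),
                     sample.int(shape[2], n_blobs, replace = TRUE),
                     sample.int(shape[3], n_blobs, replace = TRUE))
    amp <- stats::runif(n_blobs, 0.5, 1)
    a[centers] <- amp
    a
  })
  arr <- gauss_smooth(arr, smooth)
  rng <- range(arr)
  arr <- if (rng[2] > rng[1]) (arr - rng[1]) / (rng[2] - rng[1])
         else array(0.5, dim = shape)
  mri_volume(arr, subject_id = "template", space_tag = "synthetic-template")
}

#' Synthetic cohort specification
#'
#' @param shape Volume shape (default `c(40, 48, 40)` for speed; the
#'   full-resolution `c(121, 145, 121)` is supported).
#' @param n_per_class Subjects per class (>= 4; default 20).
#' @param d Fractional intensity reduction in the affected region for class 1
#'   (default 0.3; `d = 0` makes the classes exchangeable).
#' @param region `"inner"` (the central-crop window), `"uniform"` (whole
#'   volume), or a logical mask array of dimension `shape`.
#' @param inner_k Central-slice count defining the `"inner"` region; default
#'   `floor(min(shape) * 100 / 121)`, the same proportion as cropping a
#'   121-voxel axis to its 100 central slices.
#' @param noise_sd Additive Gaussian subject-noise sd (> 0; default 0.1).
#' @param noise_smooth Smoothing width applied to the noise field
#'   (default 0.5 voxels: light spatial correlation).
#' @param smooth Template smoothing width (default 2).
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(shape = c(40L, 48L, 40L), n_per_class = 20L, d = 0.3,
                       region = "inner", inner_k = NULL, noise_sd = 0.1,
                       noise_smooth = 0.5, smooth = 2, seed = 1L) {
  shape <- as.integer(shape)
  if (n_per_class < 4L) stop("n_per_class must be >= 4")
  if (d < 0) stop("d must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(inner_k)) inner_k <- max(1L, floor(min(shape) * 100 / 121))
  structure(list(shape = shape, n_per_class = as.integer(n_per_class), d = d,
                 region = region, inner_k = as.integer(inner_k),
                 noise_sd = noise_sd, noise_smooth = noise_smooth,
                 smooth = smooth, seed = as.integer(seed)),
            class = "synth_spec")
}

.effect_mask <- function(spec) {
  if (is.array(spec$region)) {
    stopifnot(identical(dim(spec$region), as.integer(spec$shape)))
    return(spec$region)
  }
  switch(spec$region,
         inner = inner_mask(spec$shape, spec$inner_k),
         uniform = array(TRUE, dim = spec$shape),
         stop("unknown region: ", spec$region))
}

#' Generate a synthetic labeled cohort
#'
#' Class 0 volumes are template + noise; class 1 volumes scale the affected
#' region's template intensities by `(1 - d)` before adding noise. All
#' volumes share shape and space tag, emulating co-registration.
#'
#' @param spec A [synth_spec()].
#' @param dir Optional directory: when given, volumes are written as
#'   NIfTI-1 (`.nii.gz`), plus `manifest.csv`, `mask.nii.gz` and
#'   `spec.json`.
#' @return A cohort list (`volumes`, `labels`, `classes`, `subject_ids`)
#'   with extra fields `mask` (affected-region logical array), `template`,
#'   `spec`, and (when written) `manifest_path`.
#' @export
make_cohort <- function(spec = synth_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  tpl <- make_template(spec$shape, smooth = spec$smooth, seed = spec$seed)
  mask <- .effect_mask(spec)
  tpl1 <- tpl$voxels
  tpl1[mask] <- tpl1[mask] * (1 - spec$d)
  n <- spec$n_per_class
  labels <- rep(c(0L, 1L), each = n)
  ids <- sprintf("sub-%03d", seq_len(2L * n))
  noise_seeds <- derive_seeds(spec$seed + 1L, 2L * n)
  volumes <- lapply(seq_len(2L * n), function(i) {
    base <- if (labels[i] == 0L) tpl$voxels else tpl1
    eps <- with_seed(noise_seeds[i],
                     array(stats::rnorm(prod(spec$shape), sd = spec$noise_sd),
                           dim = spec$shape))
    if (spec$noise_smooth > 0) eps <- gauss_smooth(eps, spec$noise_smooth)
    mri_volume(base + eps, subject_id = ids[i], label = labels[i],
               space_tag = "synthetic-MNI")
  })
  cohort <- list(volumes = volumes, labels = labels,
                 classes = c("class0", "class1"), subject_ids = ids,
                 mask = mask, template = tpl, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, paste0(ids, ".nii.gz"))
    for (i in seq_along(volumes)) write_volume(volumes[[i]], paths[i])
    write_nifti(array(as.numeric(mask), dim = spec$shape),
                file.path(dir, "mask.nii.gz"), descrip = "synthetic-MNI")
    man <- data.frame(subject_id = ids, path = paste0(ids, ".nii.gz"),
                      label = paste0("class", labels))
    write_manifest(man, file.path(dir, "manifest.csv"))
    jsonlite::write_json(unclass(spec)[c("shape", "n_per_class", "d",
                                         "inner_k", "noise_sd",
                                         "noise_smooth", "smooth", "seed")],
                         file.path(dir, "spec.json"), auto_unbox = TRUE)
    cohort$manifest_path <- file.path(dir, "manifest.csv")
  }
  cohort
}
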