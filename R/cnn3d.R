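# Patch-based 3D convolutional network trained from scratch. Volumes are
# tiled into non-overlapping patches (reference configuration 28 x 28 x 121
# with stride-4 convolution and pooling); every patch inherits its parent
# volume's label, one network is trained on all patches, and the per-volume
# score is the sum-rule merge of its patch scores.
#
# The layer sequence is fixed: convolution -> ReLU -> max-pooling ->
# fully-connected -> soft-max -> classification. The convolution is realized
# as a linear map on an im2col expansion of the patch (indices precomputed
# once per geometry), which makes forward and backward passes plain matrix
# algebra; training uses stochastic gradient descent with momentum.

#' 3D patch / CNN specification
#'
#' @param patch_shape Patch extents (default `c(28, 28, 121)`).
#' @param field Convolution receptive-field edge (default 3).
#' @param conv_stride,pool_stride Strides of the convolution and max-pooling
#'   (default 4, the reference configuration).
#' @param pool_window Max-pooling window edge, at most 3 (default 3).
#' @param filters Number of convolution filters (default 8, desk scale).
#' @param learning_rate Initial SGDM learning rate (default 1e-4).
#' @param momentum SGDM momentum (default 0.9).
#' @param minibatch Mini-batch size (default 30 patches).
#' @param epochs Training epochs cap (default 80; convergence is typically
#'   earlier).
#' @return A `patch3d_spec`.
#' @export
patch3d_spec <- function(patch_shape = c(28L, 28L, 121L), field = 3L,
                         conv_stride = 4L, pool_stride = 4L, pool_window = 3L,
                         filters = 8L, learning_rate = 1e-4, momentum = 0.9,
                         minibatch = 30L, epochs = 80L) {
  patch_shape <- as.integer(patch_shape)
  stopifnot(length(patch_shape) == 3L, all(patch_shape >= 1L))
  if (pool_window > 3L) stop("pooling window is capped at 3")
  structure(list(patch_shape = patch_shape, field = as.integer(field),
                 conv_stride = as.integer(conv_stride),
                 pool_stride = as.integer(pool_stride),
                 pool_window = as.integer(pool_window),
                 filters = as.integer(filters),
                 learning_rate = learning_rate, momentum = momentum,
                 minibatch = as.integer(minibatch),
                 epochs = as.integer(epochs)),
            class = "patch3d_spec")
}

#' Tile a volume into non-overlapping 3D patches
#'
#' The grid is anchored at the first voxel on each axis; the number of
#' patches is `prod(floor(extent / patch_extent))` and leftover margins
#' beyond the last full patch are dropped. A 121 x 145 x 121 volume with
#' 28 x 28 x 121 patches yields 4 * 5 * 1 = 20 patches.
#'
#' @param v An [mri_volume()] or a 3D array.
#' @param spec A [patch3d_spec()] (only `patch_shape` is used).
#' @return List of 3D arrays in grid order (axis 1 fastest).
#' @export
extract_patches_3d <- function(v, spec) {
  vox <- if (inherits(v, "mri_volume")) v$voxels else v
  shp <- dim(vox)
  ps <- spec$patch_shape
  if (any(ps > shp))
    stop("patch shape ", paste(ps, collapse = "x"),
         " exceeds volume shape ", paste(shp, collapse = "x"))
  counts <- shp %/% ps
  out <- vector("list", prod(counts))
  m <- 0L
  for (k in seq_len(counts[3])) for (j in seq_len(counts[2]))
    for (i in seq_len(counts[1])) {
      m <- m + 1L
      out[[m]] <- vox[(i - 1L) * ps[1] + seq_len(ps[1]),
                      (j - 1L) * ps[2] + seq_len(ps[2]),
                      (k - 1L) * ps[3] + seq_len(ps[3]), drop = FALSE]
    }
  out
}

# Precompute geometry: im2col indices for the convolution and grouping
# indices for the pooling, for one patch shape.
.cnn_geometry <- function(spec) {
  ps <- spec$patch_shape; f <- spec$field
  s <- spec$conv_stride; w <- spec$pool_window; q <- spec$pool_stride
  odim <- (ps - f) %/% s + 1L
  if (any(odim < 1L)) stop("receptive field does not fit the patch")
  off <- as.matrix(expand.grid(df = 0:(f - 1), dg = 0:(f - 1), dh = 0:(f - 1)))
  orig <- as.matrix(expand.grid(i = seq(0, by = s, length.out = odim[1]),
                                j = seq(0, by = s, length.out = odim[2]),
                                k = seq(0, by = s, length.out = odim[3])))
  n_out <- nrow(orig)
  lin <- function(i, j, k) 1L + i + ps[1] * (j + ps[2] * k)
  im2col <- matrix(0L, n_out, f^3)
  for (c0 in seq_len(f^3))
    im2col[, c0] <- lin(orig[, 1] + off[c0, 1], orig[, 2] + off[c0, 2],
                        orig[, 3] + off[c0, 3])
  w_eff <- pmin(rep(w, 3L), odim)     # shrink the window on short axes
  pdim <- (odim - w_eff) %/% q + 1L
  poff <- as.matrix(expand.grid(0:(w_eff[1] - 1), 0:(w_eff[2] - 1),
                                0:(w_eff[3] - 1)))
  porig <- as.matrix(expand.grid(i = seq(0, by = q, length.out = pdim[1]),
                                 j = seq(0, by = q, length.out = pdim[2]),
                                 k = seq(0, by = q, length.out = pdim[3])))
  olin <- function(i, j, k) 1L + i + odim[1] * (j + odim[2] * k)
  pool <- matrix(0L, nrow(porig), nrow(poff))
  for (c0 in seq_len(nrow(poff)))
    pool[, c0] <- olin(porig[, 1] + poff[c0, 1], porig[, 2] + poff[c0, 2],
                       porig[, 3] + poff[c0, 3])
  list(odim = odim, n_out = n_out, im2col = im2col, pool = pool,
       n_pool = nrow(porig))
}

.cnn_forward <- function(P, net, geo) {
  # P: n_out x f^3 im2col matrix of one patch
  Z <- P %*% net$Wc + matrix(net$bc, geo$n_out, length(net$bc), byrow = TRUE)
  A <- pmax(Z, 0)
  nf <- ncol(Z)
  pooled <- matrix(0, geo$n_pool, nf)
  arg <- matrix(0L, geo$n_pool, nf)
  for (fi in seq_len(nf)) {
    G <- matrix(A[geo$pool, fi], geo$n_pool, ncol(geo$pool))
    am <- max.col(G, ties.method = "first")
    arg[, fi] <- geo$pool[cbind(seq_len(geo$n_pool), am)]
    pooled[, fi] <- G[cbind(seq_len(geo$n_pool), am)]
  }
  feat <- as.numeric(pooled)
  logits <- as.numeric(crossprod(net$Wf, feat)) + net$bf
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  list(Z = Z, A = A, arg = arg, feat = feat, p = p)
}

.cnn_backward <- function(P, fw, y, net, geo) {
  dlogit <- fw$p
  dlogit[y + 1L] <- dlogit[y + 1L] - 1
  dWf <- outer(fw$feat, dlogit)
  dbf <- dlogit
  dfeat <- as.numeric(net$Wf %*% dlogit)
  nf <- ncol(net$Wc)
  dA <- matrix(0, geo$n_out, nf)
  dpool <- matrix(dfeat, geo$n_pool, nf)
  for (fi in seq_len(nf))
    dA[fw$arg[, fi], fi] <- dA[fw$arg[, fi], fi] + dpool[, fi]
  dZ <- dA * (fw$Z > 0)
  list(dWc = crossprod(P, dZ), dbc = colSums(dZ), dWf = dWf, dbf = dbf)
}

#' Train the patch-based 3D CNN
#'
#' All patches from all training volumes are pooled (label inherited from the
#' parent volume) and standardized by the global training mean/sd; one
#' network is trained by SGDM with soft-max cross-entropy loss.
#'
#' @param volumes List of [mri_volume()] (or 3D arrays).
#' @param labels 0/1 vector, one per volume.
#' @param spec A [patch3d_spec()].
#' @param seed Seed for weight initialization and mini-batch shuffling; equal
#'   seeds give bit-identical models on one thread.
#' @return A `cnn3d_model`; score volumes with [predict_cnn3d()].
#' @export
train_patch_cnn <- function(volumes, labels, spec = patch3d_spec(),
                            seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2L) stop("both classes must be present")
  geo <- .cnn_geometry(spec)
  plist <- lapply(volumes, extract_patches_3d, spec = spec)
  if (any(vapply(plist, length, 1L) < 1L)) stop("a volume produced no patches")
  Pmats <- lapply(unlist(plist, recursive = FALSE),
                  function(p) matrix(as.numeric(p)[geo$im2col], geo$n_out,
                                     ncol(geo$im2col)))
  ylab <- rep(labels, vapply(plist, length, 1L))
  gm <- mean(unlist(lapply(Pmats, mean)))
  gs <- stats::sd(unlist(lapply(Pmats, as.numeric)))
  if (!is.finite(gs) || gs < 1e-12) gs <- 1
  Pmats <- lapply(Pmats, function(P) (P - gm) / gs)
  nf <- spec$filters
  f3 <- ncol(geo$im2col)
  nfeat <- geo$n_pool * nf
  net <- with_seed(seed, list(
    Wc = matrix(stats::rnorm(f3 * nf, sd = sqrt(2 / f3)), f3, nf),
    bc = numeric(nf),
    Wf = matrix(stats::rnorm(nfeat * 2, sd = sqrt(2 / nfeat)), nfeat, 2),
    bf = numeric(2)))
  vel <- lapply(list(Wc = net$Wc, bc = net$bc, Wf = net$Wf, bf = net$bf),
                function(x) x * 0)
  n <- length(Pmats)
  bs <- min(spec$minibatch, n)
  order_seeds <- derive_seeds(seed, spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ord <- with_seed(order_seeds[ep], sample.int(n))
    for (start in seq(1, n, by = bs)) {
      batch <- ord[start:min(start + bs - 1, n)]
      grads <- list(dWc = net$Wc * 0, dbc = net$bc * 0,
                    dWf = net$Wf * 0, dbf = net$bf * 0)
      for (i in batch) {
        fw <- .cnn_forward(Pmats[[i]], net, geo)
        if (any(!is.finite(fw$p)))
          stop("non-finite network output at epoch ", ep,
               " (diverged; lower the learning rate)")
        bw <- .cnn_backward(Pmats[[i]], fw, ylab[i], net, geo)
        for (g in names(grads)) grads[[g]] <- grads[[g]] + bw[[g]]
      }
      for (g in names(grads)) grads[[g]] <- grads[[g]] / length(batch)
      vel$Wc <- spec$momentum * vel$Wc - spec$learning_rate * grads$dWc
      vel$bc <- spec$momentum * vel$bc - spec$learning_rate * grads$dbc
      vel$Wf <- spec$momentum * vel$Wf - spec$learning_rate * grads$dWf
      vel$bf <- spec$momentum * vel$bf - spec$learning_rate * grads$dbf
      net$Wc <- net$Wc + vel$Wc; net$bc <- net$bc + vel$bc
      net$Wf <- net$Wf + vel$Wf; net$bf <- net$bf + vel$bf
    }
  }
  structure(list(net = net, geo = geo, spec = spec, gm = gm, gs = gs,
                 seed = seed),
            class = "cnn3d_model")
}

#' Score a patch with a trained 3D CNN
#' @keywords internal
.cnn_score_patch <- function(model, patch) {
  P <- (matrix(as.numeric(patch)[model$geo$im2col], model$geo$n_out,
               ncol(model$geo$im2col)) - model$gm) / model$gs
  .cnn_forward(P, model$net, model$geo)$p[2]
}

#' Score volumes with a trained 3D CNN
#'
#' The per-volume score is the sum-rule merge (mean) of the class-1 soft-max
#' outputs of all the patches that compose the volume.
#'
#' @param model A `cnn3d_model`.
#' @param volumes List of [mri_volume()] (or 3D arrays).
#' @return Numeric scores in `[0,1]`, named by subject id when available.
#' @export
predict_cnn3d <- function(model, volumes) {
  s <- vapply(volumes, function(v) {
    ps <- extract_patches_3d(v, model$spec)
    mean(vapply(ps, function(p) .cnn_score_patch(model, p), numeric(1)))
  }, numeric(1))
  ids <- vapply(volumes, function(v)
    if (inherits(v, "mri_volume")) v$subject_id else NA_character_,
    character(1))
  if (!anyNA(ids)) names(s) <- ids
  s
}
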