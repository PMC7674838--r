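# Kernel partial least squares feature extraction. Components are extracted
# iteratively: on the current (deflated) kernels, the component t_l is the
# leading eigenvector of K_X K_y (K_y = Y Y' on the centered label vector) --
# the fixed point of the kernel-NIPALS iteration -- after which both kernels
# are deflated by projection off t_l. Per-feature explanatory weights w_i
# aggregate squared correlation loadings v_il across components weighted by
# the component-label correlation Psi(Y, t_l); gamma_l reports the
# class-size-weighted mean of each component's class means.

.kernel_matrix <- function(kind, X1, X2 = NULL, sigma = NULL) {
  if (is.null(X2)) X2 <- X1
  if (kind == "linear") return(tcrossprod(X1, X2))
  # gaussian: exp(-||a-b||^2 / (2 sigma^2))
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

.median_bandwidth <- function(X) {
  d <- as.numeric(stats::dist(X))
  s <- stats::median(d[d > 0])
  if (!is.finite(s) || s == 0) 1 else s
}

.center_train_kernel <- function(K) {
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  H %*% K %*% H
}

.center_test_kernel <- function(Kt, Ktrain_raw) {
  n <- ncol(Kt)
  m <- nrow(Kt)
  colm <- colMeans(Ktrain_raw)
  allm <- mean(Ktrain_raw)
  Kt - matrix(rowMeans(Kt), m, n) -
    matrix(colm, m, n, byrow = TRUE) + allm
}

#' Fit a kernel PLS model
#'
#' Extracts `h` mutually orthogonal components maximizing covariance with the
#' binary labels in the kernel-induced feature space. Each component is
#' oriented so that it correlates non-negatively with the class-1 indicator.
#'
#' @param fm A [feature_matrix()].
#' @param h Number of components (default 10); capped at the achievable rank
#'   with a warning when the deflated kernel degenerates earlier.
#' @param kernel `"gaussian"` (default; bandwidth by the median
#'   pairwise-distance heuristic unless `sigma` is given) or `"linear"`.
#' @param sigma Gaussian bandwidth override.
#' @return A `kpls_model` with components `T` (N x h, unit-norm columns),
#'   `U`, raw/centered train kernels, per-feature weights `w` and loadings
#'   `v`, component-label correlations `psi`, component contributions
#'   `gamma`, class component means, and the discriminative-form diagnostics
#'   `alpha`, `S1`, `S2` (between/within-class scatter of the component
#'   scores).
#' @export
kpls_fit <- function(fm, h = 10L, kernel = c("gaussian", "linear"),
                     sigma = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  kernel <- match.arg(kernel)
  X <- fm$X
  N <- nrow(X)
  h <- as.integer(h)
  if (h < 1L || h > N - 1L) stop("h must be in 1..N-1")
  if (kernel == "gaussian" && is.null(sigma)) sigma <- .median_bandwidth(X)
  Kraw <- .kernel_matrix(kernel, X, sigma = sigma)
  K <- .center_train_kernel(Kraw)
  Yc <- matrix(fm$y - mean(fm$y), ncol = 1)
  Kd <- K
  Yd <- Yc
  Tm <- matrix(0, N, 0); Um <- matrix(0, N, 0)
  nm0 <- NULL
  for (l in seq_len(h)) {
    Ky <- tcrossprod(Yd)
    Mx <- Kd %*% Ky
    nm <- sqrt(sum(Mx^2))
    if (is.null(nm0)) nm0 <- max(nm, .Machine$double.xmin)
    if (!is.finite(nm) || nm < 1e-10 * nm0) {
      warning("kernel rank exhausted after ", l - 1L,
              " components (requested ", h, ")")
      break
    }
    # leading eigenvector of Kd Ky by power iteration (deterministic start)
    t_l <- Kd %*% Yd[, 1]
    if (sqrt(sum(t_l^2)) < 1e-12) t_l <- rep(1, N)
    for (it in 1:500) {
      t_new <- Mx %*% t_l
      nn <- sqrt(sum(t_new^2))
      if (nn < 1e-14) break
      t_new <- t_new / nn
      if (sum(abs(t_new - t_l)) < 1e-12 || sum(abs(t_new + t_l)) < 1e-12) {
        t_l <- t_new; break
      }
      t_l <- t_new
    }
    t_l <- t_l / sqrt(sum(t_l^2))
    if (stats::cov(t_l, Yc)[1] < 0) t_l <- -t_l   # canonical orientation
    u_l <- Yd %*% crossprod(Yd, t_l)
    nu <- sqrt(sum(u_l^2))
    u_l <- if (nu > 1e-14) u_l / nu else Yc / sqrt(sum(Yc^2))
    Tm <- cbind(Tm, t_l); Um <- cbind(Um, u_l)
    P <- diag(N) - tcrossprod(t_l)               # deflate off t_l
    Kd <- P %*% Kd %*% P
    Yd <- P %*% Yd
  }
  h_eff <- ncol(Tm)
  # per-feature loadings and explanatory weights (Eq-style aggregation)
  v <- suppressWarnings(stats::cor(X, Tm))       # D x h, NA for constant cols
  v[!is.finite(v)] <- 0
  psi <- as.numeric(suppressWarnings(stats::cor(Yc, Tm)))
  psi[!is.finite(psi)] <- 0
  D <- ncol(X)
  w <- as.numeric(D * (v^2 %*% psi) / sum(psi))
  # gamma_l: class-size-weighted mean of class means of each component
  cls <- sort(unique(fm$y))
  Ni <- as.numeric(table(factor(fm$y, levels = cls)))
  m_il <- t(vapply(cls, function(c0) colMeans(Tm[fm$y == c0, , drop = FALSE]),
                   numeric(h_eff)))              # classes x h
  gamma <- as.numeric(Ni %*% m_il / sum(Ni))
  # discriminative-form diagnostics on component scores
  grand <- colMeans(Tm)
  S1 <- matrix(0, h_eff, h_eff); S2 <- matrix(0, h_eff, h_eff)
  for (ci in seq_along(cls)) {
    Ti <- Tm[fm$y == cls[ci], , drop = FALSE]
    dm <- colMeans(Ti) - grand
    S1 <- S1 + Ni[ci] * tcrossprod(dm)
    S2 <- S2 + crossprod(sweep(Ti, 2, colMeans(Ti)))
  }
  alpha_e <- eigen(solve(S2 + 1e-8 * diag(h_eff)) %*% S1)
  alpha <- Re(alpha_e$vectors[, which.max(Re(alpha_e$values))])
  structure(list(kernel = kernel, sigma = sigma, h = h_eff,
                 T = Tm, U = Um, K = K, Kraw = Kraw, X_train = X,
                 y = fm$y, v = v, w = stats::setNames(w, fm$feature_ids),
                 psi = psi, gamma = gamma, N_i = Ni,
                 class_component_means = m_il,
                 alpha = alpha, S1 = S1, S2 = S2,
                 proj = Um %*% solve(crossprod(Tm, K %*% Um)),
                 feature_ids = fm$feature_ids),
            class = "kpls_model")
}

#' Project subjects onto fitted kernel-PLS components
#'
#' Everything is expressed through kernel evaluations between new and
#' training subjects, so only dot products (or the Gaussian kernel) of the
#' original features are needed. Transforming the training set reproduces the
#' training components `T` up to numerical tolerance.
#'
#' @param model A [kpls_fit()] model.
#' @param X New subjects x features matrix (or a [feature_matrix()]); feature
#'   count must match training.
#' @return Matrix of component scores, subjects x h.
#' @export
kpls_transform <- function(model, X) {
  stopifnot(inherits(model, "kpls_model"))
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$X_train))
    stop("feature count mismatch: model has ", ncol(model$X_train),
         ", data has ", ncol(X))
  Kt_raw <- .kernel_matrix(model$kernel, X, model$X_train, sigma = model$sigma)
  Kt <- .center_test_kernel(Kt_raw, model$Kraw)
  Kt %*% model$proj
}
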