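# Linear support vector machine, L2-regularized hinge loss, solved in the
# dual by coordinate descent (the LIBLINEAR L1-loss dual CD scheme): with
# labels y in {-1,+1} and box 0 <= alpha_i <= C, each pass updates one alpha
# against the maintained primal vector w = sum_i alpha_i y_i x_i. The bias is
# handled through an appended constant feature. Probability-style outputs in
# [0,1] come from Platt scaling of the decision values, so that sum-rule
# fusion operates on commensurate scores across heterogeneous members.

.svm_dual_cd <- function(X, y01, C, max_pass = 200L, tol = 1e-6, seed = 1L) {
  Xa <- cbind(X, 1)                   # bias as constant feature
  y <- ifelse(y01 == 1L, 1, -1)
  n <- nrow(Xa)
  Qii <- rowSums(Xa^2)
  alpha <- numeric(n)
  w <- numeric(ncol(Xa))
  idx <- with_seed(seed, sample.int(n))   # fixed sweep order: deterministic
  for (pass in seq_len(max_pass)) {
    max_delta <- 0
    for (i in idx) {
      G <- y[i] * sum(w * Xa[i, ]) - 1
      a_old <- alpha[i]
      a_new <- min(max(a_old - G / Qii[i], 0), C)
      if (a_new != a_old) {
        w <- w + (a_new - a_old) * y[i] * Xa[i, ]
        alpha[i] <- a_new
        max_delta <- max(max_delta, abs(a_new - a_old))
      }
    }
    if (max_delta < tol) break
  }
  list(w = w[-length(w)], b = w[length(w)], alpha = alpha)
}

# Platt (2000) sigmoid fit with regularized targets, robust implementation
# (Lin, Lin & Weng 2007): minimizes the regularized-target cross-entropy of
# P(y=1|f) = 1 / (1 + exp(A f + B)) by Newton steps with backtracking.
.platt_fit <- function(f, y01, max_iter = 100L) {
  prior1 <- sum(y01 == 1L); prior0 <- sum(y01 == 0L)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y01 == 1L, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    z <- A * f + B
    # t*z + log(1 + exp(-z)), computed branchlessly and overflow-safe
    sum(t * z + pmax(-z, 0) + log1p(exp(-abs(z))))
  }
  F <- fval(A, B)
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- stats::plogis(-z)             # P(y = 1 | f) = 1 / (1 + exp(z))
    d1 <- t - p
    d2 <- p * (1 - p)
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    step <- 1
    repeat {
      A2 <- A + step * dA; B2 <- B + step * dB
      F2 <- fval(A2, B2)
      if (F2 < F + 1e-4 * step * (g1 * dA + g2 * dB) || step < 1e-10) break
      step <- step / 2
    }
    A <- A + step * dA; B <- B + step * dB; F <- fval(A, B)
  }
  c(A = A, B = B)
}

#' Train a linear SVM with probability outputs
#'
#' @param fm A [feature_matrix()] (or plain matrix with `y` supplied).
#' @param y Labels when `fm` is a plain matrix.
#' @param C Soft-margin cost (default 1).
#' @param seed Seed for the coordinate-descent sweep order (results are
#'   deterministic given the seed).
#' @return An `svm_model` with weights `w`, bias `b`, Platt coefficients, and
#'   training metadata.
#' @export
train_svm <- function(fm, y = NULL, C = 1, seed = 1L) {
  if (inherits(fm, "feature_matrix")) {
    X <- fm$X; y <- fm$y
  } else {
    X <- as.matrix(fm)
    if (is.null(y)) stop("y required when fm is a plain matrix")
  }
  if (length(unique(y)) != 2L || min(table(y)) < 2L)
    stop("need two classes with >= 2 subjects each")
  mu <- colMeans(X)
  sdv <- col_sds(X)
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  fit <- .svm_dual_cd(Z, y, C = C, seed = seed)
  f <- as.numeric(Z %*% fit$w + fit$b)
  platt <- .platt_fit(f, y)
  structure(list(w = fit$w, b = fit$b, mu = mu, sd = sdv, C = C,
                 platt = platt, seed = seed),
            class = "svm_model")
}

#' Score subjects with a trained SVM
#'
#' @param model An `svm_model`.
#' @param X New subjects x features matrix (or [feature_matrix()]).
#' @param type `"prob"` (default; Platt-scaled score in `[0,1]`) or
#'   `"decision"` (raw margin).
#' @return Numeric score vector.
#' @export
predict_svm <- function(model, X, type = c("prob", "decision")) {
  type <- match.arg(type)
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  f <- as.numeric(Z %*% model$w + model$b)
  if (type == "decision") return(f)
  unname(stats::plogis(-(model$platt["A"] * f + model$platt["B"])))
}
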