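# Aggregate Selection: three feature-ranking criteria (Fisher score,
# two-sample t statistic, sparse L1 logistic regression) whose raw statistics
# live on incommensurate scales, made comparable through the analytic
# hierarchy process: each criterion's scores become a pairwise comparison
# matrix whose normalized principal eigenvector is a column of a performance
# matrix; the final ranking is performance matrix times criterion weights.

#' Construct a feature matrix
#'
#' @param X Numeric matrix, subjects x features (D columns of flattened
#'   voxels or any other features). No missing values allowed.
#' @param y Binary labels (0/1 or two-level factor), at least 2 subjects per
#'   class.
#' @param feature_ids Stable feature identifiers (default `f1..fD`; voxel
#'   features use "i_j_k" coordinates).
#' @param subject_ids Optional subject identifiers.
#' @return A `feature_matrix` list with fields `X`, `y`, `feature_ids`,
#'   `subject_ids`.
#' @export
feature_matrix <- function(X, y, feature_ids = NULL, subject_ids = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X))) stop("X must be finite with no NAs")
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (min(table(y)) < 2L || length(unique(y)) != 2L)
    stop("need two classes with >= 2 subjects each")
  if (is.null(feature_ids))
    feature_ids <- if (!is.null(colnames(X))) colnames(X)
                   else paste0("f", seq_len(ncol(X)))
  if (length(feature_ids) != ncol(X))
    stop("feature_ids length must equal ncol(X)")
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(X)))
  structure(list(X = X, y = y, feature_ids = as.character(feature_ids),
                 subject_ids = as.character(subject_ids)),
            class = "feature_matrix")
}

.class_stats <- function(fm) {
  X0 <- fm$X[fm$y == 0L, , drop = FALSE]
  X1 <- fm$X[fm$y == 1L, , drop = FALSE]
  list(n0 = nrow(X0), n1 = nrow(X1),
       m0 = colMeans(X0), m1 = colMeans(X1),
       v0 = col_vars(X0), v1 = col_vars(X1))
}

# degenerate-ratio convention shared by fisher and t scores:
# 0/0 -> 0; positive numerator over zero denominator -> max finite score + 1
.sentinel_ratio <- function(num, den) {
  s <- num / den
  zero_den <- den <= 1e-10 * max(den, 0)
  zero_num <- num <= 1e-10 * max(num, 0)
  zero_both <- zero_den & zero_num
  perfect <- zero_den & !zero_num
  s[zero_both] <- 0
  if (any(perfect)) {
    finite_max <- suppressWarnings(max(s[is.finite(s) & !perfect], 0))
    s[perfect] <- finite_max + 1
  }
  s
}

#' Fisher score per feature
#'
#' `score_j = sum_c n_c (mu_cj - mu_j)^2 / sum_c n_c sigma_cj^2` with class
#' sizes `n_c`, class means `mu_cj`, grand mean `mu_j` and unbiased class
#' variances `sigma_cj^2`. Features constant everywhere score 0; a perfect
#' separator with zero within-class variance gets the largest finite score
#' plus one (sentinel).
#'
#' @param fm A [feature_matrix()].
#' @return Numeric score vector named by `feature_ids`.
#' @export
fisher_score <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  st <- .class_stats(fm)
  mu <- (st$n0 * st$m0 + st$n1 * st$m1) / (st$n0 + st$n1)
  num <- st$n0 * (st$m0 - mu)^2 + st$n1 * (st$m1 - mu)^2
  den <- st$n0 * st$v0 + st$n1 * st$v1
  stats::setNames(.sentinel_ratio(num, den), fm$feature_ids)
}

#' Absolute Welch two-sample t statistic per feature
#'
#' `|t_j| = |mu_1j - mu_0j| / sqrt(v_1j/n_1 + v_0j/n_0)`. Degenerate cases
#' follow the same convention as [fisher_score()].
#'
#' @param fm A [feature_matrix()].
#' @return Numeric score vector named by `feature_ids`.
#' @export
ttest_score <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  st <- .class_stats(fm)
  num <- abs(st$m1 - st$m0)
  den <- sqrt(st$v1 / st$n1 + st$v0 / st$n0)
  stats::setNames(.sentinel_ratio(num, den), fm$feature_ids)
}

#' Sparse L1-regularized logistic-regression importance per feature
#'
#' Fits an L1-penalized binomial logistic regression (coordinate descent via
#' glmnet) on internally standardized features; importance is the absolute
#' fitted coefficient at the selected penalty. Under adequate regularization
#' most importances are exactly zero (sparsity). The penalty is chosen by
#' inner cross-validation (deterministic stratified folds derived from
#' `seed`) unless `lambda` is given.
#'
#' @param fm A [feature_matrix()].
#' @param lambda Optional fixed penalty; `NULL` (default) selects
#'   `lambda.min` by inner CV.
#' @param nfolds Inner CV folds for penalty selection (default 3).
#' @param seed Seed controlling the inner CV fold assignment.
#' @return Numeric score vector (absolute coefficients) named by
#'   `feature_ids`.
#' @export
sbmlr_score <- function(fm, lambda = NULL, nfolds = 3L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$X
  if (ncol(X) < 2L) stop("sbmlr_score needs >= 2 features (glmnet contract)")
  if (!is.null(lambda)) {
    fit <- suppressWarnings(
      glmnet::glmnet(X, fm$y, family = "binomial", alpha = 1,
                     standardize = TRUE,
                     lambda = sort(c(lambda, lambda * 2), decreasing = TRUE)))
    co <- as.numeric(stats::coef(fit, s = lambda))[-1]
  } else {
    nfolds <- min(as.integer(nfolds), min(table(fm$y)))
    if (nfolds >= 3L) {
      foldid <- make_folds(fm$y, k = nfolds, seed = seed, as_foldid = TRUE)
      # suppressWarnings: cv.glmnet warns about small per-fold class counts
      # at desk-scale cohort sizes; harmless for penalty selection
      cv <- suppressWarnings(
        glmnet::cv.glmnet(X, fm$y, family = "binomial", alpha = 1,
                          standardize = TRUE, foldid = foldid,
                          nlambda = 30, lambda.min.ratio = 0.05))
      co <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    } else {
      # classes too small for CV splits (glmnet needs >= 2 per class in
      # every training part): deterministic fallback, the geometric
      # midpoint of the computed penalty path
      fit <- suppressWarnings(
        glmnet::glmnet(X, fm$y, family = "binomial", alpha = 1,
                       standardize = TRUE, nlambda = 30,
                       lambda.min.ratio = 0.05))
      s_mid <- exp(mean(log(range(fit$lambda))))
      co <- as.numeric(stats::coef(fit, s = s_mid))[-1]
    }
  }
  stats::setNames(abs(co), fm$feature_ids)
}

# Saaty's random-consistency index for matrix orders 1..15; beyond that the
# asymptotic approximation 1.98 (n-2)/n.
.saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
               1.51, 1.48, 1.56, 1.57, 1.59)

#' Random-consistency index RI(n)
#'
#' @param n Matrix order.
#' @return The tabulated RI for `n <= 15`, else `1.98 * (n - 2) / n`.
#' @export
random_index <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n <= 15L) .saaty_ri[n] else 1.98 * (n - 2) / n
}

# Shift-and-floor positivization of criterion scores before ratio-matrix
# construction: already strictly positive vectors pass through; otherwise
# s' = s - min(s) + delta with delta = 1e-6 * range(s).
.positivize <- function(s) {
  if (all(!is.finite(s)) || all(s == 0)) stop("all-zero scores: cannot rank")
  rng <- diff(range(s))
  if (rng == 0) {
    if (s[1] > 0) return(s)
    stop("constant non-positive scores: cannot rank")
  }
  if (min(s) > 0) return(s)
  s - min(s) + 1e-6 * rng
}

#' Build a pairwise comparison matrix from criterion scores
#'
#' Constructs the ratio matrix `M_ij = s_i / s_j` from (positivized)
#' criterion scores. Ratio matrices are reciprocal, transitive and perfectly
#' consistent by construction: their principal eigenvalue equals the order
#' `n` (so CR = 0) and the normalized principal eigenvector equals the
#' normalized score vector.
#'
#' @param scores Numeric score vector (one entry per ranked item).
#' @return A `comparison_matrix` list: `M`, `n`, `lambda_max`, `eigvec`
#'   (normalized to sum 1), `CI`, `CR`, `RI`.
#' @export
build_comparison_matrix <- function(scores) {
  s <- .positivize(as.numeric(scores))
  n <- length(s)
  M <- outer(s, s, "/")
  e <- eigen(M)
  k <- which.max(Re(e$values))
  lambda_max <- Re(e$values[k])
  v <- Re(e$vectors[, k])
  if (sum(v) < 0) v <- -v
  v <- v / sum(v)
  ci <- if (n >= 2) (lambda_max - n) / (n - 1) else 0
  ri <- random_index(n)
  cr <- if (abs(ci) < 1e-12) 0 else if (ri > 0) ci / ri else Inf
  structure(list(M = M, n = n, lambda_max = lambda_max, eigvec = v,
                 CI = ci, CR = cr, RI = ri),
            class = "comparison_matrix")
}

#' Consistency ratio of a comparison matrix
#'
#' `CI = (lambda_max - n)/(n - 1)`, `CR = CI / RI(n)`. A set of judgments is
#' considered consistent when CR does not exceed 0.1; CR = 0 means perfectly
#' consistent judgments (as for any ratio-built matrix).
#'
#' @param M A `comparison_matrix` from [build_comparison_matrix()], or a
#'   square positive reciprocal matrix.
#' @return The CR value.
#' @export
consistency_ratio <- function(M) {
  if (inherits(M, "comparison_matrix")) return(M$CR)
  M <- as.matrix(M)
  n <- nrow(M)
  if (n < 2L) stop("comparison matrix order must be >= 2")
  if (any(M <= 0)) stop("comparison matrix must be strictly positive")
  if (max(abs(M * t(M) - 1)) > 1e-6)
    stop("matrix is not reciprocal (M_ij * M_ji must equal 1)")
  lambda_max <- max(Re(eigen(M, only.values = TRUE)$values))
  ci <- (lambda_max - n) / (n - 1)
  ri <- random_index(n)
  if (abs(ci) < 1e-12) 0 else if (ri > 0) ci / ri else Inf
}

# Normalized principal eigenvector of the ratio matrix built from scores.
# For a consistent ratio matrix this equals s / sum(s) exactly, which keeps
# Aggregate Selection tractable for D in the tens of thousands where the
# D x D matrix could never be materialized. Equality of this closed form
# with the dense eigensolver route is property-tested.
#
# A criterion returning identical scores for every feature (e.g. sparse
# logistic regression shrinking every coefficient to zero) carries no
# ranking information; it contributes the uniform column rather than an
# error, so the other criteria decide.
.ratio_eigvec <- function(scores) {
  s <- as.numeric(scores)
  if (diff(range(s)) == 0) return(rep(1 / length(s), length(s)))
  s <- .positivize(s)
  s / sum(s)
}

#' Aggregate Selection
#'
#' Ranks features by combining several criteria through the analytic
#' hierarchy process: each criterion's scores define a consistent ratio
#' comparison matrix whose normalized principal eigenvector forms a column of
#' the performance matrix `S` (columns sum to 1); the final score vector is
#' `S %*% weights`, and the top `k` features are returned (ties broken by
#' feature order, which is stable).
#'
#' @param fm A [feature_matrix()].
#' @param k Number of features to select.
#' @param weights Criterion importance weights, summing to 1; default equal
#'   (1/3 each), set a priori to avoid bias.
#' @param criteria Named list of criterion functions `fm -> scores`; default
#'   Fisher score, absolute t statistic, sparse logistic importances.
#' @param seed Seed forwarded to stochastic criteria (sparse logistic CV).
#' @return List with `selected` (feature ids), `index` (column indices),
#'   `final_scores` (all D), `performance` (D x criteria matrix), `weights`.
#' @export
aggregate_select <- function(fm, k, weights = NULL, criteria = NULL,
                             seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  D <- ncol(fm$X)
  k <- as.integer(k)
  if (k < 1L || k > D) stop("k must be in 1..D")
  if (is.null(criteria))
    criteria <- list(
      fisher = fisher_score,
      ttest = ttest_score,
      sbmlr = function(f) sbmlr_score(f, seed = seed))
  if (is.null(weights)) weights <- rep(1 / length(criteria), length(criteria))
  if (length(weights) != length(criteria) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must match criteria and sum to 1")
  S <- matrix(NA_real_, D, length(criteria),
              dimnames = list(fm$feature_ids, names(criteria)))
  for (i in seq_along(criteria)) {
    sc <- tryCatch(criteria[[i]](fm),
                   error = function(e) stop("criterion '", names(criteria)[i],
                                            "' failed: ", conditionMessage(e)))
    S[, i] <- .ratio_eigvec(sc)
  }
  final <- as.numeric(S %*% weights)
  ord <- order(-final, seq_len(D))      # stable: ties by feature order
  idx <- ord[seq_len(k)]
  list(selected = fm$feature_ids[idx], index = idx, final_scores = final,
       performance = S, weights = weights)
}

#' Export an Aggregate Selection result as CSV
#'
#' @param sel Result of [aggregate_select()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  df <- data.frame(feature_id = rownames(sel$performance),
                   final_score = sel$final_scores,
                   sel$performance, check.names = FALSE)
  df <- df[order(-df$final_score), ]
  df$selected <- df$feature_id %in% sel$selected
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
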