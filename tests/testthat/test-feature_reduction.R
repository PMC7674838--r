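# Ranking criteria, AHP comparison matrices, Aggregate Selection.

test_that("fisher_score matches a direct loop implementation", {
  fm <- toy_fm(n_per_class = 3L, D = 6L, seed = 21)
  got <- fisher_score(fm)
  want <- numeric(6)
  for (j in 1:6) {
    x <- fm$X[, j]
    mu <- mean(x)
    num <- den <- 0
    for (c0 in 0:1) {
      xc <- x[fm$y == c0]
      num <- num + length(xc) * (mean(xc) - mu)^2
      den <- den + length(xc) * stats::var(xc)
    }
    want[j] <- num / den
  }
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("fisher_score degenerate conventions and scale invariance", {
  X <- cbind(const = rep(1, 8), sep = rep(c(0, 1), each = 4),
             noise = c(rnorm(8)))
  set.seed(1)
  X[, 3] <- rnorm(8)
  y <- rep(c(0L, 1L), each = 4L)
  s <- fisher_score(feature_matrix(X, y))
  expect_identical(unname(s["const"]), 0)            # constant feature
  expect_gt(s["sep"], s["noise"])                    # sentinel is largest
  expect_true(is.finite(s["sep"]))
  # invariance to positive per-feature rescaling
  fm <- toy_fm(seed = 3)
  scl <- runif(ncol(fm$X), 0.5, 20)
  fm2 <- feature_matrix(sweep(fm$X, 2, scl, "*"), fm$y)
  expect_equal(unname(fisher_score(fm)), unname(fisher_score(fm2)),
               tolerance = 1e-9)
})

test_that("ttest_score equals the Welch statistic and is scale invariant", {
  fm <- toy_fm(n_per_class = 5L, D = 8L, seed = 22)
  got <- ttest_score(fm)
  want <- vapply(seq_len(8), function(j)
    abs(stats::t.test(fm$X[fm$y == 1L, j], fm$X[fm$y == 0L, j])$statistic),
    numeric(1))
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
  # identical class distributions -> 0
  X <- matrix(rep(c(1, 2, 3, 4), 2), 8, 1)
  X <- cbind(X, X)
  y <- rep(c(0L, 1L), each = 4L)
  expect_equal(unname(ttest_score(feature_matrix(X, y))), c(0, 0))
  # scale invariance
  scl <- runif(8, 0.1, 5)
  fm2 <- feature_matrix(sweep(fm$X, 2, scl, "*"), fm$y)
  expect_equal(unname(got), unname(ttest_score(fm2)), tolerance = 1e-9)
})

test_that("sbmlr_score is sparse under strong regularization and finds the
           separating feature", {
  set.seed(31)
  n <- 30L
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c(0L, 1L), each = n / 2L)
  fm <- feature_matrix(X, y)
  # pure noise + strong penalty: all-zero coefficients
  s_strong <- sbmlr_score(fm, lambda = 5)
  expect_true(all(s_strong == 0))
  # one strongly separating feature among noise: strictly largest score
  X2 <- X
  X2[, 4] <- y + rnorm(n, sd = 0.1)
  s <- sbmlr_score(feature_matrix(X2, y), seed = 7)
  expect_identical(as.integer(which.max(s)), 4L)
  expect_gt(s[4], max(s[-4]))
})

test_that("sbmlr_score approaches the unpenalized logistic fit as reg -> 0", {
  set.seed(32)
  X <- matrix(rnorm(40 * 2), 40, 2)
  y <- as.integer(stats::runif(40) < stats::plogis(0.8 * X[, 1] - 0.5 * X[, 2]))
  if (min(table(y)) < 2) y[1:2] <- c(0L, 1L)
  fm <- feature_matrix(X, y)
  ref <- abs(stats::coef(stats::glm(y ~ X, family = stats::binomial()))[-1])
  got <- sbmlr_score(fm, lambda = 1e-5)
  expect_equal(unname(got), unname(ref), tolerance = 1e-2)
})

test_that("ratio-built comparison matrices are perfectly consistent", {
  cm <- build_comparison_matrix(c(1, 2, 4))
  expect_equal(cm$lambda_max, 3, tolerance = 1e-10)
  expect_equal(cm$CI, 0, tolerance = 1e-10)
  expect_identical(cm$CR, 0)
  # uniform scores: all-ones matrix, uniform eigenvector
  cm1 <- build_comparison_matrix(c(1, 1, 1, 1, 1))
  expect_true(all(cm1$M == 1))
  expect_equal(cm1$eigvec, rep(0.2, 5), tolerance = 1e-12)
  expect_identical(cm1$CR, 0)
  expect_error(build_comparison_matrix(c(0, 0, 0)), "all-zero")
})

test_that("principal eigenpair matches a power-iteration oracle on a
           perturbed reciprocal matrix", {
  set.seed(41)
  s <- runif(4, 0.5, 3)
  M <- outer(s, s, "/")
  # perturb one judgment pair, keeping reciprocity
  M[1, 2] <- M[1, 2] * 1.6; M[2, 1] <- 1 / M[1, 2]
  lam_pkg <- max(Re(eigen(M, only.values = TRUE)$values))
  x <- rep(1, 4)
  for (i in 1:2000) { x <- M %*% x; x <- x / sqrt(sum(x^2)) }
  lam_power <- as.numeric(t(x) %*% M %*% x)
  expect_equal(lam_pkg, lam_power, tolerance = 1e-8)
  # CR equals the hand-computed (lambda-3)/2 / RI(3) for a 3x3 case
  s3 <- c(1, 2, 4)
  M3 <- outer(s3, s3, "/")
  M3[1, 3] <- M3[1, 3] * 2; M3[3, 1] <- 1 / M3[1, 3]
  lam3 <- max(Re(eigen(M3, only.values = TRUE)$values))
  expect_equal(consistency_ratio(M3), ((lam3 - 3) / 2) / random_index(3),
               tolerance = 1e-10)
  expect_gt(consistency_ratio(M3), 0)
})

test_that("consistency_ratio validates its input", {
  expect_error(consistency_ratio(matrix(1, 1, 1)), ">= 2")
  expect_error(consistency_ratio(matrix(c(1, -1, -1, 1), 2, 2)), "positive")
  expect_error(consistency_ratio(matrix(c(1, 2, 3, 1), 2, 2)), "reciprocal")
  expect_identical(consistency_ratio(matrix(1, 5, 5)), 0)
})

test_that("aggregate_select degenerates correctly and matches the
           hand-chained AHP product", {
  fm <- toy_fm(n_per_class = 8L, D = 50L, informative = 4L, seed = 51)
  crits <- list(fisher = fisher_score, ttest = ttest_score)
  # identical criteria -> final ranking equals that ranking
  sel_same <- aggregate_select(fm, k = 5, criteria = list(a = fisher_score,
                                                          b = fisher_score),
                               weights = c(0.5, 0.5))
  expect_identical(order(-sel_same$final_scores)[1:5],
                   order(-fisher_score(fm), seq_len(50))[1:5])
  # degenerate weights (1, 0) -> fisher-only ranking
  sel_f <- aggregate_select(fm, k = 5, criteria = crits, weights = c(1, 0))
  expect_identical(sel_f$index, order(-fisher_score(fm), seq_len(50))[1:5])
  # step-by-step oracle: column-normalized eigenvectors times weights
  w <- c(0.6, 0.4)
  sel <- aggregate_select(fm, k = 7, criteria = crits, weights = w)
  pos <- function(s) { if (min(s) > 0) s else s - min(s) + 1e-6 * diff(range(s)) }
  col1 <- pos(fisher_score(fm)); col1 <- col1 / sum(col1)
  col2 <- pos(ttest_score(fm)); col2 <- col2 / sum(col2)
  want <- as.numeric(cbind(col1, col2) %*% w)
  expect_equal(sel$final_scores, want, tolerance = 1e-12)
  expect_identical(sel$index, order(-want, seq_len(50))[1:7])
  # performance-matrix columns sum to 1
  expect_equal(colSums(sel$performance), c(fisher = 1, ttest = 1),
               tolerance = 1e-12)
})

test_that("closed-form ratio eigenvector equals the dense eigensolver", {
  set.seed(61)
  for (rep in 1:5) {
    s <- runif(sample(3:20, 1), 0.01, 10)
    cm <- build_comparison_matrix(s)
    expect_equal(cm$eigvec, s / sum(s), tolerance = 1e-8)
  }
})

test_that("aggregate_select is invariant to feature permutation", {
  fm <- toy_fm(n_per_class = 6L, D = 20L, seed = 71)
  perm <- with(list(), { set.seed(72); sample.int(20) })
  fm_p <- feature_matrix(fm$X[, perm], fm$y,
                         feature_ids = fm$feature_ids[perm])
  crits <- list(fisher = fisher_score, ttest = ttest_score)
  sel <- aggregate_select(fm, k = 6, criteria = crits, weights = c(0.5, 0.5))
  sel_p <- aggregate_select(fm_p, k = 6, criteria = crits,
                            weights = c(0.5, 0.5))
  expect_setequal(sel$selected, sel_p$selected)
  expect_equal(sel$final_scores[perm], sel_p$final_scores, tolerance = 1e-12)
})

test_that("criterion failures propagate with the criterion name", {
  fm <- toy_fm(seed = 81)
  bad <- list(broken = function(f) stop("boom"))
  expect_error(aggregate_select(fm, k = 2, criteria = bad, weights = 1),
               "broken")
})
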