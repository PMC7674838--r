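# SVM, slice backends, patch extraction and the 3D CNN.

test_that("linear SVM separates separable data and is deterministic", {
  set.seed(101)
  X <- matrix(rnorm(30 * 2), 30, 2)
  y <- rep(c(0L, 1L), each = 15L)
  X[y == 1L, ] <- X[y == 1L, ] + 4
  m <- train_svm(X, y = y, C = 1, seed = 5)
  p <- predict_svm(m, X)
  expect_equal(auc(p, y), 1)
  expect_true(all(p >= 0 & p <= 1))
  # duplicated training -> identical scores (determinism)
  m2 <- train_svm(X, y = y, C = 1, seed = 5)
  expect_identical(predict_svm(m2, X), p)
  expect_error(train_svm(X, y = rep(0L, 30)), "two classes")
})

test_that("SVM on permuted labels stays near chance in cross-validation", {
  set.seed(102)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- sample(rep(c(0L, 1L), each = 20L))
  folds <- make_folds(y, 5, seed = 3)
  scores <- numeric(40)
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    m <- train_svm(X[-te, ], y = y[-te], seed = 4)
    scores[te] <- predict_svm(m, X[te, , drop = FALSE])
  }
  a <- auc(scores, y)
  expect_gte(a, 0.3); expect_lte(a, 0.7)
})

test_that("slice models respect keys and track intensity signal", {
  # build one slice group directly: class-1 subjects have uniformly higher
  # band intensity (raw composition, no per-volume rescaling)
  set.seed(103)
  n <- 16L
  ids <- sprintf("s%02d", 1:n)
  labels <- stats::setNames(rep(c(0L, 1L), each = n / 2L), ids)
  cfg <- decomp_config("A", 1L, scale = FALSE)
  vols <- lapply(ids, function(id) {
    base <- array(stats::runif(12^3, 0, 0.5), c(12L, 12L, 12L))
    if (labels[id] == 1L) base <- base + 0.3
    mri_volume(base, subject_id = id, label = labels[id])
  })
  g <- lapply(vols, compose_rgb, cfg = cfg, n = 5)
  sm <- train_slice_model(g, labels, slice_backend("lin"), seed = 1)
  sc <- predict_slice_model(sm, g)
  expect_named_scores(sc, ids)
  expect_gte(auc(sc[ids], labels), 0.9)
  # score monotone in mean band intensity (higher intensity, higher score)
  mns <- vapply(g, function(im) mean(im$bands), numeric(1))
  expect_gt(stats::cor(mns, sc[ids], method = "spearman"), 0)
  # mixed-key groups rejected
  g_mixed <- c(g[1:3], lapply(vols[4:6], compose_rgb, cfg = cfg, n = 6))
  expect_error(train_slice_model(g_mixed, labels), "mixed")
  # determinism
  sm2 <- train_slice_model(g, labels, slice_backend("lin"), seed = 1)
  expect_identical(predict_slice_model(sm2, g), sc)
})

test_that("identical images with mixed labels score the class prevalence", {
  v <- random_volume(c(8L, 8L, 8L), seed = 104, subject_id = "a")
  cfg <- decomp_config("A", 0L)
  imgs <- lapply(sprintf("s%d", 1:6), function(id) {
    im <- compose_rgb(v, cfg, 3)
    im$subject_id <- id
    im
  })
  labels <- stats::setNames(c(0L, 0L, 1L, 1L, 1L, 1L), sprintf("s%d", 1:6))
  sm <- train_slice_model(imgs, labels, slice_backend("lin"))
  sc <- predict_slice_model(sm, imgs)
  expect_equal(unname(sc), rep(4 / 6, 6), tolerance = 1e-8)
})

test_that("backends are interchangeable behind the same interface", {
  co <- tiny_cohort(n_per_class = 6L, d = 0.4, region = "uniform",
                    noise_sd = 0.05, shape = c(10L, 10L, 10L), seed = 105)
  groups <- decompose_cohort(co, decomp_config("B", 0L, stride = 2L))
  labels <- stats::setNames(co$labels, co$subject_ids)
  g <- groups[[2]]
  for (bk in list(slice_backend("lin"), slice_backend("ridge"),
                  slice_backend("svm"))) {
    sm <- train_slice_model(g, labels, bk, seed = 2)
    sc <- predict_slice_model(sm, g)
    expect_named_scores(sc, co$subject_ids)
  }
})

test_that("patch tiling counts and non-overlap match the floor-division
           oracle", {
  # reference geometry: 121 x 145 x 121 with 28 x 28 x 121 patches -> 20
  v <- array(seq_len(121 * 145 * 121) %% 97, c(121L, 145L, 121L))
  spec <- patch3d_spec(patch_shape = c(28L, 28L, 121L))
  patches <- extract_patches_3d(v, spec)
  expect_length(patches, prod(c(121, 145, 121) %/% c(28, 28, 121)))
  expect_length(patches, 20L)
  # patch equal to the volume: exactly one patch, identical
  v2 <- random_volume(c(6L, 5L, 4L), seed = 7)
  p1 <- extract_patches_3d(v2, patch3d_spec(patch_shape = c(6L, 5L, 4L)))
  expect_length(p1, 1L)
  expect_identical(p1[[1]][, , ], v2$voxels)
  # non-overlap: voxel index sets are disjoint (checked via value identity
  # on a volume of unique values)
  v3 <- mri_volume(array(seq_len(9 * 8 * 7), c(9L, 8L, 7L)))
  ps <- extract_patches_3d(v3, patch3d_spec(patch_shape = c(3L, 4L, 7L)))
  vals <- unlist(ps)
  expect_identical(anyDuplicated(vals), 0L)
  expect_length(vals, prod(c(9, 8, 7) %/% c(3, 4, 7)) * 3 * 4 * 7)
  # validation
  expect_error(extract_patches_3d(v2, patch3d_spec(patch_shape = c(7L, 5L, 4L))),
               "exceeds")
})

desk_cnn_spec <- function() patch3d_spec(patch_shape = c(8L, 8L, 16L),
                                         field = 3L, conv_stride = 2L,
                                         pool_stride = 2L, filters = 4L,
                                         learning_rate = 1e-3, epochs = 100L)

test_that("3D CNN separates a strong global intensity effect out of sample", {
  idx_tr <- c(1:7, 11:17); idx_te <- c(8:10, 18:20)
  aucs <- vapply(1:5, function(s) {
    co <- tiny_cohort(n_per_class = 10L, d = 0.25, region = "uniform",
                      noise_sd = 0.08, shape = c(16L, 16L, 16L),
                      seed = 20 + s)
    m <- train_patch_cnn(co$volumes[idx_tr], co$labels[idx_tr],
                         desk_cnn_spec(), seed = s)
    auc(predict_cnn3d(m, co$volumes[idx_te]), co$labels[idx_te])
  }, numeric(1))
  expect_true(all(aucs >= 0.85))
})

test_that("3D CNN stays near chance on zero-effect cohorts", {
  idx_tr <- c(1:7, 11:17); idx_te <- c(8:10, 18:20)
  aucs <- vapply(1:3, function(s) {
    co <- tiny_cohort(n_per_class = 10L, d = 0, region = "uniform",
                      noise_sd = 0.08, shape = c(16L, 16L, 16L),
                      seed = 40 + s)
    m <- train_patch_cnn(co$volumes[idx_tr], co$labels[idx_tr],
                         desk_cnn_spec(), seed = s)
    auc(predict_cnn3d(m, co$volumes[idx_te]), co$labels[idx_te])
  }, numeric(1))
  expect_true(mean(aucs >= 0.3 & aucs <= 0.7) >= 2 / 3)
})

test_that("per-volume CNN score is the mean of its patch scores and
           training is seed-reproducible", {
  co <- tiny_cohort(n_per_class = 5L, d = 0.3, region = "uniform",
                    shape = c(16L, 16L, 16L), seed = 106)
  spec <- desk_cnn_spec()
  spec$epochs <- 10L
  m <- train_patch_cnn(co$volumes, co$labels, spec, seed = 9)
  v <- co$volumes[[2]]
  s_vol <- predict_cnn3d(m, list(v))
  score_patch <- get(".cnn_score_patch", asNamespace("mrifusion"))
  s_patches <- vapply(extract_patches_3d(v, spec),
                      function(p) score_patch(m, p), numeric(1))
  expect_equal(unname(s_vol), mean(s_patches), tolerance = 1e-12)
  m2 <- train_patch_cnn(co$volumes, co$labels, spec, seed = 9)
  expect_identical(m$net, m2$net)
})
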