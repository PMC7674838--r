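# Shared fixtures, all generated in code.

# deterministic volume whose voxel (i,j,k) value is a known function of the
# coordinates -- handy for slicing/cropping oracles
coord_volume <- function(shape = c(6L, 7L, 8L), fun = function(i, j, k)
                           i + 10 * j + 100 * k, subject_id = "coord") {
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  mri_volume(array(fun(g$i, g$j, g$k), dim = shape), subject_id = subject_id)
}

random_volume <- function(shape = c(8L, 9L, 10L), seed = 1L,
                          subject_id = "rand", label = NA) {
  set.seed(seed)
  mri_volume(array(stats::runif(prod(shape)), dim = shape),
             subject_id = subject_id, label = label)
}

# small two-class feature matrix with a few informative features
toy_fm <- function(n_per_class = 10L, D = 12L, informative = 3L,
                   delta = 1.5, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- matrix(stats::rnorm(n * D), n, D)
  y <- rep(c(0L, 1L), each = n_per_class)
  X[y == 1L, seq_len(informative)] <- X[y == 1L, seq_len(informative)] + delta
  feature_matrix(X, y)
}

# tiny synthetic cohort for pipeline tests (fast: ~16x16x16)
tiny_cohort <- function(n_per_class = 8L, d = 0.3, shape = c(16L, 16L, 16L),
                        region = "inner", noise_sd = 0.1, seed = 1L) {
  make_cohort(synth_spec(shape = shape, n_per_class = n_per_class, d = d,
                         region = region, noise_sd = noise_sd, seed = seed))
}

expect_named_scores <- function(s, ids) {
  expect_true(is.numeric(s))
  expect_setequal(names(s), ids)
  expect_true(all(s >= 0 & s <= 1))
}
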