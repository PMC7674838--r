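# RGB-like slice decomposition: approaches A-D, gap, stride, grouping.

test_that("extract_slice returns the plane at the mapped axis", {
  v <- coord_volume(c(6L, 7L, 8L), fun = function(i, j, k) j + k)
  s1 <- extract_slice(v, "sagittal", 1)
  expect_equal(s1, outer(seq_len(7), seq_len(8), "+"))
  # brute-force loop oracle on a random volume
  v2 <- random_volume(c(6L, 7L, 8L), seed = 11)
  got <- extract_slice(v2, "coronal", 5)
  want <- matrix(0, 6, 8)
  for (i in 1:6) for (k in 1:8) want[i, k] <- v2$voxels[i, 5, k]
  expect_identical(got, want)
  # slice count equals the axis extent
  expect_identical(dim(extract_slice(v2, "transaxial", 8)), c(6L, 7L))
  expect_error(extract_slice(v2, "transaxial", 9), "out of range")
  expect_error(extract_slice(v2, "sagittal", 0), "out of range")
})

test_that("compose_rgb stacks the right slices for every approach", {
  v <- random_volume(c(10L, 10L, 10L), seed = 2)
  raw_cfg <- function(ap, gap) decomp_config(ap, gap = gap, scale = FALSE)

  # approach A, gap 1, n = 1: the first three sagittal slices as R/G/B
  im <- compose_rgb(v, raw_cfg("A", 1L), 1)
  for (b in 1:3)
    expect_identical(im$bands[, , b], extract_slice(v, "sagittal", b))

  # gap = 0: three identical bands
  im0 <- compose_rgb(v, raw_cfg("C", 0L), 4)
  expect_identical(im0$bands[, , 1], im0$bands[, , 2])
  expect_identical(im0$bands[, , 2], im0$bands[, , 3])
  expect_identical(im0$bands[, , 1], extract_slice(v, "transaxial", 4))

  # approach B, gap 2, n = 5: coronal slices 5, 7, 9
  imB <- compose_rgb(v, raw_cfg("B", 2L), 5)
  expect_identical(imB$bands[, , 1], extract_slice(v, "coronal", 5))
  expect_identical(imB$bands[, , 2], extract_slice(v, "coronal", 7))
  expect_identical(imB$bands[, , 3], extract_slice(v, "coronal", 9))

  # approach D: sagittal(n), coronal(n+gap), transaxial(n+2 gap)
  imD <- compose_rgb(v, raw_cfg("D", 1L), 3)
  expect_identical(imD$bands[, , 1], extract_slice(v, "sagittal", 3))
  expect_identical(imD$bands[, , 2], extract_slice(v, "coronal", 4))
  expect_identical(imD$bands[, , 3], extract_slice(v, "transaxial", 5))

  # out-of-range band
  expect_error(compose_rgb(v, raw_cfg("A", 2L), 8), "out of range")
})

test_that("approach D pads bands to a common shape on non-cubic volumes", {
  v <- random_volume(c(6L, 8L, 10L), seed = 3)
  im <- compose_rgb(v, decomp_config("D", 0L, scale = FALSE), 2)
  # sagittal plane 8x10, coronal 6x10, transaxial 6x8 -> padded to 8x10
  expect_identical(dim(im$bands), c(8L, 10L, 3L))
  expect_identical(im$bands[, , 1], extract_slice(v, "sagittal", 2))
  # coronal band centered: one zero row added top, one bottom
  expect_true(all(im$bands[1, , 2] == 0))
  expect_identical(im$bands[2:7, , 2], extract_slice(v, "coronal", 2))
})

test_that("anchor sets match exhaustive enumeration and ignore content", {
  shapes <- list(c(100L, 100L, 100L), c(10L, 12L, 14L), c(9L, 9L, 9L))
  axes_of <- list(A = c(1L, 1L, 1L), B = c(2L, 2L, 2L), C = c(3L, 3L, 3L),
                  D = c(1L, 2L, 3L))
  for (shape in shapes) for (ap in names(axes_of)) for (gap in 0:2) {
    for (stride in c(1L, NA)) {
      cfg <- decomp_config(ap, gap = gap,
                           stride = if (is.na(stride)) NULL else stride)
      # oracle: try every anchor, keep those whose three bands fit
      ax <- axes_of[[ap]]
      ok <- Filter(function(n)
        all(vapply(1:3, function(b) n + (b - 1L) * gap <= shape[ax[b]],
                   logical(1))),
        seq_len(max(shape)))
      ok <- ok[seq(1, length(ok), by = cfg$stride)]
      expect_identical(decomp_anchors(shape, cfg), as.integer(ok),
                       info = sprintf("%s gap%d stride%s shape %s", ap, gap,
                                      cfg$stride, paste(shape, collapse = "x")))
    }
  }
  # 100^3, approach A: gap 0 stride 1 -> 100 images; gap 1 default stride -> 33
  expect_length(decomp_anchors(c(100L, 100L, 100L), decomp_config("A", 0L)),
                100L)
  expect_length(decomp_anchors(c(100L, 100L, 100L), decomp_config("A", 1L)),
                33L)
})

test_that("decomposition is lossless for gap 0, stride 1 and deterministic", {
  v <- random_volume(c(7L, 8L, 9L), seed = 4)
  cfg <- decomp_config("A", 0L, stride = 1L, scale = FALSE)
  imgs <- decompose_volume(v, cfg)
  expect_length(imgs, 7L)
  rebuilt <- array(0, dim = v$shape)
  for (im in imgs) rebuilt[im$n, , ] <- im$bands[, , 1]
  expect_identical(rebuilt, v$voxels)
  # determinism: equal volumes give band-wise equal images
  imgs2 <- decompose_volume(v, cfg)
  expect_identical(lapply(imgs, `[[`, "bands"), lapply(imgs2, `[[`, "bands"))
  # too-small volume errors
  tiny <- mri_volume(array(0, c(2L, 2L, 2L)))
  expect_error(decompose_volume(tiny, decomp_config("A", 2L)), "too small")
})

test_that("group_by_slice partitions a cohort into per-slice groups", {
  co <- tiny_cohort(n_per_class = 4L, shape = c(10L, 10L, 10L), seed = 6L)
  cohort3 <- cohort_subset(co, c(1L, 2L, 5L))
  cfg <- decomp_config("A", 0L, stride = 1L)
  imgs <- unlist(lapply(cohort3$volumes, decompose_volume, cfg = cfg),
                 recursive = FALSE)
  groups <- group_by_slice(imgs)
  expect_length(groups, 10L)
  expect_true(all(vapply(groups, length, 1L) == 3L))
  # union of groups is the input multiset
  expect_identical(sum(vapply(groups, length, 1L)), length(imgs))
  # identical key sets across co-registered subjects
  keysets <- lapply(cohort3$volumes, function(v)
    vapply(decompose_volume(v, cfg), `[[`, character(1), "key"))
  expect_identical(keysets[[1]], keysets[[2]])
  expect_identical(keysets[[1]], keysets[[3]])
  # removing one subject removes exactly one image from every group
  imgs2 <- unlist(lapply(cohort3$volumes[-2], decompose_volume, cfg = cfg),
                  recursive = FALSE)
  groups2 <- group_by_slice(imgs2)
  expect_true(all(vapply(groups2, length, 1L) == 2L))
  expect_identical(names(groups2), names(groups))
})
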