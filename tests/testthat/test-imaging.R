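# Data model, I/O, and contrast-to-saturation conversion.

test_that("dynamic_image enforces its grid and time contracts", {
  v <- array(0, c(4, 4, 4, 3))
  expect_s3_class(dynamic_image(v, c(1, 1, 1), times = c(0, 2, 4)),
                  "dynamic_image")
  expect_error(dynamic_image(v, c(1, 1, 1), times = c(0, 2)),
               "number of frames")
  expect_error(dynamic_image(v, c(1, 1, 1), times = c(0, 2, 2)),
               "strictly increasing")
  expect_error(dynamic_image(v, c(1, -1, 1), times = c(0, 2, 4)),
               "positive")
  expect_error(label_map(array(9L, c(2, 2, 2)), c(1, 1, 1)),
               "not in the dictionary")
})

test_that("load_dynamic_series stacks frames and rejects grid mismatch", {
  td <- withr::local_tempdir()
  paths <- file.path(td, sprintf("f%d.nii.gz", 1:4))
  for (i in 1:4)
    write_image3d(image3d(array(i, c(5, 6, 7)), c(1, 1, 1.5)), paths[i])
  img <- load_dynamic_series(paths, times = c(0, 2, 4, 6))
  expect_equal(dim(img$values), c(5, 6, 7, 4))
  expect_equal(img$values[1, 1, 1, ], c(1, 2, 3, 4))
  expect_equal(img$spacing, c(1, 1, 1.5))

  bad <- file.path(td, "bad.nii.gz")
  write_image3d(image3d(array(0, c(5, 6, 8)), c(1, 1, 1.5)), bad)
  expect_error(load_dynamic_series(c(paths[1:3], bad), c(0, 2, 4, 6)),
               "grid")
  expect_error(load_dynamic_series(paths[1:2], c(0, 2, 4)), "length")
  expect_error(read_image3d(file.path(td, "absent.nii.gz")), "cannot read")
})

test_that("4D round-trip preserves values, grid metadata, and times", {
  td <- withr::local_tempdir()
  set.seed(42)
  img <- dynamic_image(array(rnorm(5 * 4 * 3 * 6), c(5, 4, 3, 6)),
                       spacing = c(0.5, 0.7, 1.25),
                       origin = c(-10, 3, 2.5),
                       times = c(0, 1.5, 3, 4.5, 6, 9))
  p <- file.path(td, "series.nii.gz")
  write_dynamic_image(img, p)
  back <- read_dynamic_image(p)
  expect_equal(back$values, img$values, tolerance = 1e-7)
  expect_equal(back$spacing, img$spacing)
  expect_equal(back$origin, img$origin)
  expect_equal(back$times, img$times)

  lm <- label_map(array(sample(0:4, 60, TRUE), c(5, 4, 3)),
                  spacing = c(0.5, 0.7, 1.25))
  lp <- file.path(td, "labels.nii.gz")
  write_label_map(lm, lp)
  lback <- read_label_map(lp)
  expect_identical(lback$values, lm$values)
  expect_equal(lback$labels, lm$labels)
})

test_that("baseline is the mean of the pre-contrast frames", {
  v <- array(40, c(3, 3, 3, 5))
  img <- dynamic_image(v, c(1, 1, 1), times = 0:4)
  expect_true(all(compute_baseline(img, 2)$values == 40))

  v[1, 1, 1, 1:2] <- c(10, 20)
  img <- dynamic_image(v, c(1, 1, 1), times = 0:4)
  expect_equal(compute_baseline(img, 2)$values[1, 1, 1], 15)
  expect_error(compute_baseline(img, 0), "n_pre")
  expect_error(compute_baseline(img, 5), "n_pre")
})

test_that("baseline is invariant to permutation of the pre frames", {
  set.seed(7)
  v <- array(rnorm(3^3 * 6, 40), c(3, 3, 3, 6))
  img <- dynamic_image(v, c(1, 1, 1), times = 0:5)
  perm <- v
  perm[, , , 1:3] <- v[, , , c(3, 1, 2)]
  imgp <- dynamic_image(perm, c(1, 1, 1), times = 0:5)
  expect_equal(compute_baseline(img, 3)$values,
               compute_baseline(imgp, 3)$values)
})

test_that("enhancement subtracts baseline, keeps negatives, and is linear", {
  set.seed(8)
  v <- array(rnorm(2^3 * 4, 50, 10), c(2, 2, 2, 4))
  img <- dynamic_image(v, c(1, 1, 1), times = 0:3)
  base <- compute_baseline(img, 2)
  e <- enhancement(img, base)
  expect_equal(e$values[, , , 3], v[, , , 3] - base$values)
  expect_true(any(e$values < 0))

  # identity: I == I_b everywhere -> zero enhancement
  flat <- dynamic_image(array(rep(base$values, 4), c(2, 2, 2, 4)),
                        c(1, 1, 1), times = 0:3)
  expect_true(all(enhancement(flat, base)$values == 0))

  # linearity under joint scaling of image and baseline
  img2 <- dynamic_image(2.5 * v, c(1, 1, 1), times = 0:3)
  base2 <- image3d(2.5 * base$values, c(1, 1, 1))
  expect_equal(enhancement(img2, base2)$values, 2.5 * e$values)

  wrong <- image3d(array(0, c(3, 3, 3)), c(1, 1, 1))
  expect_error(enhancement(img, wrong), "grid")
})

test_that("saturation normalisation divides by the AIF peak", {
  aif <- ref_gamma(seq(0, 38, 2))
  curve <- aif$saturation * 60
  v <- array(rep(curve, each = 8), c(2, 2, 2, 20))
  enh <- dynamic_image(v, c(1, 1, 1), times = aif$times)
  sat <- normalize_to_saturation(enh, aif)
  expect_equal(max(sat$values[1, 1, 1, ]), 60)  # aif peak is 1 here
  expect_equal(normalize_to_saturation(
    dynamic_image(0 * v, c(1, 1, 1), aif$times), aif)$values, 0 * v)
  # linear in the enhancement
  enh3 <- dynamic_image(3 * v, c(1, 1, 1), aif$times)
  expect_equal(normalize_to_saturation(enh3, aif)$values, 3 * sat$values)
  bad <- aif_curve(c(0, 1), c(0, 0))
  expect_error(normalize_to_saturation(enh, bad), "peak")
})
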