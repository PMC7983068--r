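# Synthetic perfusion phantom: analytic AIF, delayed-transport forward
# model, mixture-theory ground truth.

test_that("gamma-variate AIF peaks at t0 + alpha*beta with the set amplitude", {
  times <- seq(0, 40, 2)           # includes the analytic peak t = 16
  aif <- gamma_variate_aif(t0 = 4, alpha = 3, beta = 4, amplitude = 0.8,
                           times = times)
  # causality before arrival
  expect_true(all(aif$saturation[times <= 4] == 0))
  # stationary point of the gamma-variate: t = t0 + alpha*beta, value = A
  expect_equal(aif$saturation[times == 16], 0.8, tolerance = 1e-12)
  expect_lt(max(aif$saturation[times != 16]), 0.8)
  # linearity in amplitude
  aif2 <- gamma_variate_aif(4, 3, 4, 1.6, times)
  expect_equal(aif2$saturation, 2 * aif$saturation)
  expect_error(gamma_variate_aif(0, -1, 4, 1, times), "alpha")
})

test_that("phantom curves are the AIF delayed by distance over speed", {
  cfg <- tiny_config(block_speeds = rep(1, 8))       # uniform 1 mm/s
  ph <- build_phantom(cfg)
  d <- ph$truth$distance$values
  sel <- which(!ph$truth$vessel_mask & d > 2 & d < 8)[c(1, 50, 200)]
  for (v in sel) {
    obs <- sapply(seq_along(cfg$times), function(f)
      ph$series$values[arrayInd(v, dim(d))[1], arrayInd(v, dim(d))[2],
                       arrayInd(v, dim(d))[3], f])
    expected <- cfg$baseline + cfg$enh_amplitude * cfg$porosity *
      gamma_variate_aif(cfg$t0 + d[v] / 1, cfg$alpha, cfg$beta,
                        cfg$amplitude, cfg$times)$saturation
    expect_equal(obs, expected, tolerance = 1e-10)
  }
  # vessel voxels carry the undelayed arterial signal
  vv <- which(ph$truth$vessel_mask)[1]
  ai <- arrayInd(vv, dim(d))
  expect_equal(ph$series$values[ai[1], ai[2], ai[3], ],
               cfg$baseline + cfg$enh_amplitude * ph$aif$saturation,
               tolerance = 1e-10)
})

test_that("mixture closure identities hold exactly on ground truth", {
  ph <- build_phantom(tiny_config())
  tr <- ph$truth
  expect_equal(tr$s_nano + tr$s_blood, array(1, dim(tr$s_nano)))
  phi_sum <- as.vector(tr$phi_tissue) + tr$phi_nano + tr$phi_blood
  expect_equal(phi_sum, array(1, dim(tr$s_nano)))
  expect_true(all(tr$s_nano >= 0 & tr$s_nano <= 1))
  expect_true(all(tr$phi_nano >= 0 & tr$phi_nano <= 1))
})

test_that("identical seed and config give bit-identical series", {
  a <- build_phantom(tiny_config(noise_sd = 3, seed = 99L))
  b <- build_phantom(tiny_config(noise_sd = 3, seed = 99L))
  expect_identical(a$series$values, b$series$values)
  c <- build_phantom(tiny_config(noise_sd = 3, seed = 100L))
  expect_false(identical(a$series$values, c$series$values))
})

test_that("two-block phantoms delay arrivals by d/a1 - d/a2", {
  # octant speeds 1 and 2 mm/s left/right of the mid-x plane
  cfg <- tiny_config(block_speeds = rep(c(1, 2), 4),
                     times = seq(0, by = 2, length.out = 40))
  ph <- build_phantom(cfg)
  sat <- normalize_to_saturation(
    enhancement(ph$series, compute_baseline(ph$series, 1)), ph$aif)
  bm <- bat_map(sat, !ph$truth$vessel_mask)
  d <- ph$truth$distance$values
  sh <- dim(d)
  # mirrored voxel pair across the mid-x plane: same distance, speeds 1 vs 2
  i <- 4; j <- sh[2] %/% 2; k <- sh[3] %/% 2
  im <- sh[1] + 1 - i
  expect_equal(d[i, j, k], d[im, j, k])
  dd <- d[i, j, k]
  diff_bat <- bm$values$values[i, j, k] - bm$values$values[im, j, k]
  # within one frame interval of the analytic delay difference
  expect_lte(abs(diff_bat - (dd / 1 - dd / 2)), 2)
})

test_that("with uniform speed, arrival is nondecreasing in distance", {
  cfg <- tiny_config(block_speeds = rep(1.5, 8))
  ph <- build_phantom(cfg)
  sat <- normalize_to_saturation(
    enhancement(ph$series, compute_baseline(ph$series, 1)), ph$aif)
  bm <- bat_map(sat, !ph$truth$vessel_mask)
  ok <- bm$valid
  d <- ph$truth$distance$values[ok]
  b <- bm$values$values[ok]
  o <- order(d)
  # nondecreasing up to exact ties in the quantised arrival
  expect_true(all(diff(b[o])[diff(d[o]) > 1e-9] >= 0))
})

test_that("tofts phantom fills regions with forward-model curves", {
  times <- seq(0, 118, 2)
  aif <- ref_gamma(times)
  regions <- array(1L, c(4, 4, 4)); regions[3:4, , ] <- 2L
  pars <- data.frame(label = 1:2, ktrans = c(0, 0.01), ve = c(0.3, 0.3),
                     fpv = c(0, 1))
  ph <- build_tofts_phantom(pars, regions, aif)
  # ktrans = 0, fpv = 0: identically zero
  expect_true(all(ph$values[1, 1, 1, ] == 0))
  # region 2 curve: forward model with fpv passthrough
  expect_equal(ph$values[3, 1, 1, ],
               extended_tofts_forward(0.01, 0.3, 1, aif, times))
  expect_error(
    build_tofts_phantom(data.frame(label = 1, ktrans = 0.1, ve = 0,
                                   fpv = 0), regions, aif),
    "ve")
})
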