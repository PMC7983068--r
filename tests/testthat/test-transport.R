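# Flow speed, superpixels, Darcy/Poiseuille permeability, flow-rate and
# blood-volume estimators.

test_that("pixelwise speed divides distance by referenced transit time", {
  sh <- c(2, 2, 1)
  dist <- image3d(array(c(5, 5, 0, 5), sh), c(1, 1, 1))
  bvals <- image3d(array(c(4.5, 2, 4, 2), sh), c(1, 1, 1))
  bm <- structure(list(values = bvals,
                       valid = array(c(TRUE, TRUE, TRUE, TRUE), sh)),
                  class = "bat_map")
  sf <- pixelwise_speed(dist, bm, inlet_bat = 2)
  expect_equal(sf$values$values[1, 1, 1], 5 / 2.5)  # 5 mm over 2.5 s
  expect_false(sf$valid[2, 1, 1])                   # BAT == inlet
  expect_false(sf$valid[1, 2, 1])                   # inside vessel, d = 0
  expect_false(sf$valid[2, 2, 1])
  expect_true(is.na(sf$values$values[2, 2, 1]))
})

test_that("superpixels tile a featureless volume near-regularly", {
  ref <- image3d(array(1, c(60, 60, 60)), c(1, 1, 1))
  part <- slic_superpixels(ref, array(TRUE, c(60, 60, 60)),
                           grid_size = 20, iterations = 2)
  expect_gte(part$n_regions, 25)
  expect_lte(part$n_regions, 29)
  # partition property: disjoint cover of the mask
  expect_equal(sum(part$sizes), 60^3)
  expect_true(all(part$labels > 0))
  expect_equal(part$mean_volume_mm3, 60^3 / part$n_regions)
})

test_that("superpixels adhere to a sharp intensity boundary", {
  sh <- c(40, 40, 20)
  v <- array(0, sh)
  v[21:40, , ] <- 1
  part <- slic_superpixels(image3d(v, c(1, 1, 1)), array(TRUE, sh),
                           grid_size = 10, iterations = 2)
  # no region may straddle the boundary deeper than grid_size / 4
  depth <- sapply(seq_len(part$n_regions), function(k) {
    idx <- which(part$labels == k, arr.ind = TRUE)
    left <- idx[idx[, 1] <= 20, 1]
    right <- idx[idx[, 1] >= 21, 1]
    if (length(left) && length(right))
      min(length(unique(left)), length(unique(right))) else 0
  })
  expect_lte(max(depth), 10 / 4)
})

test_that("regions are spatially connected", {
  set.seed(3)
  sh <- c(30, 30, 15)
  v <- array(rnorm(prod(sh)), sh)
  part <- slic_superpixels(image3d(v, c(1, 1, 1)), array(TRUE, sh),
                           grid_size = 10, iterations = 2,
                           compactness = 0.1)
  comp <- array(darcyflow:::.cc_labels(as.integer(part$labels),
                                       as.integer(sh)), sh)
  for (k in seq_len(part$n_regions)) {
    expect_equal(length(unique(comp[part$labels == k])), 1)
  }
})

test_that("region speed refit recovers a homogeneous phantom exactly", {
  cfg <- tiny_config(block_speeds = rep(1, 8))
  ph <- build_phantom(cfg)
  sat <- normalize_to_saturation(
    enhancement(ph$series, compute_baseline(ph$series, 1)), ph$aif)
  tissue <- !ph$truth$vessel_mask
  part <- slic_superpixels(image3d(apply(sat$values, 1:3, mean),
                                   cfg$spacing), tissue, grid_size = 12)
  fit <- superpixel_speed_fit(sat, ph$aif, ph$truth$distance, part)
  expect_true(all(fit$valid))
  expect_true(all(abs(fit$alpha - 1) < 0.01))
  # a region of zero-enhancement voxels is flagged invalid
  sat0 <- sat
  sat0$values[] <- 0
  fit0 <- superpixel_speed_fit(sat0, ph$aif, ph$truth$distance, part)
  expect_false(any(fit0$valid))
})

test_that("Poiseuille gradient follows the quartic radius law", {
  g <- pressure_gradient_poiseuille(Q = 2.95e-6, R = 1.09e-3, mu = 3.5e-3)
  expect_equal(g, 18626.1, tolerance = 1e-4)   # hand-computed 8*mu*Q/(pi R^4)
  expect_equal(pressure_gradient_poiseuille(2 * 2.95e-6, 1.09e-3, 3.5e-3),
               2 * g)
  expect_equal(pressure_gradient_poiseuille(2.95e-6, 2 * 1.09e-3, 3.5e-3),
               g / 16)
  expect_error(pressure_gradient_poiseuille(-1, 1, 1), "positive")
})

test_that("permeability is linear in speed, quartic in radius", {
  R <- 1.09e-3; Q <- 2.95e-6
  expect_equal(permeability(0, R, Q), 0)
  expect_equal(permeability(1, R, Q), 1.8791e-7, tolerance = 1e-4)
  expect_equal(permeability(3, R, Q), 3 * permeability(1, R, Q))
  expect_equal(permeability(1, 2 * R, Q), 16 * permeability(1, R, Q))
  # invariant under joint scaling of speed and flow rate
  expect_equal(permeability(2, R, 2 * Q), permeability(1, R, Q))
})

test_that("viscosity cancels between the Darcy and Poiseuille forms", {
  R <- 8e-4; Q <- 2e-6; a <- 0.003
  for (mu in c(1e-3, 3.5e-3, 7e-3)) {
    gp <- pressure_gradient_poiseuille(Q, R, mu)
    expect_equal(permeability(a, R, Q), a * mu / gp, tolerance = 1e-12)
  }
})

test_that("mass-conservation flow rate handles constant and advective input", {
  # constant phi_nano = phi0: Q = V / T
  sh <- c(5, 5, 4)
  times <- seq(0, 30, 2)
  phi0 <- 0.2
  v <- array(phi0, c(sh, length(times)))
  img <- dynamic_image(v, c(1, 1, 1), times = times)
  inlet <- aif_curve(times, rep(phi0, length(times)))
  Q <- flow_rate_from_mass(img, array(TRUE, sh), inlet)
  V_m3 <- prod(sh) * 1e-9
  expect_equal(Q, V_m3 / 30, tolerance = 1e-12)
  # homogeneity: scaling all concentrations leaves Q unchanged
  img2 <- dynamic_image(3 * v, c(1, 1, 1), times = times)
  inlet2 <- aif_curve(times, 3 * inlet$saturation)
  expect_equal(flow_rate_from_mass(img2, array(TRUE, sh), inlet2), Q)
  # density cancels
  expect_equal(flow_rate_from_mass(img, array(TRUE, sh), inlet,
                                   density = 1060), Q)

  # 1D advection column: prescribed influx Q_true = a * A
  a_mm_s <- 2; phi <- 0.3
  times <- seq(0, 60, 1)
  nxs <- 200
  x <- (seq_len(nxs) - 0.5)            # mm, voxel centres
  sat_col <- t(sapply(x, function(xx)
    gamma_variate_aif(4, 3, 4, 1, times)$saturation * 0 +
      darcyflow:::gamma_variate(times - xx / a_mm_s, 4, 3, 4, 1)))
  vals <- array(0, c(nxs, 1, 1, length(times)))
  vals[, 1, 1, ] <- phi * sat_col
  col <- dynamic_image(vals, c(1, 1, 1), times = times)
  inlet <- aif_curve(times,
                     phi * darcyflow:::gamma_variate(times, 4, 3, 4, 1))
  Qhat <- flow_rate_from_mass(col, array(TRUE, c(nxs, 1, 1)), inlet)
  Q_true <- (a_mm_s * 1e-3) * (1e-3)^2  # speed m/s times face area m^2
  expect_lt(abs(Qhat - Q_true) / Q_true, 0.05)
  expect_error(flow_rate_from_mass(img, array(TRUE, sh),
                                   aif_curve(times, 0 * times)),
               "inlet")
})

test_that("blood volume is the AUC ratio and converges with refinement", {
  times <- seq(0, 58, 2)
  aif <- ref_gamma(times)
  sh <- c(2, 2, 1)
  v <- array(0, c(sh, length(times)))
  v[1, 1, 1, ] <- aif$saturation
  v[2, 1, 1, ] <- 0.5 * aif$saturation
  sat <- dynamic_image(v, c(1, 1, 1), times = times)
  bv <- blood_volume_map(sat, aif)
  expect_equal(bv$values[1, 1, 1], 1)
  expect_equal(bv$values[2, 1, 1], 0.5)
  expect_equal(bv$values[2, 2, 1], 0)
  # trapezoid BV approaches the fine-grid quadrature value
  fine_t <- seq(0, 58, 0.1)
  fine_aif <- ref_gamma(fine_t)
  shifted <- darcyflow:::gamma_variate(fine_t - 3, 4, 3, 4, 1)
  vf <- array(0, c(1, 1, 1, length(fine_t)))
  vf[1, 1, 1, ] <- shifted
  bv_fine <- blood_volume_map(dynamic_image(vf, c(1, 1, 1), fine_t),
                              fine_aif)$values[1, 1, 1]
  coarse <- seq(0, 58, 2)
  vc <- array(0, c(1, 1, 1, length(coarse)))
  vc[1, 1, 1, ] <- darcyflow:::gamma_variate(coarse - 3, 4, 3, 4, 1)
  bv_coarse <- blood_volume_map(dynamic_image(vc, c(1, 1, 1), coarse),
                                ref_gamma(coarse))$values[1, 1, 1]
  expect_lt(abs(bv_coarse - bv_fine), 0.02)
  expect_error(blood_volume_map(sat, aif_curve(times, 0 * times)), "area")
})

test_that("mean flow from blood volume integrates voxel volumes", {
  # BV = 1 over 1 mL with dt = 1 s gives 1 mL/s
  bv <- image3d(array(1, c(10, 10, 10)), c(1, 1, 1))
  expect_equal(mean_flow_from_bv(bv, dt = 1), 1e-6)
  expect_equal(mean_flow_from_bv(bv, dt = 0.5), 2e-6)
  set.seed(12)
  rv <- array(runif(4^3), c(4, 4, 4))
  bv2 <- image3d(rv, c(1.5, 1, 2))
  expect_equal(mean_flow_from_bv(bv2, dt = 2),
               sum(rv) * 3 * 1e-9 / 2)
  expect_error(mean_flow_from_bv(bv, dt = 0), "positive")
})
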