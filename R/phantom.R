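# Synthetic perfusion phantom. The forward model is the analytic solution of
# the 1D hyperbolic transport equation along vessel-normal characteristics:
# the tissue saturation at distance d from the feeding vessel is the arterial
# input delayed by the transit time d / a(x). Every inverse stage of the
# pipeline (baseline, enhancement, AIF, BAT, speed, superpixel fit) is
# therefore testable against exact ground truth.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Gamma-variate arterial input function
#'
#' The standard first-pass bolus shape,
#' `s(t) = A * ((t - t0) / (alpha * beta))^alpha * exp(alpha - (t - t0) / beta)`
#' for `t > t0` and 0 before; parameterised so its peak value is exactly
#' `amplitude`, attained at `t = t0 + alpha * beta`.
#'
#' @param t0 bolus arrival delay in s.
#' @param alpha dimensionless shape parameter, > 0.
#' @param beta scale parameter in s, > 0.
#' @param amplitude peak saturation, > 0.
#' @param times sample times in s.
#' @return an [aif_curve()].
#' @export
gamma_variate_aif <- function(t0, alpha, beta, amplitude, times) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0", call. = FALSE)
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  aif_curve(times, gamma_variate(times, t0, alpha, beta, amplitude))
}

# vectorised gamma-variate evaluation at arbitrary times
gamma_variate <- function(t, t0, alpha, beta, amplitude) {
  s <- numeric(length(t))
  ok <- t > t0
  tt <- t[ok] - t0
  s[ok] <- amplitude * (tt / (alpha * beta))^alpha * exp(alpha - tt / beta)
  s
}

#' Phantom configuration
#'
#' Defaults describe the reference validation phantom: a 60^3 voxel grid at
#' 1 mm isotropic spacing, 30 frames at 2 s spacing, a straight cylindrical
#' feeding vessel along the z axis through the grid centre, porosity 0.3, and
#' a 2x2x2 octant block structure of true flow speeds spanning 0.5-4 mm/s.
#'
#' @param shape grid dimensions in voxels.
#' @param spacing voxel size in mm.
#' @param vessel_radius vessel cylinder radius in mm.
#' @param vessel_axis axis the cylinder runs along (1, 2 or 3).
#' @param porosity tissue porosity in (0, 1).
#' @param block_speeds speeds in mm/s for the 8 octant blocks (recycled).
#' @param t0,alpha,beta,amplitude gamma-variate AIF parameters.
#' @param baseline pre-contrast tissue intensity in HU.
#' @param enh_amplitude peak enhancement scale C in HU (signal is
#'   `baseline + C * porosity * s_nano + noise`).
#' @param noise_sd additive Gaussian noise standard deviation in HU.
#' @param times frame times in s.
#' @param seed random seed used for the noise draw (mandatory for
#'   reproducibility).
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(60, 60, 60), spacing = c(1, 1, 1),
                           vessel_radius = 2, vessel_axis = 3,
                           porosity = 0.3,
                           block_speeds = seq(0.5, 4, length.out = 8),
                           t0 = 8, alpha = 3, beta = 4, amplitude = 1,
                           baseline = 40, enh_amplitude = 200,
                           noise_sd = 4, times = seq(0, by = 2,
                                                     length.out = 30),
                           seed = 1L) {
  if (vessel_radius <= 0) stop("vessel_radius must be > 0", call. = FALSE)
  if (porosity <= 0 || porosity >= 1)
    stop("porosity must lie in (0, 1)", call. = FALSE)
  if (any(block_speeds <= 0)) stop("speeds must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 vessel_radius = vessel_radius, vessel_axis = vessel_axis,
                 porosity = porosity, block_speeds = block_speeds,
                 t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude,
                 baseline = baseline, enh_amplitude = enh_amplitude,
                 noise_sd = noise_sd, times = times, seed = as.integer(seed)),
            class = "phantom_config")
}

# Octant block index (1..8) for each voxel relative to the grid centre.
octant_blocks <- function(shape) {
  ix <- seq_len(shape[1]) > shape[1] / 2
  iy <- seq_len(shape[2]) > shape[2] / 2
  iz <- seq_len(shape[3]) > shape[3] / 2
  bx <- array(ix, shape)
  by <- aperm(array(iy, shape[c(2, 1, 3)]), c(2, 1, 3))
  bz <- aperm(array(iz, shape[c(3, 1, 2)]), c(2, 3, 1))
  1L + bx + 2L * by + 4L * bz
}

# Straight-cylinder vessel mask through the grid centre.
cylinder_mask <- function(shape, spacing, radius, axis = 3,
                          center = NULL) {
  perp <- setdiff(1:3, axis)
  w1 <- axis_world(shape[perp[1]], spacing[perp[1]], 0)
  w2 <- axis_world(shape[perp[2]], spacing[perp[2]], 0)
  if (is.null(center)) center <- c(mean(w1), mean(w2))
  r2 <- outer((w1 - center[1])^2, (w2 - center[2])^2, "+")
  inplane <- r2 <= radius^2
  m <- array(FALSE, shape)
  idx <- which(inplane, arr.ind = TRUE)
  if (nrow(idx)) {
    for (k in seq_len(shape[axis])) {
      full <- matrix(0L, nrow(idx), 3)
      full[, perp[1]] <- idx[, 1]
      full[, perp[2]] <- idx[, 2]
      full[, axis] <- k
      m[full] <- TRUE
    }
  }
  m
}

#' Generate a synthetic 4D perfusion series with ground truth
#'
#' The voxel signal is
#' `I(x, t) = I_b + C * phi(x) * s_AIF(t - d(x) / a(x)) + eps`,
#' with `d(x)` the Euclidean distance to the vessel surface, `a(x)` the true
#' piecewise-constant flow speed, and `eps ~ N(0, sigma)` seeded. Vessel
#' voxels carry the undelayed arterial signal itself. Ground-truth saturation
#' and volume-fraction fields obey the mixture closure identities exactly:
#' saturations sum to one and the tissue/nano/blood fractions sum to one.
#'
#' @param config a [phantom_config()].
#' @return a list with elements `series` (a [dynamic_image()]), `labels`
#'   (a [label_map()] with vessel/tumor/parenchyma/aorta regions), `aif`
#'   (the generator [aif_curve()]), and `truth` (ground-truth fields:
#'   `speed`, `distance`, `porosity`, `vessel_mask`, `s_nano`, `s_blood`,
#'   `phi_tissue`, `phi_nano`, `phi_blood`).
#' @export
build_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  spacing <- config$spacing
  times <- config$times
  nf <- length(times)
  nv <- prod(shape)

  vessel <- cylinder_mask(shape, spacing, config$vessel_radius,
                          config$vessel_axis)
  if (!any(vessel)) stop("vessel mask is empty", call. = FALSE)

  dist <- edt3(vessel, shape, spacing)         # mm, 0 inside the vessel
  blocks <- octant_blocks(shape)
  speeds <- rep(config$block_speeds, length.out = 8)
  speed <- array(speeds[blocks], shape)
  if (any(speed <= 0)) stop("speed field must be positive", call. = FALSE)

  # porosity: phi in tissue, 1 inside the vessel (pure blood pool)
  phi <- array(config$porosity, shape)
  phi[vessel] <- 1

  # delayed saturation field: s_nano(x, t) = s_AIF(t - d / a); vessel d = 0
  delay <- as.vector(dist / speed)
  tq <- rep(times, each = nv) - delay          # nv * nf query times
  s_nano <- gamma_variate(tq, config$t0, config$alpha, config$beta,
                          config$amplitude)
  s_nano <- array(s_nano, c(shape, nf))

  signal <- config$baseline +
    config$enh_amplitude * as.vector(phi) * s_nano
  if (config$noise_sd > 0) {
    noise <- with_seed(config$seed,
                       rnorm(length(signal), 0, config$noise_sd))
    signal <- signal + noise
  }
  series <- dynamic_image(array(signal, c(shape, nf)), spacing = spacing,
                          times = times)

  aif <- gamma_variate_aif(config$t0, config$alpha, config$beta,
                           config$amplitude, times)

  # labels: vessel, plus an "aorta" ROI (one end slab of the vessel used for
  # AIF extraction), a small tumor block, parenchyma elsewhere
  lab <- array(3L, shape)
  lab[vessel] <- 1L
  ax <- config$vessel_axis
  slab <- slice.index(array(0, shape), ax) <= max(3L, shape[ax] %/% 10)
  lab[vessel & slab] <- 4L
  tm <- tumor_block(shape)
  lab[tm & !vessel] <- 2L
  labels <- label_map(lab, spacing = spacing)

  truth <- list(speed = image3d(speed, spacing),
                distance = image3d(dist, spacing),
                porosity = image3d(phi, spacing),
                vessel_mask = vessel,
                s_nano = s_nano,
                s_blood = 1 - s_nano,
                phi_tissue = 1 - phi,
                phi_nano = as.vector(phi) * s_nano,
                phi_blood = as.vector(phi) * (1 - s_nano),
                blocks = blocks)
  list(series = series, labels = labels, aif = aif, truth = truth,
       config = config)
}

# small off-centre block standing in for a tumor ROI
tumor_block <- function(shape) {
  m <- array(FALSE, shape)
  rng <- function(n, lo, hi) max(1, round(n * lo)):min(n, round(n * hi))
  m[rng(shape[1], 0.6, 0.8), rng(shape[2], 0.6, 0.8),
    rng(shape[3], 0.4, 0.6)] <- TRUE
  m
}

#' Generate a synthetic series from the extended Tofts forward model
#'
#' Each labelled region's enhancement curve is the extended Tofts solution
#' for that region's parameters; used for fit-recovery testing.
#'
#' @param region_params data.frame with columns `label`, `ktrans` (1/s),
#'   `ve`, `fpv`.
#' @param regions 3D integer array of region labels (0 = outside).
#' @param aif an [aif_curve()].
#' @param times frame times in s (defaults to the AIF samples).
#' @param spacing voxel size in mm.
#' @param baseline baseline intensity added to every voxel.
#' @param amplitude enhancement scale multiplying the Tofts curve.
#' @param noise_sd additive Gaussian noise sd (same units as `amplitude`).
#' @param seed noise seed.
#' @return a [dynamic_image()].
#' @export
build_tofts_phantom <- function(region_params, regions, aif,
                                times = aif$times, spacing = c(1, 1, 1),
                                baseline = 0, amplitude = 1, noise_sd = 0,
                                seed = 1L) {
  stopifnot(inherits(aif, "aif_curve"),
            all(c("label", "ktrans", "ve", "fpv") %in% names(region_params)))
  shape <- dim(regions)
  nf <- length(times)
  vals <- array(baseline, c(shape, nf))
  for (r in seq_len(nrow(region_params))) {
    p <- region_params[r, ]
    if (p$ktrans > 0 && p$ve <= 0)
      stop("ve must be > 0 when ktrans > 0", call. = FALSE)
    curve <- extended_tofts_forward(p$ktrans, p$ve, p$fpv, aif, times)
    sel <- which(regions == p$label)
    for (f in seq_len(nf))
      vals[sel + (f - 1) * prod(shape)] <-
        baseline + amplitude * curve[f]
  }
  if (noise_sd > 0)
    vals <- vals + with_seed(seed, rnorm(length(vals), 0, noise_sd))
  dynamic_image(vals, spacing = spacing, times = times)
}
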