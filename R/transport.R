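# The core estimators: voxelwise flow speed from distance over transit
# time, SLIC superpixels as a piecewise-constant speed basis, per-region
# model refits of the delayed-AIF transport solution, and the
# Darcy/Poiseuille permeability with flow-rate and blood-volume
# alternatives.

#' Voxelwise flow speed from distance and arrival time
#'
#' `a(x) = d(x) / (BAT(x) - inlet_bat)` in mm/s. The transit time is
#' referenced to the arterial (inlet) arrival so that injection delay does
#' not fold into the speed. Voxels with non-positive transit time or zero
#' distance (inside the vessel) are invalid.
#'
#' @param distance an [image3d()] distance map in mm.
#' @param bat a [bat_map()].
#' @param inlet_bat inlet (arterial) arrival time in s.
#' @return list of class `speed_field`: `values` ([image3d()], mm/s, `NA`
#'   where invalid) and `valid` (logical array).
#' @export
pixelwise_speed <- function(distance, bat, inlet_bat) {
  stopifnot(inherits(distance, "image3d"), inherits(bat, "bat_map"))
  if (!identical(dim(distance$values), dim(bat$values$values)))
    stop("distance and BAT maps are not on the same grid", call. = FALSE)
  transit <- bat$values$values - inlet_bat
  valid <- bat$valid & is.finite(transit) & transit > 0 &
    distance$values > 0
  a <- array(NA_real_, dim(distance$values))
  a[valid] <- distance$values[valid] / transit[valid]
  if (!any(valid))
    warning("no voxels with positive transit time: empty speed field")
  structure(list(values = image3d(a, spacing = distance$spacing,
                                  origin = distance$origin),
                 valid = valid),
            class = "speed_field")
}

#' @export
print.speed_field <- function(x, ...) {
  v <- x$values$values[x$valid]
  cat(sprintf("<speed_field> %d valid voxels, median %.3g mm/s\n",
              sum(x$valid), if (length(v)) median(v) else NA_real_))
  invisible(x)
}

#' SLIC superpixels on a masked volume
#'
#' Simple linear iterative clustering in joint (intensity, world-position)
#' feature space, restricted to the mask: seeds on a regular grid of
#' `grid_size` voxels, bounded window assignment, batch centre updates, and
#' a final connectivity enforcement (each region one 6-connected
#' component). Distances are spacing-aware; intensity is scaled by the
#' masked intensity range.
#'
#' @param reference an [image3d()] (typically the temporal-mean
#'   enhancement).
#' @param mask logical 3D array or [label_map()].
#' @param grid_size seed grid spacing in voxels.
#' @param iterations assignment/update sweeps.
#' @param compactness spatial regularisation weight; larger values give
#'   more compact, intensity-blind regions.
#' @return list of class `superpixel_partition`: `labels` (3D integer
#'   array, 0 outside the mask), `n_regions`, `sizes` (voxel counts), and
#'   `mean_volume_mm3`.
#' @export
slic_superpixels <- function(reference, mask, grid_size = 20,
                             iterations = 2, compactness = 0.1) {
  stopifnot(inherits(reference, "image3d"))
  m <- as_mask(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  sh <- dim(reference$values)
  sp <- reference$spacing
  x <- reference$values

  iscale <- diff(range(x[m]))
  if (!is.finite(iscale) || iscale <= 0) iscale <- 1
  s_mm <- grid_size * mean(sp)

  # world coordinates per axis
  wx <- axis_world(sh[1], sp[1], 0)
  wy <- axis_world(sh[2], sp[2], 0)
  wz <- axis_world(sh[3], sp[3], 0)

  # seed grid over the mask bounding box, cell centres
  bb <- apply(which(m, arr.ind = TRUE), 2, range)
  seeds <- list()
  for (a in 1:3) {
    lo <- bb[1, a]; hi <- bb[2, a]
    n <- max(1L, round((hi - lo + 1) / grid_size))
    seeds[[a]] <- round(seq(lo, hi, length.out = n + 1)[-1] -
                          (hi - lo + 1) / (2 * n))
  }
  cent <- as.matrix(expand.grid(seeds[[1]], seeds[[2]], seeds[[3]]))
  # keep seeds whose cell intersects the mask; snap each to a mask voxel
  keep <- logical(nrow(cent))
  half <- ceiling(grid_size / 2)
  for (c0 in seq_len(nrow(cent))) {
    rng <- lapply(1:3, function(a)
      max(1, cent[c0, a] - half):min(sh[a], cent[c0, a] + half))
    sub <- m[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    if (any(sub)) {
      keep[c0] <- TRUE
      if (!m[cent[c0, 1], cent[c0, 2], cent[c0, 3]]) {
        loc <- which(sub, arr.ind = TRUE)
        dd <- rowSums(sweep(loc, 2, (dim(sub) + 1) / 2)^2)
        b <- loc[which.min(dd), ]
        cent[c0, ] <- c(rng[[1]][b[1]], rng[[2]][b[2]], rng[[3]][b[3]])
      }
    }
  }
  cent <- cent[keep, , drop = FALSE]
  K <- nrow(cent)
  cw <- cbind(wx[cent[, 1]], wy[cent[, 2]], wz[cent[, 3]])
  ci <- x[cent]

  lab <- array(0L, sh)
  bestd <- array(Inf, sh)
  for (it in seq_len(iterations)) {
    lab[] <- 0L
    bestd[] <- Inf
    for (k in seq_len(K)) {
      rng <- lapply(1:3, function(a) {
        r <- round(grid_size)
        ctr <- which.min(abs(list(wx, wy, wz)[[a]] - cw[k, a]))
        max(1, ctr - r):min(sh[a], ctr + r)
      })
      sub <- m[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      if (!any(sub)) next
      xi <- x[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      dsub <- dim(sub)
      dx2 <- (wx[rng[[1]]] - cw[k, 1])^2
      dy2 <- (wy[rng[[2]]] - cw[k, 2])^2
      dz2 <- (wz[rng[[3]]] - cw[k, 3])^2
      sp2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      D2 <- ((xi - ci[k]) / iscale)^2 +
        compactness^2 * sp2 / s_mm^2
      D2[!sub] <- Inf
      cur <- bestd[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      upd <- D2 < cur
      if (any(upd)) {
        lsub <- lab[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
        lsub[upd] <- k
        cur[upd] <- D2[upd]
        lab[rng[[1]], rng[[2]], rng[[3]]] <- lsub
        bestd[rng[[1]], rng[[2]], rng[[3]]] <- cur
      }
    }
    # any masked voxel missed by every window: nearest centre spatially
    miss <- which(m & lab == 0L)
    if (length(miss)) {
      mi <- arrayInd(miss, sh)
      pw <- cbind(wx[mi[, 1]], wy[mi[, 2]], wz[mi[, 3]])
      for (q in seq_along(miss)) {
        d2 <- colSums((t(cw) - pw[q, ])^2)
        lab[miss[q]] <- which.min(d2)
      }
    }
    # batch centre update
    sel <- which(m)
    li <- lab[sel]
    ai <- arrayInd(sel, sh)
    for (k in unique(li)) {
      w <- li == k
      cw[k, ] <- c(mean(wx[ai[w, 1]]), mean(wy[ai[w, 2]]),
                   mean(wz[ai[w, 3]]))
      ci[k] <- mean(x[sel[w]])
    }
  }

  lab <- enforce_connectivity(lab, sh)
  # compact relabel 1..K'
  u <- sort(unique(lab[lab > 0L]))
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  lab[lab > 0L] <- lut[lab[lab > 0L]]
  sizes <- tabulate(lab[lab > 0L])
  structure(list(labels = lab, n_regions = length(sizes), sizes = sizes,
                 mean_volume_mm3 = mean(sizes) * prod(sp),
                 spacing = sp, origin = reference$origin),
            class = "superpixel_partition")
}

# Keep the largest 6-connected component of each label; reattach every
# orphan component to the most frequent neighbouring label.
enforce_connectivity <- function(lab, sh) {
  for (sweep_i in 1:10) {
    comp <- array(.cc_labels(as.integer(lab), as.integer(sh)), sh)
    tab <- table(comp[comp > 0], lab[comp > 0])
    # main component per label = largest component carrying that label
    comp_sizes <- tabulate(comp[comp > 0])
    comp_lab <- integer(max(comp))
    nz <- which(comp > 0)
    comp_lab[comp[nz]] <- lab[nz]
    main <- tapply(seq_along(comp_sizes), comp_lab[seq_along(comp_sizes)],
                   function(ids) ids[which.max(comp_sizes[ids])])
    orphan_ids <- setdiff(which(comp_sizes > 0), unlist(main))
    if (!length(orphan_ids)) break
    changed <- FALSE
    for (oc in orphan_ids) {
      vox <- which(comp == oc)
      nb_lab <- neighbor_labels(lab, comp, oc, vox, sh)
      if (length(nb_lab)) {
        tt <- sort(table(nb_lab), decreasing = TRUE)
        lab[vox] <- as.integer(names(tt)[1])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

neighbor_labels <- function(lab, comp, oc, vox, sh) {
  ai <- arrayInd(vox, sh)
  out <- integer(0)
  for (a in 1:3) for (s in c(-1L, 1L)) {
    ni <- ai
    ni[, a] <- ni[, a] + s
    ok <- ni[, a] >= 1 & ni[, a] <= sh[a]
    if (!any(ok)) next
    lin <- ni[ok, 1] + (ni[ok, 2] - 1) * sh[1] +
      (ni[ok, 3] - 1) * sh[1] * sh[2]
    sel <- lab[lin] > 0L & comp[lin] != oc
    out <- c(out, lab[lin][sel])
  }
  out
}

#' @export
print.superpixel_partition <- function(x, ...) {
  cat(sprintf("<superpixel_partition> %d regions, mean volume %.3g mm^3\n",
              x$n_regions, x$mean_volume_mm3))
  invisible(x)
}

#' Per-region flow speed by refitting the transport model
#'
#' For each superpixel, the region speed `alpha_i` minimises the squared
#' misfit between the observed saturation curves of member voxels and the
#' delayed arterial input `c_x * s_AIF(t - d(x) / alpha_i)`, where each
#' voxel's amplitude `c_x` is profiled out by linear least squares (the
#' amplitude carries the unknown porosity and proportionality constant;
#' only the delay carries speed). The search is a deterministic log-spaced
#' grid over `[a_min, a_max]` followed by local refinement.
#'
#' @param sat saturation-normalised [dynamic_image()].
#' @param aif an [aif_curve()].
#' @param distance an [image3d()] distance map (mm).
#' @param partition a [slic_superpixels()] result.
#' @param inlet_bat inlet arrival time (s) subtracted from the frame times
#'   so model and data share the arterial time origin; 0 keeps raw times.
#' @param a_range speed search bounds in mm/s.
#' @param n_grid number of log-spaced grid points.
#' @param max_voxels per-region cap on fitted voxels (deterministic
#'   stride subsampling) to bound runtime.
#' @return data.frame with columns `region`, `n_voxels`, `alpha` (mm/s),
#'   `valid`.
#' @export
superpixel_speed_fit <- function(sat, aif, distance, partition,
                                 inlet_bat = 0, a_range = c(0.1, 10),
                                 n_grid = 40, max_voxels = 400) {
  stopifnot(inherits(sat, "dynamic_image"), inherits(aif, "aif_curve"),
            inherits(distance, "image3d"),
            inherits(partition, "superpixel_partition"))
  times <- sat$times - inlet_bat
  nf <- length(times)
  sh <- dim(sat$values)[1:3]
  vox_mat <- matrix(sat$values, ncol = nf)
  alphas <- exp(seq(log(a_range[1]), log(a_range[2]),
                    length.out = n_grid))
  K <- partition$n_regions
  out <- data.frame(region = seq_len(K), n_voxels = 0L,
                    alpha = NA_real_, valid = FALSE)

  region_obj <- function(S, d, alpha) {
    # negative profiled gain: smaller is better
    tq <- rep(times, each = length(d)) - d / alpha
    mdl <- matrix(approx(aif$times, aif$saturation, xout = tq,
                         yleft = 0, yright = 0)$y, nrow = length(d))
    num <- rowSums(S * mdl)
    den <- rowSums(mdl * mdl)
    ok <- den > 0
    -sum(num[ok]^2 / den[ok])
  }

  for (k in seq_len(K)) {
    sel <- which(partition$labels == k)
    out$n_voxels[k] <- length(sel)
    if (!length(sel)) next
    S <- vox_mat[sel, , drop = FALSE]
    d <- distance$values[sel]
    keep <- rowSums(S * S) > 0 & d > 0
    S <- S[keep, , drop = FALSE]
    d <- d[keep]
    if (!nrow(S)) next
    if (nrow(S) > max_voxels) {
      stride <- seq(1, nrow(S), length.out = max_voxels)
      stride <- unique(round(stride))
      S <- S[stride, , drop = FALSE]
      d <- d[stride]
    }
    obj <- vapply(alphas, function(a) region_obj(S, d, a), numeric(1))
    j <- which.min(obj)
    lo <- alphas[max(1, j - 1)]
    hi <- alphas[min(n_grid, j + 1)]
    ref <- optimize(function(a) region_obj(S, d, a), lower = lo,
                    upper = hi, tol = 1e-4)
    out$alpha[k] <- ref$minimum
    out$valid[k] <- TRUE
  }
  out
}

#' Poiseuille pressure gradient
#'
#' Laminar tube flow: `grad(p) . n = 8 mu Q / (pi R^4)`.
#'
#' @param Q volumetric flow rate in m^3/s.
#' @param R vessel radius in m.
#' @param mu dynamic viscosity in Pa s (blood: 3.5e-3).
#' @return pressure gradient in Pa/m.
#' @export
pressure_gradient_poiseuille <- function(Q, R, mu) {
  if (any(Q <= 0) || any(R <= 0) || any(mu <= 0))
    stop("Q, R, mu must be positive", call. = FALSE)
  8 * mu * Q / (pi * R^4)
}

#' Darcy permeability from flow speed
#'
#' Combining Darcy's law `a = (kappa / mu) |grad p|` with the Poiseuille
#' gradient under a spatially homogeneous pressure-gradient assumption,
#' viscosity cancels analytically and `kappa = a pi R^4 / (8 Q)`.
#'
#' @param speed flow speed in m/s (scalar, array, or a `speed_field` whose
#'   mm/s values are converted internally).
#' @param R mean vessel radius in m.
#' @param Q volumetric flow rate in m^3/s.
#' @return permeability in m^2, same shape as `speed`.
#' @export
permeability <- function(speed, R, Q) {
  if (R <= 0 || Q <= 0) stop("R and Q must be positive", call. = FALSE)
  a <- if (inherits(speed, "speed_field"))
    mm_s_to_m_s(speed$values$values) else speed
  a * pi * R^4 / (8 * Q)
}

#' Flow rate from integral mass conservation
#'
#' `Q = m(T) / integral_0^T rho phi_nano_inlet dt`: the mass accumulated in
#' the tissue ROI at time `T` divided by the time-integrated inlet
#' nanoparticle fraction (trapezoid rule). Valid while `T` precedes transit
#' out of the ROI (inflow-only window).
#'
#' @param phi_nano a [dynamic_image()] whose values are the nanoparticle
#'   volume fraction (porosity times saturation).
#' @param roi logical 3D array or [label_map()] selecting the tissue.
#' @param inlet_curve an [aif_curve()] giving the inlet nanoparticle
#'   fraction versus time.
#' @param t_index frame index taken as `T` (default: last frame).
#' @param density fluid mass density in kg/m^3 (cancels; configurable).
#' @return flow rate in m^3/s.
#' @export
flow_rate_from_mass <- function(phi_nano, roi, inlet_curve,
                                t_index = length(phi_nano$times),
                                density = 1000) {
  stopifnot(inherits(phi_nano, "dynamic_image"),
            inherits(inlet_curve, "aif_curve"))
  m <- as_mask(roi)
  if (!any(m)) stop("ROI is empty", call. = FALSE)
  voxvol_m3 <- prod(phi_nano$spacing) * 1e-9
  frame <- phi_nano$values[, , , t_index]
  mass <- density * sum(frame[m]) * voxvol_m3          # kg
  tt <- inlet_curve$times
  upto <- tt <= phi_nano$times[t_index]
  denom <- density * trapz(tt[upto], inlet_curve$saturation[upto])
  if (!is.finite(denom) || denom <= 0)
    stop("zero inlet integral: flow rate undefined", call. = FALSE)
  mass / denom
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Blood volume map from area under the curve
#'
#' `BV(x) = integral phi_nano(x, t) dt / integral s_AIF(t) dt` by the
#' trapezoid rule on the sampled grid; dimensionless.
#'
#' @param sat a [dynamic_image()] of tissue nanoparticle fraction (or
#'   saturation) curves.
#' @param aif an [aif_curve()] with positive area under the curve.
#' @return an [image3d()] of dimensionless blood volume.
#' @export
blood_volume_map <- function(sat, aif) {
  stopifnot(inherits(sat, "dynamic_image"), inherits(aif, "aif_curve"))
  denom <- trapz(aif$times, aif$saturation)
  if (!is.finite(denom) || denom <= 0)
    stop("AIF area under the curve must be positive", call. = FALSE)
  nf <- dim(sat$values)[4]
  w <- trapz_weights(sat$times)
  vox <- matrix(sat$values, ncol = nf)
  bv <- as.vector(vox %*% w) / denom
  image3d(array(bv, dim(sat$values)[1:3]), spacing = sat$spacing,
          origin = sat$origin)
}

trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

#' Mean flow rate from a blood volume map
#'
#' `Q = (1 / dt) * integral_Omega BV(x) dV`, with the volume integral as a
#' voxel-volume-weighted sum.
#'
#' @param bv an [image3d()] of dimensionless blood volume.
#' @param dt time interval in s.
#' @param mask optional logical mask restricting the integral.
#' @return mean flow rate in m^3/s.
#' @export
mean_flow_from_bv <- function(bv, dt, mask = NULL) {
  stopifnot(inherits(bv, "image3d"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  v <- bv$values
  if (!is.null(mask)) v <- v[as_mask(mask)]
  voxvol_m3 <- prod(bv$spacing) * 1e-9
  sum(v) * voxvol_m3 / dt
}
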