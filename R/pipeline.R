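# End-to-end orchestration: baseline -> enhancement -> AIF -> BAT ->
# distance -> superpixels -> speed refit -> permeability -> Tofts control ->
# correlations. The result is a classed fit object; when an output
# directory is given, maps, per-region CSV tables, and a JSON manifest are
# written so reruns with the same configuration are byte-identical.

#' Pearson correlation between two maps at superpixel level
#'
#' Region means of both maps (over finite voxels) are correlated; a
#' voxelwise option exists for completeness.
#'
#' @param map_a,map_b [image3d()] objects on the same grid.
#' @param partition a [slic_superpixels()] result (ignored when
#'   `level = "voxel"`).
#' @param level `"region"` (default) or `"voxel"`.
#' @return list with `r`, `p` (two-sided, t-distribution), `n`.
#' @export
correlate_maps <- function(map_a, map_b, partition = NULL,
                           level = c("region", "voxel")) {
  stopifnot(inherits(map_a, "image3d"), inherits(map_b, "image3d"))
  level <- match.arg(level)
  if (level == "region") {
    stopifnot(inherits(partition, "superpixel_partition"))
    a <- region_means(map_a$values, partition)
    b <- region_means(map_b$values, partition)
  } else {
    ok <- is.finite(map_a$values) & is.finite(map_b$values)
    a <- map_a$values[ok]
    b <- map_b$values[ok]
  }
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3)
    stop("fewer than 3 valid pairs: correlation undefined", call. = FALSE)
  ct <- cor.test(a[ok], b[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

# per-region mean over finite voxels (NA when a region has none)
region_means <- function(values, partition) {
  lab <- partition$labels
  out <- rep(NA_real_, partition$n_regions)
  ok <- lab > 0L & is.finite(values)
  if (any(ok)) {
    s <- tapply(values[ok], lab[ok], mean)
    out[as.integer(names(s))] <- s
  }
  out
}

#' Mean permeability over a mask
#'
#' @param kappa an [image3d()] permeability map in m^2 (or a plain array).
#' @param mask logical 3D array or [label_map()].
#' @return mean permeability over valid (finite) masked voxels, in m^2.
#' @export
summarize_permeability <- function(kappa, mask = NULL) {
  v <- if (inherits(kappa, "image3d")) kappa$values else kappa
  if (!is.null(mask)) v <- v[as_mask(mask)]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no valid voxels", call. = FALSE)
  mean(v)
}

#' Fit the convective transport model to a dynamic series
#'
#' Runs the full estimation chain on a 4D contrast series with labelled
#' vessel/tissue/aorta regions and returns a classed fit holding the speed
#' field, the superpixel speeds, the permeability map, the extended Tofts
#' control parameters, and the correlation report.
#'
#' @param series a [dynamic_image()] in HU.
#' @param labels a [label_map()] with vessel, tumor, parenchyma and aorta
#'   labels.
#' @param n_pre number of pre-contrast frames for the baseline.
#' @param mu blood viscosity in Pa s.
#' @param Q_ml_min hepatic flow rate in ml/min (converted internally).
#' @param rho fluid density in kg/m^3.
#' @param grid_size,iterations,compactness superpixel parameters.
#' @param a_range speed search bounds in mm/s.
#' @param tofts_level `"region"` (fit superpixel-mean curves; default) or
#'   `"voxel"`.
#' @param cnr_min contrast-to-noise gate for arrival mapping: a voxel's
#'   peak enhancement must exceed `cnr_min` times the pre-contrast noise
#'   level (estimated from the `n_pre` baseline frames) for its arrival
#'   time to count. Set to 0 to disable.
#' @param vessel_radius_mm optional known vessel radius; when `NULL` it is
#'   estimated from the vessel mask by [estimate_mean_radius()].
#' @param out_dir optional output directory for maps, CSVs and manifest.
#' @return an object of class `darcy_run`.
#' @export
darcy_run <- function(series, labels, n_pre = 3, mu = 3.5e-3,
                      Q_ml_min = 177, rho = 1000, grid_size = 20,
                      iterations = 2, compactness = 0.1,
                      a_range = c(0.1, 10),
                      tofts_level = c("region", "voxel"), cnr_min = 3,
                      vessel_radius_mm = NULL, out_dir = NULL) {
  stopifnot(inherits(series, "dynamic_image"), inherits(labels, "label_map"))
  tofts_level <- match.arg(tofts_level)
  stages <- character(0)
  stage <- function(name) stages <<- c(stages, name)

  run <- list(constants = list(mu = mu, Q_ml_min = Q_ml_min,
                               Q_m3_s = ml_min_to_m3s(Q_ml_min),
                               rho = rho,
                               dt = mean(diff(series$times))))

  stage("baseline")
  base <- compute_baseline(series, n_pre)

  stage("enhancement")
  enh <- enhancement(series, base)

  stage("aif")
  aif <- extract_aif(enh, labels)
  sat <- normalize_to_saturation(enh, aif)
  inlet_bat <- bolus_arrival_time(aif$saturation, aif$times)
  if (is.na(inlet_bat))
    stop("stage aif: arterial arrival undefined", call. = FALSE)

  tissue <- label_mask(labels, "tumor") | label_mask(labels, "parenchyma")
  vessel <- label_mask(labels, "vessel") | label_mask(labels, "aorta")

  stage("bat")
  # pre-contrast frames of the normalised series are pure noise around 0;
  # their dispersion (bias-corrected for the subtracted mean) sets the
  # contrast-to-noise validity gate
  pre <- as.vector(sat$values[, , , seq_len(n_pre)][tissue])
  noise_hat <- sd(pre) * sqrt(n_pre / max(1, n_pre - 1))
  bat <- bat_map(sat, tissue, min_peak = cnr_min * noise_hat)

  stage("distance")
  dist <- distance_map(vessel, spacing = labels$spacing)

  stage("speed")
  speed <- pixelwise_speed(dist, bat, inlet_bat)

  stage("superpixels")
  mean_enh <- image3d(apply(sat$values, 1:3, mean), sat$spacing,
                      sat$origin)
  part <- slic_superpixels(mean_enh, tissue, grid_size = grid_size,
                           iterations = iterations,
                           compactness = compactness)

  stage("speed_fit")
  fit <- superpixel_speed_fit(sat, aif, dist, part, a_range = a_range)
  region_pixel_speed <- region_means(speed$values$values, part)

  stage("permeability")
  R_mm <- if (is.null(vessel_radius_mm))
    estimate_mean_radius(vessel, spacing = labels$spacing) else
      vessel_radius_mm
  Q <- run$constants$Q_m3_s
  kappa_vox <- permeability(speed, R_mm * 1e-3, Q)
  kappa_map <- image3d(kappa_vox, series$spacing, series$origin)
  kappa_region <- permeability(mm_s_to_m_s(fit$alpha), R_mm * 1e-3, Q)

  stage("tofts")
  tofts <- if (tofts_level == "voxel") {
    tm <- tofts_map(sat, aif, tissue)
    list(ktrans = region_means(tm$ktrans$values, part),
         ve = region_means(tm$ve$values, part),
         fpv = region_means(tm$fpv$values, part), maps = tm)
  } else {
    fit_region_tofts(sat, aif, part)
  }

  stage("correlations")
  rep_tab <- correlation_report(region_pixel_speed, fit$alpha, tofts)

  regions <- data.frame(region = fit$region, n_voxels = fit$n_voxels,
                        mean_distance_mm = region_means(dist$values, part),
                        pixel_speed_mm_s = region_pixel_speed,
                        alpha_mm_s = fit$alpha,
                        kappa_m2 = kappa_region,
                        ktrans = tofts$ktrans, ve = tofts$ve,
                        fpv = tofts$fpv)

  out <- structure(list(
    aif = aif, inlet_bat = inlet_bat, bat = bat, distance = dist,
    speed = speed, partition = part, regions = regions,
    correlations = rep_tab,
    kappa = kappa_map,
    kappa_mean = summarize_permeability(kappa_map, tissue),
    vessel_radius_mm = R_mm, constants = run$constants,
    stages = stages), class = "darcy_run")

  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

# region-level Tofts control: fit the mean curve of each superpixel
fit_region_tofts <- function(sat, aif, part) {
  nf <- dim(sat$values)[4]
  vox <- matrix(sat$values, ncol = nf)
  lab <- as.vector(part$labels)
  K <- part$n_regions
  ktrans <- ve <- fpv <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    sel <- lab == k
    if (!any(sel)) next
    curve <- colMeans(vox[sel, , drop = FALSE])
    f <- fit_extended_tofts(curve, aif, sat$times)
    ktrans[k] <- f$par["ktrans"]
    ve[k] <- f$par["ve"]
    fpv[k] <- f$par["fpv"]
  }
  list(ktrans = ktrans, ve = ve, fpv = fpv)
}

correlation_report <- function(pixel_speed, alpha, tofts) {
  pair <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0)
      return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- cor.test(a[ok], b[ok])
    c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }
  rows <- rbind(
    speed_vs_alpha = pair(pixel_speed, alpha),
    speed_vs_ktrans = pair(alpha, tofts$ktrans),
    speed_vs_ve = pair(alpha, tofts$ve),
    speed_vs_fpv = pair(alpha, tofts$fpv))
  data.frame(pair = rownames(rows), r = rows[, "r"], p = rows[, "p"],
             n = as.integer(rows[, "n"]), row.names = NULL)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_image3d(run$speed$values, file.path(out_dir, "speed_mm_s.nii.gz"))
  write_image3d(run$kappa, file.path(out_dir, "kappa_m2.nii.gz"))
  write_image3d(run$bat$values, file.path(out_dir, "bat_s.nii.gz"))
  write_image3d(run$distance, file.path(out_dir, "distance_mm.nii.gz"))
  utils::write.csv(run$regions, file.path(out_dir, "regions.csv"),
                   row.names = FALSE)
  utils::write.csv(run$correlations,
                   file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(time_s = run$aif$times,
                              s_aif = run$aif$saturation),
                   file.path(out_dir, "aif.csv"), row.names = FALSE)
  manifest <- list(stages = run$stages, constants = run$constants,
                   vessel_radius_mm = run$vessel_radius_mm,
                   inlet_bat_s = run$inlet_bat,
                   n_regions = run$partition$n_regions,
                   kappa_mean_m2 = run$kappa_mean)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the pipeline from a configuration list or file
#'
#' Thin wrapper over [darcy_run()]: reads the series and label map from
#' disk, applies the configured constants, and writes outputs.
#'
#' @param config a named list or path to a JSON/YAML-free JSON config with
#'   fields `series`, `labels`, `n_pre`, optional constants (`mu`,
#'   `Q_ml_min`, `rho`), superpixel settings, and `out_dir`.
#' @return a `darcy_run` object.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  series <- read_dynamic_image(config$series)
  labels <- read_label_map(config$labels)
  args <- config[names(config) %in%
                   names(formals(darcy_run))]
  args$series <- series
  args$labels <- labels
  do.call(darcy_run, args)
}

#' @export
print.darcy_run <- function(x, ...) {
  cat("Convective transport fit\n")
  cat(sprintf("  stages: %s\n", paste(x$stages, collapse = " -> ")))
  cat(sprintf("  %d superpixel regions; inlet BAT %.3g s; vessel radius %.3g mm\n",
              x$partition$n_regions, x$inlet_bat, x$vessel_radius_mm))
  cat(sprintf("  mean tissue permeability: %.3g m^2\n", x$kappa_mean))
  cat("  correlations (region level):\n")
  for (i in seq_len(nrow(x$correlations)))
    cat(sprintf("    %-16s r = %6.3f  (n = %d)\n",
                x$correlations$pair[i], x$correlations$r[i],
                x$correlations$n[i]))
  invisible(x)
}

#' @export
summary.darcy_run <- function(object, ...) {
  v <- object$speed$values$values[object$speed$valid]
  structure(list(
    n_regions = object$partition$n_regions,
    speed_quartiles_mm_s = quantile(v, c(0.25, 0.5, 0.75)),
    kappa_mean_m2 = object$kappa_mean,
    vessel_radius_mm = object$vessel_radius_mm,
    correlations = object$correlations,
    constants = object$constants), class = "summary.darcy_run")
}

#' @export
print.summary.darcy_run <- function(x, ...) {
  cat("Convective transport fit summary\n")
  cat(sprintf("  regions: %d\n", x$n_regions))
  q <- x$speed_quartiles_mm_s
  cat(sprintf("  pixelwise speed quartiles: %.3g / %.3g / %.3g mm/s\n",
              q[1], q[2], q[3]))
  cat(sprintf("  vessel radius: %.3g mm; mean permeability: %.3g m^2\n",
              x$vessel_radius_mm, x$kappa_mean_m2))
  print(x$correlations)
  invisible(x)
}

#' @export
coef.darcy_run <- function(object, ...) {
  setNames(object$regions$alpha_mm_s,
           paste0("alpha_", object$regions$region))
}

#' @export
plot.darcy_run <- function(x, ...) {
  ok <- is.finite(x$regions$pixel_speed_mm_s) &
    is.finite(x$regions$alpha_mm_s)
  plot.default(x$regions$pixel_speed_mm_s[ok], x$regions$alpha_mm_s[ok],
               xlab = "region-mean pixelwise speed [mm/s]",
               ylab = "refit region speed [mm/s]",
               main = "Superpixel speed consistency", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
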