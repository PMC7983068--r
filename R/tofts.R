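# Extended Tofts compartmental model: the control measurement. The tissue
# curve is the causal convolution of the arterial input with an exponential
# leakage kernel plus a fractional-plasma-volume passthrough:
#   s(t) = Ktrans * int_0^t sAIF(u) exp(-(Ktrans/ve)(t-u)) du + fpv sAIF(t)
# fpv is deliberately unconstrained in the fit: negative fitted values are
# an observed feature of per-voxel fits and must not be clamped away.

#' Extended Tofts forward model
#'
#' Causal trapezoid convolution on the sampled grid, evaluated by the
#' algebraically identical one-step exponential recurrence (stable for
#' small `ve`), plus `fpv * sAIF(t)`.
#'
#' @param ktrans influx volume transfer constant in 1/s, >= 0.
#' @param ve extravascular-extracellular volume fraction in (0, 1];
#'   required positive when `ktrans > 0`.
#' @param fpv fractional plasma volume (unbounded; may be negative).
#' @param aif an [aif_curve()].
#' @param times output sample times in s (default: the AIF samples; the
#'   AIF is linearly interpolated if they differ).
#' @return numeric vector of tissue saturations at `times`.
#' @export
extended_tofts_forward <- function(ktrans, ve, fpv, aif, times = aif$times) {
  stopifnot(inherits(aif, "aif_curve"))
  if (ktrans < 0) stop("ktrans must be >= 0", call. = FALSE)
  if (ktrans > 0 && ve <= 0)
    stop("ve must be > 0 when ktrans > 0", call. = FALSE)
  s <- if (identical(times, aif$times)) aif$saturation else
    approx(aif$times, aif$saturation, xout = times, yleft = 0,
           yright = aif$saturation[length(aif$saturation)])$y
  n <- length(times)
  conv <- numeric(n)
  if (ktrans > 0) {
    r <- ktrans / ve
    for (i in 2:n) {
      dt <- times[i] - times[i - 1]
      e <- exp(-r * dt)
      conv[i] <- e * conv[i - 1] + ktrans * dt * (s[i] + e * s[i - 1]) / 2
    }
  }
  conv + fpv * s
}

#' Fit the extended Tofts model to a tissue curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) over
#' `ktrans >= 0`, `ve in (1e-6, 1]`, `fpv` unbounded. The fit starts from
#' `init`; when the converged residual exceeds `restart_factor` times the
#' curve energy heuristic, additional deterministic starts are tried and
#' the best deviance wins. Non-convergence is flagged, not thrown.
#'
#' @param curve observed tissue saturations.
#' @param aif an [aif_curve()].
#' @param times sample times in s (>= 4 samples).
#' @param init starting values `c(ktrans, ve, fpv)`.
#' @param multi_start logical; try the fallback starts unconditionally.
#' @return object of class `tofts_fit`: `par` (named vector), `residual`
#'   (RSS), `converged`, plus data for the methods.
#' @export
fit_extended_tofts <- function(curve, aif, times = aif$times,
                               init = c(ktrans = 0.005, ve = 0.3,
                                        fpv = 0.05),
                               multi_start = FALSE) {
  stopifnot(inherits(aif, "aif_curve"))
  if (length(curve) < 4) stop("need >= 4 samples", call. = FALSE)
  if (all(curve == 0)) {
    par <- c(ktrans = 0, ve = unname(init[2]), fpv = 0)
    return(structure(list(par = par, residual = 0, converged = TRUE,
                          curve = curve, times = times, aif = aif),
                     class = "tofts_fit"))
  }
  resid_fn <- function(p)
    curve - extended_tofts_forward(p[1], p[2], p[3], aif, times)
  starts <- list(unname(init))
  fallback <- list(c(0.02, 0.2, 0.1), c(0.001, 0.5, 0.2),
                   c(0.05, 0.4, 0.01))
  run1 <- function(p0) {
    tryCatch(
      minpack.lm::nls.lm(par = p0, lower = c(0, 1e-6, -Inf),
                         upper = c(1, 1, Inf), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300)),
      error = function(e) NULL)
  }
  best <- run1(starts[[1]])
  need_more <- multi_start || is.null(best) ||
    best$deviance > 0.05 * sum(curve^2)
  if (need_more) {
    for (p0 in fallback) {
      f <- run1(p0)
      if (!is.null(f) && (is.null(best) || f$deviance < best$deviance))
        best <- f
    }
  }
  if (is.null(best)) {
    return(structure(list(par = c(ktrans = NA_real_, ve = NA_real_,
                                  fpv = NA_real_),
                          residual = NA_real_, converged = FALSE,
                          curve = curve, times = times, aif = aif),
                     class = "tofts_fit"))
  }
  par <- setNames(best$par, c("ktrans", "ve", "fpv"))
  structure(list(par = par, residual = best$deviance,
                 converged = best$info %in% 1:4,
                 curve = curve, times = times, aif = aif),
            class = "tofts_fit")
}

#' @export
print.tofts_fit <- function(x, ...) {
  cat("Extended Tofts fit\n")
  cat(sprintf("  ktrans = %.4g 1/s, ve = %.4g, fpv = %.4g\n",
              x$par["ktrans"], x$par["ve"], x$par["fpv"]))
  cat(sprintf("  RSS = %.4g, converged: %s\n", x$residual, x$converged))
  invisible(x)
}

#' @export
coef.tofts_fit <- function(object, ...) object$par

#' @export
predict.tofts_fit <- function(object, times = object$times, ...) {
  p <- object$par
  extended_tofts_forward(p[1], p[2], p[3], object$aif, times)
}

#' @export
residuals.tofts_fit <- function(object, ...) {
  object$curve - predict(object)
}

#' Voxelwise extended Tofts parameter maps
#'
#' Fits every masked voxel independently; per-voxel failures are flagged in
#' the validity mask, and voxel order does not affect the result.
#'
#' @param sat saturation-normalised [dynamic_image()].
#' @param aif an [aif_curve()].
#' @param mask logical 3D array or [label_map()].
#' @param init,multi_start passed to [fit_extended_tofts()].
#' @return list of class `tofts_param_maps`: `ktrans`, `ve`, `fpv`,
#'   `residual` ([image3d()] each) and `valid` (logical array).
#' @export
tofts_map <- function(sat, aif, mask,
                      init = c(ktrans = 0.005, ve = 0.3, fpv = 0.05),
                      multi_start = FALSE) {
  stopifnot(inherits(sat, "dynamic_image"))
  m <- as_mask(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  sh <- dim(sat$values)[1:3]
  nf <- dim(sat$values)[4]
  sel <- which(m)
  vox <- matrix(sat$values, ncol = nf)[sel, , drop = FALSE]
  maps <- list(ktrans = array(NA_real_, sh), ve = array(NA_real_, sh),
               fpv = array(NA_real_, sh), residual = array(NA_real_, sh))
  valid <- array(FALSE, sh)
  for (q in seq_along(sel)) {
    f <- fit_extended_tofts(vox[q, ], aif, sat$times, init = init,
                            multi_start = multi_start)
    if (all(is.finite(f$par))) {
      maps$ktrans[sel[q]] <- f$par["ktrans"]
      maps$ve[sel[q]] <- f$par["ve"]
      maps$fpv[sel[q]] <- f$par["fpv"]
      maps$residual[sel[q]] <- f$residual
      valid[sel[q]] <- f$converged
    }
  }
  structure(list(ktrans = image3d(maps$ktrans, sat$spacing, sat$origin),
                 ve = image3d(maps$ve, sat$spacing, sat$origin),
                 fpv = image3d(maps$fpv, sat$spacing, sat$origin),
                 residual = image3d(maps$residual, sat$spacing,
                                    sat$origin),
                 valid = valid),
            class = "tofts_param_maps")
}
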