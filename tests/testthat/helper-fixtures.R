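# Small in-code fixtures shared across test files.

# a tiny fast phantom: 24^3 grid, 20 frames; vessel radius 1.5 mm
tiny_config <- function(..., shape = c(24, 24, 24),
                        times = seq(0, by = 2, length.out = 20),
                        vessel_radius = 1.5, t0 = 4, noise_sd = 0,
                        seed = 11L) {
  phantom_config(shape = shape, times = times,
                 vessel_radius = vessel_radius, t0 = t0,
                 noise_sd = noise_sd, seed = seed, ...)
}

# digital cylinder mask along one axis through the in-plane grid centre
make_cylinder <- function(shape, spacing, radius_mm, axis = 3) {
  perp <- setdiff(1:3, axis)
  w1 <- (seq_len(shape[perp[1]]) - 1) * spacing[perp[1]]
  w2 <- (seq_len(shape[perp[2]]) - 1) * spacing[perp[2]]
  r2 <- outer((w1 - mean(w1))^2, (w2 - mean(w2))^2, "+")
  inplane <- r2 <= radius_mm^2
  m <- array(FALSE, shape)
  for (k in seq_len(shape[axis])) {
    idx <- which(inplane, arr.ind = TRUE)
    full <- matrix(0L, nrow(idx), 3)
    full[, perp[1]] <- idx[, 1]
    full[, perp[2]] <- idx[, 2]
    full[, axis] <- k
    m[full] <- TRUE
  }
  m
}

# brute-force nearest-vessel distance over every voxel pair
brute_distance <- function(mask, spacing) {
  sh <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  w <- sweep(idx - 1, 2, spacing, "*")
  q <- arrayInd(seq_len(prod(sh)), sh)
  qw <- sweep(q - 1, 2, spacing, "*")
  array(apply(qw, 1, function(p) sqrt(min(colSums((t(w) - p)^2)))), sh)
}

# brute-force peak-gradient arrival: earliest interval with maximal slope
brute_bat <- function(curve, times) {
  best <- -Inf
  at <- NA_real_
  for (i in seq_len(length(curve) - 1)) {
    s <- (curve[i + 1] - curve[i]) / (times[i + 1] - times[i])
    if (is.finite(s) && s > best) {
      best <- s
      at <- times[i]
    }
  }
  if (!is.finite(best) || best <= 0) NA_real_ else at
}

ref_gamma <- function(times, t0 = 4, alpha = 3, beta = 4, A = 1) {
  gamma_variate_aif(t0, alpha, beta, A, times)
}
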