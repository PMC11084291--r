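#' Synthetic Poiseuille flow fixture
#'
#' Steady Hagen-Poiseuille pipe flow sampled on a cell-centered Cartesian
#' grid: `u_z(r) = dP (R^2 - r^2) / (4 mu L)`. The stored velocity is the
#' full parabola (not clamped at the wall) and the lumen is carried in the
#' quadrature weights: each cell's volume measure is scaled by its
#' sub-sampled coverage fraction of the disc `r < R`, so finite-difference
#' gradients of the field are exact and the only discretisation error in
#' integrated quantities is the quadrature of the mask. The attached
#' manifest records the closed forms: flow rate `Q = pi R^4 dP / (8 mu L)`,
#' wall shear `tau_w = dP R / (2 L)`, maximum velocity, and dissipation
#' rate `dP * Q`.
#'
#' @param R Tube radius (m).
#' @param L Tube length (m).
#' @param dP Driving pressure difference (Pa).
#' @param constants A [blood_properties()].
#' @param dims Grid resolution `c(nx, ny, nz)` over `[-R, R]^2 x [0, L]`,
#'   at least 8 per axis.
#' @param times Time samples (the flow is steady; default `c(0, 1)` s).
#' @param coverage_subsample Sub-samples per cell edge for the lumen
#'   coverage fraction (default 4).
#' @return List with `field` (a [vector_field_series()]) and `manifest`
#'   (kind, params, analytic record).
#' @export
#' @examples
#' fx <- make_poiseuille(dims = c(16, 16, 8))
#' fx$manifest$analytic$Q
make_poiseuille <- function(R = 0.01, L = 0.1, dP = 100,
                            constants = blood_properties(),
                            dims = c(32, 32, 8), times = c(0, 1),
                            coverage_subsample = 4) {
  if (R <= 0 || L <= 0 || dP < 0) stop("require R, L > 0 and dP >= 0")
  if (any(dims < 8)) stop("grid too coarse: need at least 8 cells per axis")
  dims <- as.integer(dims)
  hx <- 2 * R / dims[1]; hy <- 2 * R / dims[2]; hz <- L / dims[3]
  xs <- -R + (seq_len(dims[1]) - 0.5) * hx
  ys <- -R + (seq_len(dims[2]) - 0.5) * hy
  zs <- (seq_len(dims[3]) - 0.5) * hz
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  mu <- constants$mu
  uz <- dP * (R^2 - pts[, 1]^2 - pts[, 2]^2) / (4 * mu * L)
  # lumen coverage per (x, y) cell, sub-sampled
  s <- coverage_subsample
  off <- (seq_len(s) - 0.5) / s - 0.5
  cover_xy <- matrix(0, dims[1], dims[2])
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      sx <- xs[i] + off * hx
      sy <- ys[j] + off * hy
      rr <- outer(sx^2, sy^2, `+`)
      cover_xy[i, j] <- mean(rr < R^2)
    }
  }
  cover <- rep(as.numeric(cover_xy), dims[3])
  measure <- cover * hx * hy * hz
  nt <- length(times)
  np <- nrow(pts)
  vecs <- array(0, c(nt, np, 3))
  for (ti in seq_len(nt)) vecs[ti, , 3] <- uz
  Q <- pi * R^4 * dP / (8 * mu * L)
  field <- vector_field_series(times, pts, vecs, measure, kind = "velocity",
                               grid = list(dims = dims,
                                           spacing = c(hx, hy, hz),
                                           origin = c(xs[1], ys[1], zs[1])))
  list(field = field,
       manifest = list(kind = "poiseuille", seed = NULL,
                       params = list(R = R, L = L, dP = dP, mu = mu,
                                     dims = dims),
                       analytic = list(Q = Q,
                                       tau_wall = dP * R / (2 * L),
                                       u_max = dP * R^2 / (4 * mu * L),
                                       u_mean = dP * R^2 / (8 * mu * L),
                                       dissipation_rate = dP * Q)))
}

#' Synthetic solid-body rotation fixture
#'
#' `u = Omega x r` on a cell-centered cube grid. The analytic record
#' carries `|curl u| = 2 |Omega|` and zero viscous dissipation (a rigid
#' motion has no strain).
#'
#' @param omega Angular velocity vector (rad/s); a scalar means rotation
#'   about +z.
#' @param extent Half-width of the cube domain (m).
#' @param dims Grid resolution per axis (single integer or length 3).
#' @param times Time samples (steady; default `c(0, 1)` s).
#' @return List with `field` and `manifest` as in [make_poiseuille()].
#' @export
make_solid_rotation <- function(omega = 5, extent = 0.05, dims = 16,
                                times = c(0, 1)) {
  if (length(omega) == 1L) omega <- c(0, 0, omega)
  if (any(!is.finite(omega))) stop("'omega' must be finite")
  dims <- as.integer(rep_len(dims, 3L))
  if (any(dims < 8)) stop("grid too coarse: need at least 8 cells per axis")
  h <- 2 * extent / dims
  ax <- lapply(1:3, function(k) -extent + (seq_len(dims[k]) - 0.5) * h[k])
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  u <- cbind(omega[2] * pts[, 3] - omega[3] * pts[, 2],
             omega[3] * pts[, 1] - omega[1] * pts[, 3],
             omega[1] * pts[, 2] - omega[2] * pts[, 1])
  nt <- length(times)
  vecs <- array(0, c(nt, nrow(pts), 3))
  for (ti in seq_len(nt)) vecs[ti, , ] <- u
  field <- vector_field_series(times, pts, vecs,
                               rep(prod(h), nrow(pts)), kind = "velocity",
                               grid = list(dims = dims, spacing = h,
                                           origin = vapply(ax, `[`, numeric(1), 1L)))
  list(field = field,
       manifest = list(kind = "solid_rotation", seed = NULL,
                       params = list(omega = omega, extent = extent,
                                     dims = dims),
                       analytic = list(curl_mag = 2 * sqrt(sum(omega^2)),
                                       dissipation_rate = 0)))
}

#' Synthetic oscillating wall-shear fixture
#'
#' Wall-shear vectors with a prescribed direction program on a flat patch
#' of equal-area points, designed so target OSI values are constructible in
#' closed form. `pattern = "square"` holds direction `+e` for the first
#' `1 - reversal_fraction` of the cycle and `-e` for the rest (samples at
#' the switch get the jump midpoint 0, keeping the discrete vector
#' integral consistent with the closed form); the expected OSI is
#' `0.5 * (1 - |1 - 2 f|)`. `pattern = "rotating"` rotates the vector
#' uniformly in the patch plane at constant magnitude; expected OSI 0.5.
#'
#' @param amplitude Shear magnitude A (Pa), `>= 0`.
#' @param reversal_fraction Fraction f of the cycle in reversed direction
#'   (square pattern), in `[0, 1]`.
#' @param period Cycle length (s).
#' @param n_points Points on the patch.
#' @param nt Time samples over the closed cycle (default 401).
#' @param pattern `"square"` or `"rotating"`.
#' @return List with `field` (wall-shear [vector_field_series()]) and
#'   `manifest` carrying the expected OSI and TAWSS.
#' @export
make_oscillating_wss <- function(amplitude = 2, reversal_fraction = 0,
                                 period = 1, n_points = 25, nt = 401,
                                 pattern = c("square", "rotating")) {
  pattern <- match.arg(pattern)
  if (amplitude < 0) stop("'amplitude' must be non-negative")
  if (reversal_fraction < 0 || reversal_fraction > 1) {
    stop("'reversal_fraction' must lie in [0, 1]")
  }
  side <- ceiling(sqrt(n_points))
  g <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(n_points), ]
  pts <- cbind(g$x * 1e-3, g$y * 1e-3, 0)
  times <- seq(0, period, length.out = nt)
  vecs <- array(0, c(nt, n_points, 3))
  if (pattern == "rotating") {
    phase <- 2 * pi * times / period
    for (ti in seq_len(nt)) {
      vecs[ti, , 1] <- amplitude * cos(phase[ti])
      vecs[ti, , 2] <- amplitude * sin(phase[ti])
    }
    expected_osi <- if (amplitude > 0) 0.5 else 0
    expected_tawss <- amplitude
  } else {
    t_switch <- (1 - reversal_fraction) * period
    sgn <- ifelse(times < t_switch - 1e-12, 1,
                  ifelse(abs(times - t_switch) <= 1e-12, 0, -1))
    for (ti in seq_len(nt)) vecs[ti, , 1] <- amplitude * sgn[ti]
    expected_osi <- if (amplitude > 0) {
      0.5 * (1 - abs(1 - 2 * reversal_fraction))
    } else 0
    expected_tawss <- amplitude
  }
  field <- vector_field_series(times, pts, vecs,
                               rep(1e-6, n_points), kind = "wall_shear")
  list(field = field,
       manifest = list(kind = "oscillating_wss", seed = NULL,
                       params = list(amplitude = amplitude,
                                     reversal_fraction = reversal_fraction,
                                     period = period, pattern = pattern),
                       analytic = list(osi = expected_osi,
                                       tawss = expected_tawss)))
}

#' Noisy samples of a Fourier waveform
#'
#' Evaluates a Fourier series on a uniform grid over one period and adds
#' i.i.d. Gaussian noise, reproducibly for a given seed.
#'
#' @param series A [fourier_series()].
#' @param sigma Noise standard deviation (waveform units), `>= 0`.
#' @param n Number of samples; must be at least `2 * n_harmonics + 1`.
#' @param seed Integer seed recorded in the manifest.
#' @return List with `samples` (a [waveform_samples()]) and `manifest`.
#' @export
make_noisy_waveform <- function(series, sigma = 0, n = 128, seed = 1) {
  stopifnot(inherits(series, "fourier_series"))
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (n < 2 * length(series$a) + 1) {
    stop("'n' must be at least 2 * n_harmonics + 1")
  }
  period <- fs_period(series)
  tt <- seq(0, period, length.out = n + 1L)[-(n + 1L)]
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  noise <- stats::rnorm(n, sd = sigma)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(samples = waveform_samples(tt, eval_fourier(series, tt) + noise,
                                  period),
       manifest = list(kind = "noisy_waveform", seed = seed,
                       params = list(sigma = sigma, n = n)))
}
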