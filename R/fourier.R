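#' Truncated Fourier series waveform
#'
#' Periodic waveform of the form
#' \deqn{V(t) = a_0 + \sum_{n=1}^{N} a_n \cos(n \omega t) + \sum_{n=1}^{N} b_n \sin(n \omega t)}
#' used throughout the package to represent inlet boundary waveforms (pump
#' outflow-graft flow and native cardiac ejection). `a0` is the offset (the
#' cycle mean), `a` and `b` the cosine/sine coefficients, and `omega` the
#' fundamental angular frequency in rad/s, so the period is `2*pi/omega`.
#'
#' @param a0 Offset term (waveform units).
#' @param a Cosine coefficients (length `n_terms`; may be empty).
#' @param b Sine coefficients (same length as `a`).
#' @param omega Fundamental angular frequency (rad/s), strictly positive.
#' @return An object of class `fourier_series`.
#' @seealso [eval_fourier()], [fit_fourier()]
#' @export
#' @examples
#' fs <- fourier_series(a0 = 1, a = c(0.5, 0), b = c(0, 0.25), omega = 2 * pi)
#' eval_fourier(fs, seq(0, 1, by = 0.25))
fourier_series <- function(a0, a = numeric(), b = numeric(), omega) {
  if (!is.numeric(a0) || length(a0) != 1L || !is.finite(a0)) {
    stop("'a0' must be a single finite number")
  }
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("'a' and 'b' must have the same length")
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0) {
    stop("'omega' must be a single positive number")
  }
  structure(list(a0 = a0, a = a, b = b, omega = omega),
            class = "fourier_series")
}

#' @export
print.fourier_series <- function(x, ...) {
  cat(sprintf("Fourier series: %d harmonics, period %.4g s, mean %.4g\n",
              length(x$a), fs_period(x), x$a0))
  invisible(x)
}

#' Period of a Fourier series
#'
#' @param series A [fourier_series()].
#' @return The period `2*pi/omega` in seconds.
#' @export
fs_period <- function(series) 2 * pi / series$omega

#' Evaluate a Fourier series
#'
#' @param series A [fourier_series()].
#' @param t Times (s) at which to evaluate; any real values (the series is
#'   periodic by construction).
#' @return Numeric vector of waveform values, same length as `t`.
#' @export
eval_fourier <- function(series, t) {
  stopifnot(inherits(series, "fourier_series"))
  n <- length(series$a)
  v <- rep.int(series$a0, length(t))
  if (n > 0L) {
    wt <- series$omega * t
    for (k in seq_len(n)) {
      v <- v + series$a[k] * cos(k * wt) + series$b[k] * sin(k * wt)
    }
  }
  v
}

#' @export
predict.fourier_series <- function(object, t, ...) eval_fourier(object, t)

#' Sampled waveform over one period
#'
#' Container for discrete waveform samples used for Fourier fitting: sample
#' times must be strictly increasing and lie within one stated period.
#'
#' @param t Sample times (s), strictly increasing, within `[0, period]`.
#' @param value Sample values (same length as `t`).
#' @param period Waveform period (s), strictly positive.
#' @return An object of class `waveform_samples`.
#' @export
waveform_samples <- function(t, value, period) {
  t <- as.numeric(t)
  value <- as.numeric(value)
  if (length(t) != length(value)) stop("'t' and 'value' lengths differ")
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing")
  if (!is.numeric(period) || length(period) != 1L || period <= 0) {
    stop("'period' must be a single positive number")
  }
  if (min(t) < 0 || max(t) > period + 1e-12) {
    stop("'t' must lie within [0, period]")
  }
  structure(list(t = t, value = value, period = period),
            class = "waveform_samples")
}

#' Least-squares Fourier fit of sampled data
#'
#' Fits an `n_terms`-harmonic Fourier series to waveform samples by ordinary
#' least squares on the design matrix of sines and cosines (so non-uniform
#' sampling is supported). On a uniform grid covering one full period the
#' fitted `a0` equals the sample mean (the trigonometric columns are
#' orthogonal to the intercept there).
#'
#' @param samples A [waveform_samples()] object.
#' @param n_terms Number of harmonics (default 8). Requires at least
#'   `2 * n_terms + 1` samples.
#' @return A [fourier_series()] with `omega = 2*pi/period`.
#' @export
#' @examples
#' tt <- seq(0, 1, length.out = 65)[-65]
#' s <- waveform_samples(tt, sin(2 * pi * tt), period = 1)
#' fit <- fit_fourier(s, n_terms = 4)
#' fit$b[1] # ~1
fit_fourier <- function(samples, n_terms = 8) {
  stopifnot(inherits(samples, "waveform_samples"))
  if (!is.numeric(n_terms) || length(n_terms) != 1L || n_terms < 0 ||
      n_terms != round(n_terms)) {
    stop("'n_terms' must be a non-negative integer")
  }
  n_terms <- as.integer(n_terms)
  m <- length(samples$t)
  if (m < 2L * n_terms + 1L) {
    stop(sprintf("underdetermined fit: %d samples for %d coefficients; need >= %d",
                 m, 2L * n_terms + 1L, 2L * n_terms + 1L))
  }
  omega <- 2 * pi / samples$period
  X <- matrix(1, nrow = m, ncol = 2L * n_terms + 1L)
  if (n_terms > 0L) {
    for (k in seq_len(n_terms)) {
      X[, 1L + k] <- cos(k * omega * samples$t)
      X[, 1L + n_terms + k] <- sin(k * omega * samples$t)
    }
  }
  beta <- qr.coef(qr(X), samples$value)
  beta[is.na(beta)] <- 0
  fourier_series(a0 = beta[1L],
                 a = if (n_terms > 0L) beta[2L:(n_terms + 1L)] else numeric(),
                 b = if (n_terms > 0L) beta[(n_terms + 2L):(2L * n_terms + 1L)] else numeric(),
                 omega = omega)
}

#' Serialize / deserialize a Fourier series as JSON
#'
#' @param series A [fourier_series()].
#' @param path File path for the JSON representation `{a0, a, b, omega}`.
#' @return `write_fourier_json` returns `path` invisibly; `read_fourier_json`
#'   returns a [fourier_series()].
#' @export
write_fourier_json <- function(series, path) {
  stopifnot(inherits(series, "fourier_series"))
  jsonlite::write_json(list(a0 = series$a0, a = series$a, b = series$b,
                            omega = series$omega),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fourier_json
#' @export
read_fourier_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fourier_series(a0 = x$a0, a = x$a, b = x$b, omega = x$omega)
}
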