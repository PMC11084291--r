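#' HeartMate III artificial-pulse speed schedule
#'
#' The HMIII controller superimposes a programmed "artificial pulse" on its
#' continuous rotation: every cycle the pump drops its set speed by
#' `drop_rpm` for `drop_dur` seconds, then rises by `rise_rpm` *from the
#' reduced speed* for `rise_dur` seconds, then returns to the set speed for
#' `rest_dur` seconds. Defaults reproduce the published schedule
#' (-2000 rpm for 0.15 s, +4000 rpm for 0.2 s, set speed for 1.65 s; 2 s
#' cycle). The alternative reading of the rise (+4000 above the set speed)
#' can be expressed by passing `rise_rpm = drop_rpm + 4000`.
#'
#' @param base_rpm Pump set speed (rpm). Typical clinical band 5000-6000 rpm;
#'   out-of-band values trigger a warning, not an error.
#' @param drop_rpm Speed decrease during the drop phase (rpm).
#' @param drop_dur Drop phase duration (s).
#' @param rise_rpm Speed increase from the reduced speed (rpm).
#' @param rise_dur Rise phase duration (s).
#' @param rest_dur Remainder of the cycle at set speed (s).
#' @param valid_band Length-2 numeric; warn when `base_rpm` falls outside.
#' @return Object of class `pulse_schedule`; its cycle period is
#'   `drop_dur + rise_dur + rest_dur`.
#' @export
#' @examples
#' sch <- pulse_schedule()
#' schedule_period(sch) # 2 s
pulse_schedule <- function(base_rpm = 5500, drop_rpm = 2000, drop_dur = 0.15,
                           rise_rpm = 4000, rise_dur = 0.2, rest_dur = 1.65,
                           valid_band = c(5000, 6000)) {
  durs <- c(drop_dur, rise_dur, rest_dur)
  if (any(!is.finite(durs)) || any(durs < 0)) {
    stop("phase durations must be non-negative finite numbers")
  }
  if (sum(durs) <= 0) stop("schedule period must be positive")
  if (base_rpm < valid_band[1] || base_rpm > valid_band[2]) {
    warning(sprintf("base_rpm %.0f outside the typical band [%.0f, %.0f] rpm",
                    base_rpm, valid_band[1], valid_band[2]))
  }
  structure(list(base_rpm = base_rpm, drop_rpm = drop_rpm,
                 drop_dur = drop_dur, rise_rpm = rise_rpm,
                 rise_dur = rise_dur, rest_dur = rest_dur),
            class = "pulse_schedule")
}

#' @rdname pulse_schedule
#' @param schedule A `pulse_schedule`.
#' @export
schedule_period <- function(schedule) {
  schedule$drop_dur + schedule$rise_dur + schedule$rest_dur
}

#' Instantaneous pump speed under the artificial pulse
#'
#' Piecewise-constant, periodic speed profile: reduced speed on
#' `[0, drop_dur)`, reduced + `rise_rpm` on `[drop_dur, drop_dur+rise_dur)`,
#' set speed for the rest of the cycle.
#'
#' @param t Times (s), `t >= 0`; vectorised.
#' @param schedule A [pulse_schedule()].
#' @return Pump speed (rpm), same length as `t`.
#' @export
hm3_speed <- function(t, schedule = pulse_schedule()) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (any(t < 0)) stop("'t' must be non-negative")
  period <- schedule_period(schedule)
  # snap to a 1 ns quantum so phase boundaries survive floating modulo
  tl <- round(t %% period, 9)
  tl[tl >= period] <- 0
  low <- schedule$base_rpm - schedule$drop_rpm
  ifelse(tl < schedule$drop_dur, low,
         ifelse(tl < schedule$drop_dur + schedule$rise_dur,
                low + schedule$rise_rpm, schedule$base_rpm))
}

#' Outflow-graft flow waveform from the artificial-pulse schedule
#'
#' Maps the pump speed schedule to a volumetric flow waveform by a linear
#' speed-to-flow calibration pinned so the cycle mean equals `mean_flow`
#' (flow proportional to instantaneous speed), then fits an `n_terms`
#' Fourier series on a uniform grid over one cycle. The published Fourier
#' coefficients for the echocardiography-derived graft velocity are not
#' available, so the calibrated schedule shape with the matched mean is the
#' reproducible stand-in: shape and cycle mean are what the downstream 0D
#' network consumes.
#'
#' @param schedule A [pulse_schedule()].
#' @param mean_flow Target cycle-mean flow (m^3/s), strictly positive.
#' @param n_terms Harmonics in the fit (default 8).
#' @param n_samples Samples per cycle for the fit grid (default 800; a
#'   multiple of the phase fractions so phase boundaries fall on samples).
#' @return A [fourier_series()] whose cycle mean equals `mean_flow` to
#'   within 0.1%.
#' @export
#' @examples
#' og <- og_flow_waveform(pulse_schedule(), mean_flow = 6.7e-5)
#' og$a0 # ~6.7e-5
og_flow_waveform <- function(schedule = pulse_schedule(), mean_flow,
                             n_terms = 8, n_samples = 800) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (!is.numeric(mean_flow) || length(mean_flow) != 1L || mean_flow <= 0) {
    stop("'mean_flow' must be a single positive flow (m^3/s)")
  }
  period <- schedule_period(schedule)
  tt <- seq(0, period, length.out = n_samples + 1L)[-(n_samples + 1L)]
  speed <- hm3_speed(tt, schedule)
  flow <- mean_flow * speed / mean(speed)
  fit_fourier(waveform_samples(tt, flow, period), n_terms = n_terms)
}

#' Residual native cardiac waveform in chronic heart failure
#'
#' Builds a half-sine ejection template — zero in diastole, a non-negative
#' half-sine lobe over the systolic fraction of the cycle — scaled so the
#' cycle mean equals `cardiac_output`, and returns its Fourier fit. The
#' template stands in for a chronic-heart-failure aortic-valve flow trace
#' (nominally ~3.2 L/min in 0.7 s cycles) whose sampled data are not
#' published; period and mean are matched exactly.
#'
#' @param cardiac_output Cycle-mean flow (m^3/s), `>= 0`. Default is
#'   3.2 L/min.
#' @param period Cardiac cycle length (s), default 0.7.
#' @param systolic_fraction Fraction of the cycle occupied by ejection,
#'   in (0, 1); default 0.35.
#' @param n_terms Harmonics in the fit (default 8).
#' @param n_samples Fit grid size (default 700).
#' @return A [fourier_series()]; its cycle integral equals
#'   `cardiac_output * period` to within 1%.
#' @export
native_hf_waveform <- function(cardiac_output = 3.2 / 60 / 1000, period = 0.7,
                               systolic_fraction = 0.35, n_terms = 8,
                               n_samples = 700) {
  if (!is.numeric(cardiac_output) || length(cardiac_output) != 1L ||
      cardiac_output < 0) {
    stop("'cardiac_output' must be a single non-negative flow (m^3/s)")
  }
  if (!is.numeric(systolic_fraction) || length(systolic_fraction) != 1L ||
      systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop("'systolic_fraction' must lie strictly between 0 and 1")
  }
  if (cardiac_output == 0) {
    return(fourier_series(a0 = 0, a = numeric(n_terms), b = numeric(n_terms),
                          omega = 2 * pi / period))
  }
  ts_len <- systolic_fraction * period
  # half-sine lobe mean over the full cycle: peak * (2/pi) * systolic_fraction
  peak <- cardiac_output * pi / (2 * systolic_fraction)
  tt <- seq(0, period, length.out = n_samples + 1L)[-(n_samples + 1L)]
  q <- ifelse(tt < ts_len, peak * sin(pi * tt / ts_len), 0)
  fit_fourier(waveform_samples(tt, q, period), n_terms = n_terms)
}

#' Combined inlet program: artificial pulse plus intermittent aortic valve
#'
#' Bundles the outflow-graft (OG) waveform with the residual native
#' waveform and the aortic-valve (AV) opening pattern. The OG component is
#' always active (period `og_period`); the AV component contributes one
#' residual-scaled native cycle at the start of every `opening_interval`-th
#' pump cycle and is zero otherwise. `av_open = FALSE` (or
#' `residual_fraction = 0`) gives the AV-closed condition.
#'
#' @param og [fourier_series()] for the OG flow (m^3/s).
#' @param native [fourier_series()] for the full native cardiac waveform
#'   (m^3/s; its own period, default 0.7 s).
#' @param residual_fraction Fraction of native output transmitted while the
#'   AV opens (default 0.05), in `[0, 1]`.
#' @param opening_interval Pump cycles per AV opening (default 5), `>= 1`.
#' @param og_period Pump cycle length (s), default 2.
#' @param av_open Logical; `FALSE` forces the AV-closed condition.
#' @return Object of class `inlet_program`.
#' @seealso [combined_inlet()]
#' @export
inlet_program <- function(og, native = native_hf_waveform(),
                          residual_fraction = 0.05, opening_interval = 5,
                          og_period = 2, av_open = TRUE) {
  stopifnot(inherits(og, "fourier_series"), inherits(native, "fourier_series"))
  if (residual_fraction < 0 || residual_fraction > 1) {
    stop("'residual_fraction' must lie in [0, 1]")
  }
  if (opening_interval < 1 || opening_interval != round(opening_interval)) {
    stop("'opening_interval' must be an integer >= 1")
  }
  structure(list(og = og, native = native,
                 residual_fraction = residual_fraction,
                 opening_interval = as.integer(opening_interval),
                 og_period = og_period, av_open = isTRUE(av_open)),
            class = "inlet_program")
}

#' Evaluate the two inlet flows of an inlet program
#'
#' @param program An [inlet_program()].
#' @param t Times (s), `t >= 0`; vectorised.
#' @return A list with numeric vectors `og` and `av` (m^3/s) and their sum
#'   `total`.
#' @export
#' @examples
#' pr <- inlet_program(og_flow_waveform(mean_flow = 6.7e-5))
#' q <- combined_inlet(pr, seq(0, 20, by = 0.01))
combined_inlet <- function(program, t) {
  stopifnot(inherits(program, "inlet_program"))
  if (any(t < 0)) stop("'t' must be non-negative")
  og <- eval_fourier(program$og, t)
  av <- numeric(length(t))
  if (program$av_open && program$residual_fraction > 0) {
    native_period <- fs_period(program$native)
    window <- program$opening_interval * program$og_period
    tl <- round(t %% window, 9)
    tl[tl >= window] <- 0
    on <- tl < native_period
    if (any(on)) {
      av[on] <- program$residual_fraction * eval_fourier(program$native, tl[on])
    }
  }
  list(og = og, av = av, total = og + av)
}

#' Read/write waveform samples as two-column CSV
#'
#' The on-disk format is a CSV with header `t_seconds,value`.
#'
#' @param samples A [waveform_samples()].
#' @param path CSV path.
#' @param period Waveform period (s) to attach on read; defaults to the last
#'   sample time.
#' @return `write_waveform_csv` returns `path` invisibly;
#'   `read_waveform_csv` returns a [waveform_samples()].
#' @export
write_waveform_csv <- function(samples, path) {
  stopifnot(inherits(samples, "waveform_samples"))
  utils::write.csv(data.frame(t_seconds = samples$t, value = samples$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path, period = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("t_seconds", "value") %in% names(d))) {
    stop("expected columns 't_seconds' and 'value'")
  }
  if (is.null(period)) period <- max(d$t_seconds)
  waveform_samples(d$t_seconds, d$value, period)
}
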