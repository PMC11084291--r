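test_that("hm3_speed reproduces the artificial-pulse schedule", {
  sch <- pulse_schedule(base_rpm = 5500)
  expect_equal(schedule_period(sch), 2)
  expect_equal(hm3_speed(0.05, sch), 3500)  # drop phase: set - 2000
  expect_equal(hm3_speed(0.25, sch), 7500)  # rise: reduced + 4000
  expect_equal(hm3_speed(1.0, sch), 5500)   # back to set speed
  expect_equal(hm3_speed(2.05, sch), 3500)  # periodic
  # full-period periodicity on a grid
  tt <- seq(0, 1.99, by = 0.01)
  expect_equal(hm3_speed(tt, sch), hm3_speed(tt + 2, sch))
  expect_error(pulse_schedule(drop_dur = -0.1), "non-negative")
  expect_warning(pulse_schedule(base_rpm = 4000), "band")
})

test_that("og_flow_waveform pins the cycle mean and keeps the pulse shape", {
  og <- og_flow_waveform(pulse_schedule(), mean_flow = 6.7e-5)
  # cycle mean via independent quadrature
  m <- integrate(function(t) eval_fourier(og, t), 0, 2,
                 subdivisions = 1000)$value / 2
  expect_equal(m, 6.7e-5, tolerance = 1e-3)
  expect_equal(og$a0, 6.7e-5, tolerance = 1e-3)
  # minimum falls inside the speed-drop phase [0, 0.15)
  td <- seq(0, 2, length.out = 4001)
  tmin <- td[which.min(eval_fourier(og, td))]
  expect_lt(tmin, 0.15)
  # degenerate pulse -> constant series at the mean
  flat <- og_flow_waveform(pulse_schedule(drop_rpm = 0, rise_rpm = 0),
                           mean_flow = 5e-5)
  expect_equal(flat$a0, 5e-5)
  expect_lt(max(abs(c(flat$a, flat$b))), 1e-18)
  expect_error(og_flow_waveform(mean_flow = -1), "positive")
})

test_that("native waveform preserves the target cardiac output", {
  z <- native_hf_waveform(cardiac_output = 0)
  expect_equal(eval_fourier(z, seq(0, 0.7, by = 0.05)), rep(0, 15))

  nat <- native_hf_waveform(cardiac_output = 5.33e-5, period = 0.7)
  expect_equal(nat$a0, 5.33e-5, tolerance = 0.01)
  # cycle integral equals CO * period within 1% (quadrature oracle)
  vol <- integrate(function(t) eval_fourier(nat, t), 0, 0.7,
                   subdivisions = 1000)$value
  expect_equal(vol, 5.33e-5 * 0.7, tolerance = 0.01)
  expect_error(native_hf_waveform(systolic_fraction = 1.2), "between 0 and 1")
})

test_that("combined inlet opens the aortic valve once per interval", {
  pr <- inlet_program(og_flow_waveform(mean_flow = 6.7e-5),
                      opening_interval = 5)
  tt <- seq(0, 20, length.out = 20001)[-20001]
  q <- combined_inlet(pr, tt)
  on <- q$av != 0
  # count contiguous AV-on events over 20 s = 2 windows of 5 pump cycles
  events <- sum(diff(c(FALSE, on)) == 1)
  expect_equal(events, 2L)
  # event count over k * interval cycles equals k
  for (k in 1:3) {
    tk <- seq(0, k * 5 * 2, length.out = k * 4000 + 1)[-(k * 4000 + 1)]
    onk <- combined_inlet(pr, tk)$av != 0
    expect_equal(sum(diff(c(FALSE, onk)) == 1), k)
  }
  # residual_fraction = 0 and av_open = FALSE both silence the valve
  pr0 <- inlet_program(pr$og, residual_fraction = 0)
  expect_true(all(combined_inlet(pr0, tt)$av == 0))
  prc <- inlet_program(pr$og, av_open = FALSE)
  expect_true(all(combined_inlet(prc, tt)$av == 0))
})

test_that("AV window volume is the residual fraction of a native cycle", {
  nat <- native_hf_waveform()
  pr <- inlet_program(og_flow_waveform(mean_flow = 6.7e-5), native = nat,
                      residual_fraction = 0.05)
  native_vol <- integrate(function(t) eval_fourier(nat, t), 0, 0.7,
                          subdivisions = 1000)$value
  window_vol <- integrate(function(t) combined_inlet(pr, t)$av, 0, 0.7,
                          subdivisions = 1000)$value
  expect_equal(window_vol, 0.05 * native_vol, tolerance = 1e-6)
})

test_that("waveform CSV round-trips", {
  tt <- seq(0, 0.6, by = 0.1)
  s <- waveform_samples(tt, sin(tt), period = 0.7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(s, path)
  back <- read_waveform_csv(path, period = 0.7)
  expect_equal(back$t, s$t)
  expect_equal(back$value, s$value)
})
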