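# small helper: wall-shear series from a function t -> 3-vector, shared grid
wss_from_fun <- function(fun, times, n_points = 5) {
  vec <- array(0, c(length(times), n_points, 3))
  for (i in seq_along(times)) vec[i, , ] <- matrix(fun(times[i]), n_points, 3,
                                                   byrow = TRUE)
  vector_field_series(times, matrix(rnorm(3 * n_points), n_points, 3), vec,
                      rep(1, n_points), kind = "wall_shear")
}

test_that("TAWSS averages the shear magnitude over the cycle", {
  tt <- seq(0, 1, length.out = 401)
  const <- wss_from_fun(function(t) c(0, 3, 0), tt)
  expect_equal(tawss(const)$values, rep(3, 5))
  # |A sin| averages to 2A/pi
  sine <- wss_from_fun(function(t) c(4 * sin(2 * pi * t), 0, 0), tt)
  expect_equal(tawss(sine)$values, rep(2 * 4 / pi, 5), tolerance = 1e-4)
  # quadrature convergence: halving dt changes the value by <= 0.1%
  sine2 <- wss_from_fun(function(t) c(4 * sin(2 * pi * t), 0, 0),
                        seq(0, 1, length.out = 801))
  expect_equal(tawss(sine)$values[1], tawss(sine2)$values[1],
               tolerance = 1e-3)
  expect_error(tawss(make_solid_rotation()$field), "wall_shear")
})

test_that("OSI hits its closed-form anchors and stays in [0, 0.5]", {
  tt <- seq(0, 1, length.out = 401)
  expect_equal(osi(wss_from_fun(function(t) c(2, 1, 0), tt))$values,
               rep(0, 5))
  for (f in c(0, 0.25, 0.5)) {
    ow <- make_oscillating_wss(reversal_fraction = f)
    expect_equal(osi(ow$field)$values,
                 rep(ow$manifest$analytic$osi, 25), tolerance = 5e-3)
  }
  rot <- make_oscillating_wss(pattern = "rotating")
  expect_equal(osi(rot$field)$values, rep(0.5, 25))
  # range property on random fields; degenerate all-zero points counted
  set.seed(71)
  for (rep in 1:5) {
    vec <- array(rnorm(21 * 6 * 3), c(21, 6, 3))
    vec[, 6, ] <- 0
    fld <- vector_field_series(seq(0, 1, length.out = 21),
                               matrix(0, 6, 3), vec, rep(1, 6), "wall_shear")
    o <- osi(fld)
    expect_true(all(o$values >= 0 & o$values <= 0.5))
    expect_equal(attr(o, "n_degenerate"), 1L)
    # triangle inequality: TAWSS >= |mean vector|
    w <- graftflow:::.trapz_weights(fld$times)
    mv <- sqrt(sum((w %*% vec[, 1, 1])^2) + sum((w %*% vec[, 1, 2])^2) +
               sum((w %*% vec[, 1, 3])^2))
    expect_gte(tawss(fld)$values[1] + 1e-12, mv)
  }
})

test_that("vorticity recovers analytic curls on structured grids", {
  # uniform flow: zero vorticity
  sr0 <- make_solid_rotation(omega = 0)
  expect_equal(max(vorticity(sr0$field)$values), 0)
  # solid-body rotation: |curl| = 2 Omega within 1% everywhere
  sr <- make_solid_rotation(omega = 5)
  expect_equal(vorticity(sr$field)$values,
               rep(sr$manifest$analytic$curl_mag, nrow(sr$field$points)),
               tolerance = 0.01)
  # Poiseuille: |curl| = |du/dr| = dP r / (2 mu L) at sampled radii
  fx <- make_poiseuille(dims = c(24, 24, 8))
  vm <- vorticity(fx$field)
  r <- sqrt(fx$field$points[, 1]^2 + fx$field$points[, 2]^2)
  expected <- fx$manifest$params$dP * r /
    (2 * fx$manifest$params$mu * fx$manifest$params$L)
  expect_equal(vm$values, expected, tolerance = 1e-8)
  # near-wall Newtonian consistency: mu * |omega| ~ tau_wall at r ~ R
  near <- which(abs(r - fx$manifest$params$R) ==
                  min(abs(r - fx$manifest$params$R)))[1]
  expect_equal(fx$manifest$params$mu * vm$values[near] *
                 fx$manifest$params$R / r[near],
               fx$manifest$analytic$tau_wall, tolerance = 0.01)
  expect_error(vorticity(wss_from_fun(function(t) c(1, 0, 0),
                                      c(0, 1))), "wall_shear|velocity")
})

test_that("TKE follows the ensemble definition", {
  base <- make_solid_rotation(omega = 1, dims = 8)$field
  expect_equal(max(tke(base, list(base, base))$values), 0)
  # seeded fluctuations with per-component variance sigma^2 -> k ~ 1.5 sigma^2
  set.seed(81)
  sigma <- 0.3
  reals <- lapply(1:60, function(i) {
    f <- base
    f$vectors <- f$vectors + array(rnorm(length(f$vectors), sd = sigma),
                                   dim(f$vectors))
    f
  })
  k <- tke(base, reals)
  expect_equal(mean(k$values), 1.5 * sigma^2, tolerance = 0.05)
  # doubling fluctuations quadruples k
  reals2 <- lapply(reals, function(f) {
    f$vectors <- base$vectors + 2 * (f$vectors - base$vectors)
    f
  })
  expect_equal(tke(base, reals2)$values, 4 * k$values, tolerance = 1e-10)
  bad <- make_solid_rotation(omega = 1, dims = 10)$field
  expect_error(tke(base, list(bad)), "match")
})

test_that("viscous energy loss matches Poiseuille dissipation", {
  fx <- make_poiseuille(dims = c(64, 64, 8))
  an <- fx$manifest$analytic
  # steady flow over a 1 s window: loss = dP * Q * (t2 - t1), within 2%
  loss <- viscous_energy_loss(fx$field, t1 = 0, t2 = 1)
  expect_equal(loss, an$dissipation_rate * 1, tolerance = 0.02)
  # rigid rotation and zero field dissipate nothing
  expect_equal(viscous_energy_loss(make_solid_rotation(omega = 7)$field), 0,
               tolerance = 1e-20)
  zero <- make_poiseuille(dP = 0, dims = c(8, 8, 8))
  expect_equal(viscous_energy_loss(zero$field), 0)
  expect_error(viscous_energy_loss(fx$field, t1 = 0.5, t2 = 0.1), "t1 < t2")
})

test_that("section flow rate integrates u.n over grid slices", {
  fx <- make_poiseuille(dims = c(48, 48, 8))
  q <- section_flow_rate(fx$field, list(point = c(0, 0, 0.05),
                                        normal = c(0, 0, 1)))
  expect_equal(q$q, rep(fx$manifest$analytic$Q, 2), tolerance = 0.01)
  # conservation: two parallel sections agree
  q2 <- section_flow_rate(fx$field, list(point = c(0, 0, 0.01),
                                         normal = c(0, 0, 1)))
  expect_equal(q$q[1], q2$q[1], tolerance = 1e-10)
  # uniform axial flow through the masked disc: Q = U * A_disc
  uni <- fx$field
  uni$vectors[, , 3] <- 2.5
  qu <- section_flow_rate(uni, list(point = c(0, 0, 0.05),
                                    normal = c(0, 0, 1)))
  expect_equal(qu$q[1], 2.5 * pi * 0.01^2, tolerance = 0.01)
  expect_error(section_flow_rate(fx$field, list(point = c(0, 0, 0.05),
                                                normal = c(1, 1, 0))),
               "align")
  expect_error(section_flow_rate(fx$field, list(point = c(0, 0, 9),
                                                normal = c(0, 0, 1))),
               "intersect")
})

test_that("reverse-flow indices classify forward and reversed regions", {
  fx <- make_poiseuille(dims = c(24, 24, 8))
  plane <- list(point = c(0, 0, 0.05), normal = c(0, 0, 1))
  all_fwd <- fx$field
  all_fwd$vectors[, , 3] <- 1
  fwd <- reverse_flow(all_fwd, plane)
  expect_equal(fwd$cycle[["mean_reverse_fraction"]], 0)
  expect_equal(fwd$cycle[["peak_reverse_velocity"]], 0)
  # uniform reversal
  rev <- fx$field
  rev$vectors[, , 3] <- -1.2
  rr <- reverse_flow(rev, plane)
  expect_equal(rr$cycle[["mean_reverse_fraction"]], 1)
  expect_equal(rr$cycle[["mean_reverse_velocity"]], 1.2)
  # half forward / half reversed by sign of x
  half <- fx$field
  half$vectors[, , 3] <- ifelse(half$points[, 1] > 0, 1, -1)
  hf <- reverse_flow(half, plane)
  expect_equal(hf$cycle[["mean_reverse_fraction"]], 0.5, tolerance = 0.02)
})

test_that("Reynolds number is linear in speed and diameter", {
  expect_equal(reynolds_number(1.35, 0.014), 5008.5, tolerance = 1e-6)
  expect_gt(reynolds_number(1.35, 0.014), 5000)
  expect_equal(reynolds_number(0, 0.014), 0)
  expect_equal(reynolds_number(1, 0.028), 2 * reynolds_number(1, 0.014))
  expect_error(reynolds_number(-1, 0.014), "non-negative")
})

test_that("pointwise shear metrics are invariant under frame rotation", {
  set.seed(91)
  ow <- make_oscillating_wss(reversal_fraction = 0.25)$field
  R <- random_rotation()
  rot <- ow
  rot$points <- ow$points %*% t(R)
  for (i in seq_along(ow$times)) rot$vectors[i, , ] <- ow$vectors[i, , ] %*% t(R)
  expect_equal(tawss(rot)$values, tawss(ow)$values, tolerance = 1e-12)
  expect_equal(osi(rot)$values, osi(ow)$values, tolerance = 1e-12)
})

test_that("field container round-trips through CSV + manifest", {
  fx <- make_poiseuille(dims = c(8, 8, 8), times = c(0, 0.5, 1))
  dir <- withr::local_tempdir()
  write_field_series(fx$field, dir)
  back <- read_field_series(dir)
  expect_equal(back$times, fx$field$times)
  expect_equal(back$vectors, fx$field$vectors, tolerance = 1e-12)
  expect_equal(back$measure, fx$field$measure, tolerance = 1e-12)
  expect_equal(back$kind, "velocity")
  expect_equal(as.numeric(back$grid$dims), as.numeric(fx$field$grid$dims))
})
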