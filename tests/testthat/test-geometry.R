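test_that("configuration enumeration gives the expected counts and order", {
  cfg <- enumerate_configurations()
  expect_length(cfg, 15L)
  sides <- vapply(cfg, `[[`, character(1), "side")
  expect_equal(sum(sides == "coronal"), 9L)
  expect_equal(sum(sides == "sagittal"), 6L)
  # deterministic order: coronal first, then distance, then angle
  expect_equal(cfg[[1]]$d, 45); expect_equal(cfg[[1]]$angle, 35)
  expect_equal(cfg[[2]]$angle, 45)
  expect_equal(cfg[[10]]$side, "sagittal")

  expect_length(enumerate_configurations(50, 45, numeric()), 1L)
  expect_length(enumerate_configurations(c(45, 55), 45, 45), 4L)
  # count law
  expect_length(enumerate_configurations(c(45, 50), c(35, 45), c(45, 55)),
                2L * (2L + 2L))
})

test_that("out-of-range parameters are rejected by name", {
  expect_error(anastomosis_params(30, "coronal", 45), "distance d")
  expect_error(anastomosis_params(50, "coronal", 60), "coronal angle")
  expect_error(anastomosis_params(50, "sagittal", 40), "sagittal angle")
  expect_error(anastomosis_params(50, "coronal", 45, og_diameter = 0),
               "og_diameter")
})

test_that("build/measure round-trips every default configuration", {
  ao <- aorta_model()
  for (p in enumerate_configurations()) {
    m <- build_geometry(ao, p)
    rec <- measure_parameters(m)
    expect_lt(abs(rec$d - p$d), 0.5)
    expect_equal(rec$side, p$side)
    expect_lt(abs(rec$angle - p$angle), 0.5)
    expect_lt(abs(rec$og_diameter - 14), 0.1)
  }
})

test_that("recovered parameters are rigid-motion invariant", {
  set.seed(61)
  m <- build_geometry(aorta_model(), anastomosis_params(55, "coronal", 35))
  base <- measure_parameters(m)
  for (rep in 1:3) {
    mt <- transform_mesh(m, random_rotation(), rnorm(3, 0, 100))
    rec <- measure_parameters(mt)
    expect_equal(rec$d, base$d, tolerance = 1e-6)
    expect_equal(rec$side, base$side)
    expect_equal(rec$angle, base$angle, tolerance = 1e-6)
    expect_equal(rec$og_diameter, base$og_diameter, tolerance = 1e-6)
  }
})

test_that("doubling resolution doubles ring vertices, not the parameters", {
  ao <- aorta_model()
  p <- anastomosis_params(50, "sagittal", 45)
  m1 <- build_geometry(ao, p, resolution = 32)
  m2 <- build_geometry(ao, p, resolution = 64)
  expect_equal(nrow(m2$vertices), 2L * nrow(m1$vertices))
  r1 <- measure_parameters(m1)
  r2 <- measure_parameters(m2)
  expect_equal(r1$d, r2$d, tolerance = 0.1)
  expect_equal(r1$angle, r2$angle, tolerance = 0.1)
  expect_equal(r1$og_diameter, r2$og_diameter, tolerance = 0.05)
})

test_that("a straight-tube aorta leaves the cardinal side ambiguous", {
  m <- build_geometry(straight_aorta(), anastomosis_params(50, "coronal", 45))
  rec <- measure_parameters(m)
  expect_equal(rec$side, "ambiguous")
  expect_equal(rec$og_diameter, 14, tolerance = 0.1)
})

test_that("placement beyond the centerline extent and missing labels error", {
  ao <- aorta_model(ascending_length = 45)
  expect_error(build_geometry(ao, anastomosis_params(50, "coronal", 45)),
               "beyond the ascending centerline extent")
  m <- build_geometry(aorta_model(), anastomosis_params(50, "coronal", 45))
  m$label <- NULL
  expect_error(measure_parameters(m), "labelled")
})

test_that("ASCII STL export is well-formed", {
  m <- build_geometry(aorta_model(), anastomosis_params(50, "coronal", 45),
                      resolution = 12)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, path)
  lines <- readLines(path)
  expect_match(lines[1], "^solid")
  expect_match(tail(lines, 1), "^endsolid")
  expect_equal(sum(grepl("^ facet normal", lines)), nrow(m$faces))
  # no degenerate (zero-area) triangles in the emitted mesh
  v <- m$vertices; f <- m$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  expect_gt(min(sqrt(rowSums(cr^2))), 1e-9)
})
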