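test_that("node pressure solves the parallel circuit", {
  # equilibrium: no inflow, one branch, node floats at the capacitor
  eq <- node_pressure(0, pc = 10, rp = 1)
  expect_equal(eq$p, 10)
  expect_equal(eq$q, 0)
  # two-branch hand algebra: rp = {1, 1}, pc = {0, 2}, q_in = 0
  two <- node_pressure(0, pc = c(0, 2), rp = c(1, 1))
  expect_equal(two$p, 1)
  expect_equal(two$q, c(1, -1))
  expect_error(node_pressure(1, numeric(), numeric()), "empty")
})

test_that("node flows conserve mass for arbitrary inputs", {
  set.seed(51)
  for (rep in 1:20) {
    k <- sample(1:9, 1)
    q_in <- rnorm(1, 0, 1e-4)
    np <- node_pressure(q_in, pc = rnorm(k, 1e4, 5e3),
                        rp = runif(k, 1e6, 1e9))
    expect_equal(sum(np$q), q_in, tolerance = 1e-12)
  }
})

test_that("steady inflow drives the node to the parallel operating point", {
  net <- aortic_network()
  sim <- simulate_network(net, inflow = 6.7e-5,
                          config = solver_config(n_cycles = 15))
  s <- summary(sim)
  expect_true(sim$converged)
  # q * R_parallel, in mmHg
  expected <- Pa_to_mmHg(6.7e-5 * total_parallel_resistance(net$branches))
  expect_equal(s$pressure_mmHg[["mean"]], expected, tolerance = 1e-3)
  # conservation at every stored sample
  resid <- max(abs(rowSums(sim$q_branch) - sim$q_in))
  expect_lt(resid / 6.7e-5, 1e-9)
  # fractions sum to 1
  expect_equal(sum(s$branch_fraction), 1, tolerance = 1e-9)
  # descending aorta takes its conductance share
  expect_equal(s$branch_fraction[["descending_aorta"]], 0.51,
               tolerance = 0.01)
})

test_that("zero inflow with zero initial state stays identically zero", {
  sim <- simulate_network(aortic_network(), inflow = 0,
                          config = solver_config(n_cycles = 3))
  expect_true(all(sim$p_node == 0))
  expect_true(all(sim$q_branch == 0))
})

test_that("pulsatile program converges to a periodic state", {
  pr <- inlet_program(og_flow_waveform(mean_flow = 6.7e-5))
  sim <- simulate_network(aortic_network(), pr)
  expect_true(sim$converged)
  expect_lte(sim$cycles_run, 12L)
  s <- summary(sim)
  expect_equal(s$pressure_mmHg[["mean"]], 73, tolerance = 0.03)
})

test_that("cycle-mean pressure is insensitive to halving the step", {
  qfun <- function(t) 6.7e-5 * (1 + 0.5 * sin(pi * t))
  run <- function(dt) {
    sim <- simulate_network(aortic_network(), qfun,
                            config = solver_config(dt = dt, n_cycles = 4,
                                                   convergence_tol = 1e-12))
    summary(sim)$pressure_Pa[["mean"]]
  }
  expect_equal(run(1e-3), run(5e-4), tolerance = 1e-4)
})

test_that("running extra cycles after convergence leaves the mean unchanged", {
  pr <- inlet_program(og_flow_waveform(mean_flow = 6.7e-5), av_open = FALSE)
  m1 <- summary(simulate_network(aortic_network(), pr,
                                 config = solver_config(n_cycles = 10)))
  m2 <- summary(simulate_network(aortic_network(), pr,
                                 config = solver_config(n_cycles = 20,
                                                        convergence_tol = 1e-7)))
  expect_equal(m1$pressure_Pa[["mean"]], m2$pressure_Pa[["mean"]],
               tolerance = 1e-3)
})

test_that("summary refuses a run shorter than one cycle", {
  sim <- simulate_network(aortic_network(), inflow = 6.7e-5,
                          config = solver_config(n_cycles = 2))
  sim$t <- sim$t[1:100]
  sim$p_node <- sim$p_node[1:100]
  expect_error(summary(sim), "shorter than one full cycle")
})

test_that("simulation CSV carries one column per branch", {
  sim <- simulate_network(aortic_network(), inflow = 6.7e-5,
                          config = solver_config(n_cycles = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_simulation_csv(sim, path)
  d <- read.csv(path, check.names = FALSE)
  expect_true(all(c("t", "p_node", "q_in", "descending_aorta") %in% names(d)))
  expect_equal(nrow(d), length(sim$t))
})
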