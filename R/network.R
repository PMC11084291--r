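#' 0D aortic flow network
#'
#' Collapses the aorta to a single pressure node fed by the inlet program
#' (outflow graft + aortic root) and drained by a set of three-element
#' Windkessel outlets. The rigid-wall assumption of the underlying flow
#' problem makes the single-node collapse the faithful desk-scale surrogate:
#' the only stored compliances are the outlet capacitors.
#'
#' @param branches Named list of [wk3()] objects (default the shipped
#'   seven-outlet set).
#' @param node_label Identifier of the aortic pressure node.
#' @return Object of class `aortic_network`.
#' @export
aortic_network <- function(branches = hm3_outlets(), node_label = "aorta") {
  if (length(branches) < 1L) stop("need at least one outlet branch")
  if (is.null(names(branches)) || any(!nzchar(names(branches)))) {
    stop("'branches' must be a named list")
  }
  ok <- vapply(branches, inherits, logical(1), what = "wk3")
  if (!all(ok)) stop("all branches must be wk3 objects")
  structure(list(branches = branches, node_label = node_label),
            class = "aortic_network")
}

#' @export
print.aortic_network <- function(x, ...) {
  cat(sprintf("Aortic 0D network '%s': %d Windkessel outlets, R_parallel = %.4g Pa s/m^3\n",
              x$node_label, length(x$branches),
              total_parallel_resistance(x$branches)))
  invisible(x)
}

#' Algebraic node pressure of the parallel outlet circuit
#'
#' With instantaneous total inflow `q_in` and per-branch capacitor
#' pressures `pc` behind proximal resistances `rp`, the common node
#' pressure is `P = (q_in + sum(pc/rp)) / sum(1/rp)` and the branch flows
#' `q_i = (P - pc_i)/rp_i` sum to `q_in` by construction.
#'
#' @param q_in Total inflow (m^3/s), scalar.
#' @param pc Per-branch capacitor pressures (Pa).
#' @param rp Per-branch proximal resistances (Pa s m^-3), all > 0.
#' @return List with `p` (node pressure, Pa) and `q` (branch flows, m^3/s).
#' @export
node_pressure <- function(q_in, pc, rp) {
  if (length(pc) == 0L) stop("empty branch set")
  if (length(pc) != length(rp)) stop("'pc' and 'rp' lengths differ")
  if (any(rp <= 0)) stop("all proximal resistances must be positive")
  g <- 1 / rp
  p <- (q_in + sum(pc * g)) / sum(g)
  list(p = p, q = (p - pc) * g)
}

#' Solver configuration for the 0D network
#'
#' @param dt Fixed integration step (s), default 1e-3.
#' @param n_cycles Maximum pump cycles to run (default 20), `>= 2`.
#' @param convergence_tol Relative cycle-to-cycle L2 change of node
#'   pressure below which the run is declared periodic (default 1e-3).
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(dt = 1e-3, n_cycles = 20, convergence_tol = 1e-3) {
  if (dt <= 0) stop("'dt' must be positive")
  if (n_cycles < 2) stop("'n_cycles' must be at least 2")
  structure(list(dt = dt, n_cycles = as.integer(n_cycles),
                 convergence_tol = convergence_tol),
            class = "solver_config")
}

#' Simulate the 0D aortic network
#'
#' Integrates all outlet capacitor states with classical RK4 at a fixed
#' step, applying the algebraic node reduction ([node_pressure()]) inside
#' every derivative evaluation, so mass is conserved at the node at every
#' stored sample to machine precision. The run stops early once the
#' relative L2 distance between consecutive cycles of node pressure drops
#' below `config$convergence_tol` (with at least two cycles run), mirroring
#' the repeating-pattern stability check used for periodic unsteady
#' simulations.
#'
#' @param network An [aortic_network()].
#' @param inflow An [inlet_program()], a function of time returning total
#'   inflow (m^3/s), or a single constant flow.
#' @param config A [solver_config()].
#' @param cycle_period Pump cycle length (s); taken from the inlet program
#'   when one is supplied (default 2 s otherwise).
#' @param pc0 Initial capacitor pressures (Pa); scalar or per branch.
#' @return Object of class `aorta_sim`: a list with `t`, `p_node` (Pa),
#'   `q_in`, `q_branch` (matrix, one column per branch), `pc_branch`,
#'   `converged`, `cycles_run`, plus the network and configuration.
#' @seealso [summary.aorta_sim()]
#' @export
#' @examples
#' net <- aortic_network()
#' sim <- simulate_network(net, inflow = 6.7e-5,
#'                         config = solver_config(n_cycles = 8))
#' Pa_to_mmHg(tail(sim$p_node, 1)) # ~73 mmHg
simulate_network <- function(network, inflow, config = solver_config(),
                             cycle_period = NULL, pc0 = 0) {
  stopifnot(inherits(network, "aortic_network"),
            inherits(config, "solver_config"))
  if (inherits(inflow, "inlet_program")) {
    if (is.null(cycle_period)) cycle_period <- inflow$og_period
    program <- inflow
    qfun <- function(t) combined_inlet(program, t)$total
  } else if (is.function(inflow)) {
    qfun <- inflow
  } else {
    qfun <- function(t) rep_len(inflow, length(t))
  }
  if (is.null(cycle_period)) cycle_period <- 2
  br <- network$branches
  nb <- length(br)
  rp <- vapply(br, `[[`, numeric(1), "Rp")
  rd <- vapply(br, `[[`, numeric(1), "Rd")
  cc <- vapply(br, `[[`, numeric(1), "C")
  dt <- config$dt
  steps_per_cycle <- round(cycle_period / dt)
  if (abs(steps_per_cycle * dt - cycle_period) > 1e-9) {
    stop("'dt' must divide the cycle period evenly")
  }
  n_steps <- steps_per_cycle * config$n_cycles

  deriv <- function(t, pc) {
    np <- node_pressure(qfun(t), pc, rp)
    np$q / cc - pc / (rd * cc)
  }

  pc <- rep_len(pc0, nb)
  tt <- seq(0, by = dt, length.out = n_steps + 1L)
  pc_hist <- matrix(NA_real_, nrow = n_steps + 1L, ncol = nb,
                    dimnames = list(NULL, names(br)))
  pc_hist[1L, ] <- pc
  converged <- FALSE
  cycles_run <- 0L
  prev_cycle <- NULL
  p_node <- numeric(n_steps + 1L)
  q_in <- numeric(n_steps + 1L)
  q_branch <- matrix(NA_real_, nrow = n_steps + 1L, ncol = nb,
                     dimnames = list(NULL, names(br)))
  np0 <- node_pressure(qfun(0), pc, rp)
  p_node[1L] <- np0$p; q_in[1L] <- qfun(0); q_branch[1L, ] <- np0$q

  i_end <- n_steps
  for (i in seq_len(n_steps)) {
    t0 <- tt[i]
    k1 <- deriv(t0, pc)
    k2 <- deriv(t0 + dt / 2, pc + dt / 2 * k1)
    k3 <- deriv(t0 + dt / 2, pc + dt / 2 * k2)
    k4 <- deriv(t0 + dt, pc + dt * k3)
    pc <- pc + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(pc))) {
      stop(sprintf("network integration diverged at step %d (t = %.4g s); try a smaller dt than %.3g s",
                   i, tt[i + 1L], dt))
    }
    pc_hist[i + 1L, ] <- pc
    qi <- qfun(tt[i + 1L])
    np <- node_pressure(qi, pc, rp)
    p_node[i + 1L] <- np$p
    q_in[i + 1L] <- qi
    q_branch[i + 1L, ] <- np$q
    if (i %% steps_per_cycle == 0L) {
      cycles_run <- cycles_run + 1L
      this_cycle <- p_node[(i - steps_per_cycle + 1L):i]
      if (!is.null(prev_cycle)) {
        denom <- sqrt(mean(prev_cycle^2))
        delta <- sqrt(mean((this_cycle - prev_cycle)^2))
        if (denom > 0 && delta / denom < config$convergence_tol) {
          converged <- TRUE
          i_end <- i
          break
        }
        if (denom == 0 && delta == 0) {
          converged <- TRUE
          i_end <- i
          break
        }
      }
      prev_cycle <- this_cycle
    }
  }
  keep <- seq_len(i_end + 1L)
  structure(list(t = tt[keep], p_node = p_node[keep], q_in = q_in[keep],
                 q_branch = q_branch[keep, , drop = FALSE],
                 pc_branch = pc_hist[keep, , drop = FALSE],
                 converged = converged, cycles_run = cycles_run,
                 cycle_period = cycle_period, dt = dt, network = network),
            class = "aorta_sim")
}

#' @export
print.aorta_sim <- function(x, ...) {
  cat(sprintf("0D aortic simulation: %.3g s at dt = %.3g s, %d cycle(s), %s\n",
              max(x$t), x$dt, x$cycles_run,
              if (x$converged) "converged (periodic)" else "not converged"))
  cat(sprintf("  node pressure (last cycle): mean %.1f mmHg [%.1f, %.1f]\n",
              Pa_to_mmHg(mean(.last_cycle(x)$p_node)),
              Pa_to_mmHg(min(.last_cycle(x)$p_node)),
              Pa_to_mmHg(max(.last_cycle(x)$p_node))))
  invisible(x)
}

# extract the final full cycle of a simulation
.last_cycle <- function(sim) {
  spc <- round(sim$cycle_period / sim$dt)
  n <- length(sim$t)
  if (n < spc + 1L) stop("simulation shorter than one full cycle")
  idx <- (n - spc):n
  list(t = sim$t[idx], p_node = sim$p_node[idx],
       q_in = sim$q_in[idx],
       q_branch = sim$q_branch[idx, , drop = FALSE], idx = idx)
}

#' Cycle summary of a network simulation
#'
#' Summarises the final full pump cycle: node-pressure mean/extremes in Pa
#' and mmHg, per-branch cycle-mean flows and flow fractions, and total
#' outflow volume per cycle.
#'
#' @param object An `aorta_sim` from [simulate_network()].
#' @param ... Unused.
#' @return A list of class `aorta_sim_summary` with elements
#'   `pressure_Pa`, `pressure_mmHg` (each mean/min/max), `branch_mean_flow`,
#'   `branch_fraction`, `outflow_volume_per_cycle`, `converged`,
#'   `cycles_run`.
#' @export
summary.aorta_sim <- function(object, ...) {
  lc <- .last_cycle(object)
  w <- .trapz_weights(lc$t)
  T_ <- max(lc$t) - min(lc$t)
  p_mean <- sum(w * lc$p_node) / T_
  q_mean <- as.numeric(w %*% lc$q_branch) / T_
  names(q_mean) <- colnames(lc$q_branch)
  structure(list(
    pressure_Pa = c(mean = p_mean, min = min(lc$p_node), max = max(lc$p_node)),
    pressure_mmHg = Pa_to_mmHg(c(mean = p_mean, min = min(lc$p_node),
                                 max = max(lc$p_node))),
    branch_mean_flow = q_mean,
    branch_fraction = q_mean / sum(q_mean),
    outflow_volume_per_cycle = sum(q_mean) * T_,
    converged = object$converged,
    cycles_run = object$cycles_run), class = "aorta_sim_summary")
}

#' @export
print.aorta_sim_summary <- function(x, ...) {
  cat(sprintf("Node pressure: mean %.1f mmHg (min %.1f, max %.1f)\n",
              x$pressure_mmHg["mean"], x$pressure_mmHg["min"],
              x$pressure_mmHg["max"]))
  cat("Branch flow fractions:\n")
  print(round(x$branch_fraction, 4))
  cat(sprintf("Outflow volume per cycle: %.4g m^3 (%s after %d cycles)\n",
              x$outflow_volume_per_cycle,
              if (x$converged) "converged" else "not converged", x$cycles_run))
  invisible(x)
}

#' @export
plot.aorta_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, Pa_to_mmHg(x$p_node), type = "l", xlab = "t (s)",
                 ylab = "node pressure (mmHg)", ...)
  graphics::plot(x$t, x$q_in * 6e4, type = "l", xlab = "t (s)",
                 ylab = "inflow (L/min)", ...)
  invisible(x)
}

#' Write a network simulation as tidy CSV
#'
#' One row per time sample: `t`, `p_node`, `q_in`, then one flow column per
#' branch.
#'
#' @param sim An `aorta_sim`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(sim, path) {
  stopifnot(inherits(sim, "aorta_sim"))
  d <- data.frame(t = sim$t, p_node = sim$p_node, q_in = sim$q_in,
                  sim$q_branch, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
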