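#' Default end-to-end run configuration
#'
#' A fully-specified configuration for [run_study()]: the supported-
#' circulation systemic state, the shipped seven-outlet Windkessel network
#' (`branches = "table"`), the default artificial-pulse schedule, the
#' intermittent aortic-valve program (5% residual, one opening per five
#' pump cycles), the fixed-step solver (dt 1e-3 s, up to 20 cycles,
#' periodicity tolerance 1e-3) and the default geometry enumeration.
#'
#' @param av_open Logical; `FALSE` selects the AV-closed condition.
#' @return Nested list understood by [run_study()].
#' @export
default_run_config <- function(av_open = TRUE) {
  list(
    systemic = list(sbp = 78, dbp = 69, map = 73, co = 6.7e-5, hr = 30,
                    distensibility = 7.9e-3),
    branches = "table",
    schedule = list(base_rpm = 5500, drop_rpm = 2000, drop_dur = 0.15,
                    rise_rpm = 4000, rise_dur = 0.2, rest_dur = 1.65),
    program = list(residual_fraction = 0.05, opening_interval = 5,
                   og_period = 2, av_open = av_open,
                   native_co = 3.2 / 60 / 1000, native_period = 0.7,
                   systolic_fraction = 0.35, n_terms = 8),
    solver = list(dt = 1e-3, n_cycles = 20, convergence_tol = 1e-3),
    geometry = list(distances = c(45, 50, 55),
                    coronal_angles = c(35, 45, 55),
                    sagittal_angles = c(45, 55), og_diameter = 14)
  )
}

.require_keys <- function(x, keys, where) {
  missing <- setdiff(keys, names(x))
  if (length(missing)) {
    stop(sprintf("invalid config: '%s' is missing key(s) %s", where,
                 paste(missing, collapse = ", ")))
  }
}

#' Run the full desk-scale study chain
#'
#' Builds the inlet program (artificial-pulse graft waveform + residual
#' native waveform), resolves the Windkessel outlet network, simulates the
#' 0D aortic node, summarises the converged cycle, enumerates the
#' anastomosis configurations, and writes everything to `out_dir`:
#' waveform CSVs and Fourier JSONs, network parameters, the simulation
#' time series, a summary JSON (pressures in Pa and mmHg, branch
#' fractions), a geometry manifest, a plain-text log with convergence
#' diagnostics, the resolved configuration, and a run manifest with md5
#' checksums of every output. The fixed-step deterministic solver makes
#' re-runs with the same configuration byte-identical.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @param out_dir Output directory (created; must not require recursion
#'   through missing parents beyond one level).
#' @return Invisibly, a list with the in-memory results (`program`,
#'   `network`, `sim`, `summary`, `configurations`) and `out_dir`.
#' @export
run_study <- function(config = default_run_config(), out_dir) {
  .require_keys(config, c("systemic", "branches", "schedule", "program",
                          "solver"), "config")
  .require_keys(config$program, c("residual_fraction", "opening_interval",
                                  "og_period", "av_open"), "config$program")
  .require_keys(config$solver, c("dt", "n_cycles", "convergence_tol"),
                "config$solver")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sy <- do.call(systemic_state, config$systemic)
  sch <- do.call(pulse_schedule, config$schedule)
  pr_cfg <- config$program
  og <- og_flow_waveform(sch, mean_flow = sy$co,
                         n_terms = pr_cfg$n_terms %||% 8)
  native <- native_hf_waveform(cardiac_output = pr_cfg$native_co %||% (3.2 / 60 / 1000),
                               period = pr_cfg$native_period %||% 0.7,
                               systolic_fraction = pr_cfg$systolic_fraction %||% 0.35,
                               n_terms = pr_cfg$n_terms %||% 8)
  program <- inlet_program(og, native,
                           residual_fraction = pr_cfg$residual_fraction,
                           opening_interval = pr_cfg$opening_interval,
                           og_period = pr_cfg$og_period,
                           av_open = pr_cfg$av_open)

  branches <- if (identical(config$branches, "table")) {
    hm3_outlets()
  } else {
    estimate_rcr(sy, branches = as.data.frame(config$branches))
  }
  network <- aortic_network(branches)

  sim <- simulate_network(network, program,
                          config = do.call(solver_config, config$solver))
  summ <- summary(sim)

  # conservation residual at every stored sample (relative to inflow scale)
  resid <- max(abs(rowSums(sim$q_branch) - sim$q_in)) / max(abs(sim$q_in))

  configurations <- if (!is.null(config$geometry)) {
    do.call(enumerate_configurations, config$geometry)
  } else {
    enumerate_configurations()
  }

  # --- outputs ---
  tt <- seq(0, program$og_period, length.out = 401)
  write_waveform_csv(waveform_samples(tt, eval_fourier(og, tt),
                                      program$og_period),
                     file.path(out_dir, "og_waveform.csv"))
  write_fourier_json(og, file.path(out_dir, "og_waveform.json"))
  write_fourier_json(native, file.path(out_dir, "native_waveform.json"))
  net_df <- data.frame(name = names(branches),
                       Rp = vapply(branches, `[[`, numeric(1), "Rp"),
                       Rd = vapply(branches, `[[`, numeric(1), "Rd"),
                       C = vapply(branches, `[[`, numeric(1), "C"))
  utils::write.csv(net_df, file.path(out_dir, "network.csv"),
                   row.names = FALSE)
  write_simulation_csv(sim, file.path(out_dir, "simulation.csv"))
  jsonlite::write_json(list(
    pressure_Pa = as.list(summ$pressure_Pa),
    pressure_mmHg = as.list(summ$pressure_mmHg),
    branch_mean_flow = as.list(summ$branch_mean_flow),
    branch_fraction = as.list(summ$branch_fraction),
    outflow_volume_per_cycle = summ$outflow_volume_per_cycle,
    converged = summ$converged, cycles_run = summ$cycles_run),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  geo <- lapply(configurations, function(p) {
    list(d = p$d, side = p$side, angle = p$angle, og_diameter = p$og_diameter)
  })
  jsonlite::write_json(geo, file.path(out_dir, "geometry_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("cycles_run: %d", summ$cycles_run),
    sprintf("converged: %s", summ$converged),
    sprintf("node_conservation_residual_rel: %.3e", resid),
    sprintf("mean_pressure_mmHg: %.4f", summ$pressure_mmHg[["mean"]])),
    file.path(out_dir, "run_log.txt"))

  files <- c("og_waveform.csv", "og_waveform.json", "native_waveform.json",
             "network.csv", "simulation.csv", "summary.json",
             "geometry_manifest.json", "config.json", "run_log.txt")
  sums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(sums) <- files
  jsonlite::write_json(sums, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(program = program, network = network, sim = sim,
                 summary = summ, configurations = configurations,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
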