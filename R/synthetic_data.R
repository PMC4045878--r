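# Study-like synthetic datasets: calibrated simulator trajectories sampled
# on an HPLC-like discrete grid and degraded with multiplicative
# measurement noise and a detection floor, plus a truth sidecar.

#' HPLC-like measurement noise model
#'
#' Multiplicative Gaussian noise with constant coefficient of variation
#' (HPLC relative precision is roughly scale-free) applied independently
#' per species and time point, a detection floor below which values report
#' zero, and clamping at zero. Volume and time are treated as controlled
#' variables and left exact.
#'
#' @param cv Relative standard deviation per observation (default 0.02,
#'   which gives duplicate-run SDs of the same order as the reported
#'   between-replicate variation).
#' @param detection_floor Concentration (g/L) below which a measurement
#'   reports 0.
#' @param seed Default seed used when none is supplied at generation time.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(cv = 0.02, detection_floor = 0.05, seed = 1) {
  if (cv < 0 || detection_floor < 0)
    stop("cv and detection_floor must be non-negative")
  structure(list(cv = cv, detection_floor = detection_floor, seed = seed),
            class = "noise_model")
}

# Fixed seed-splitting rule: sub-seed r of a master seed (kept < 2^31).
sub_seed <- function(seed, r) {
  (as.integer(seed) + 104729L * as.integer(r)) %% 2147483647L
}

# Degrade a noiseless time series with a noise model (deterministic given
# seed). Concentration columns only.
apply_noise <- function(series, nm, seed = nm$seed) {
  noisy <- as.data.frame(series)
  conc_cols <- setdiff(names(noisy), c("time_h", "volume_L"))
  set.seed(seed)
  for (cc in conc_cols) {
    v <- noisy[[cc]] * rnorm(nrow(noisy), mean = 1, sd = nm$cv)
    v <- pmax(v, 0)
    v[v < nm$detection_floor] <- 0
    noisy[[cc]] <- v
  }
  pdu_timeseries(noisy, mode = ts_mode(series),
                 biomass = ts_biomass(series))
}

#' Generate one synthetic study run
#'
#' Simulates a calibrated scenario, samples it on the output grid, applies
#' the measurement model, and returns the observed series together with a
#' truth record: the noiseless trajectory, the per-step fluxes estimated
#' from it, and a node-closed (balanced) flux set satisfying the node and
#' redox balances exactly. Deterministic given the seed.
#'
#' @param scenario Scenario name (see [list_scenarios()]) or a
#'   [sim_config()].
#' @param seed Integer seed for the measurement noise.
#' @param noise A [noise_model()].
#' @param policy An [estimation_policy()] used for the truth fluxes
#'   (fed-batch scenarios only).
#' @return A list of class `synthetic_run`: `observed` (noisy
#'   [pdu_timeseries()]), `truth` (list with `trajectory`, `step_fluxes`,
#'   `balanced_fluxes`, `seed`, `noise`), and `schedule`.
#' @export
generate_run <- function(scenario, seed = 1, noise = noise_model(),
                         policy = estimation_policy()) {
  cfg <- if (inherits(scenario, "sim_config")) scenario
         else calibrate_scenario(scenario)
  clean <- simulate_reactor(cfg)
  observed <- if (noise$cv == 0 && noise$detection_floor == 0) clean
              else apply_noise(clean, noise, seed)
  step_fluxes <- NULL; balanced <- NULL
  if (cfg$mode == "fedbatch") {
    step_fluxes <- estimate_step_fluxes(clean, cfg$schedule, policy = policy)
    balanced <- do.call(rbind, lapply(seq_len(nrow(step_fluxes)), function(k) {
      f <- infer_branch_fluxes(step_fluxes$v1[k],
                               max(step_fluxes$v4[k], 0))
      data.frame(step = step_fluxes$step[k],
                 v1 = f$molar[["v1"]], v2 = f$molar[["v2"]],
                 v3 = f$molar[["v3"]], v4 = f$molar[["v4"]])
    }))
  }
  structure(list(observed = observed,
                 truth = list(trajectory = clean,
                              step_fluxes = step_fluxes,
                              balanced_fluxes = balanced,
                              seed = seed, noise = noise),
                 schedule = cfg$schedule,
                 scenario = if (is.character(scenario)) scenario
                            else "custom"),
            class = "synthetic_run")
}

#' Generate a pair of independent replicate runs
#'
#' Two runs of the same scenario with sub-seeds derived from one master
#' seed by the fixed splitting rule, emulating duplicate independent
#' biotransformation experiments whose mean and SD are reported.
#'
#' @inheritParams generate_run
#' @return A list of two `synthetic_run` objects.
#' @export
generate_duplicate_pair <- function(scenario, seed = 1,
                                    noise = noise_model(),
                                    policy = estimation_policy()) {
  list(generate_run(scenario, sub_seed(seed, 1L), noise, policy),
       generate_run(scenario, sub_seed(seed, 2L), noise, policy))
}

#' Write a synthetic run to disk
#'
#' Writes the observed series in the package CSV dialect plus a
#' `*.truth.json` sidecar holding the noiseless trajectory, the truth
#' fluxes and the seed/noise configuration.
#'
#' @param run A `synthetic_run`.
#' @param path Output CSV path; the sidecar replaces `.csv` with
#'   `.truth.json`.
#' @return `path`, invisibly.
#' @export
write_synthetic_run <- function(run, path) {
  write_timeseries(run$observed, path)
  side <- paste0(sub("\\.csv$", "", path), ".truth.json")
  truth <- list(scenario = run$scenario,
                seed = run$truth$seed,
                noise = unclass(run$truth$noise),
                trajectory = as.data.frame(run$truth$trajectory),
                step_fluxes = if (is.null(run$truth$step_fluxes)) NULL
                              else as.data.frame(run$truth$step_fluxes),
                balanced_fluxes = run$truth$balanced_fluxes)
  jsonlite::write_json(truth, side, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
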