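# Fixture builders used across the test files. All data are constructed in
# code; no files are shipped.

# Minimal batch series: one species profile, others flat.
make_batch_series <- function(t, glycerol = 50, hpa = 0, hp = 0, pdo = 0,
                              V = 0.5, X = 6) {
  n <- length(t)
  rep_len2 <- function(v) if (length(v) == 1) rep(v, n) else v
  pdu_timeseries(data.frame(
    time_h = t, volume_L = V,
    glycerol_g_L = rep_len2(glycerol), hpa_g_L = rep_len2(hpa),
    hp_g_L = rep_len2(hp), pdo_g_L = rep_len2(pdo)),
    mode = "batch", biomass = X)
}

# Fed-batch series with explicit volumes.
make_fedbatch_series <- function(t, V, glycerol = 0, hpa = 0, hp = 0,
                                 pdo = 0, x = 6) {
  n <- length(t)
  rep_len2 <- function(v) if (length(v) == 1) rep(v, n) else v
  pdu_timeseries(data.frame(
    time_h = t, volume_L = rep_len2(V),
    glycerol_g_L = rep_len2(glycerol), hpa_g_L = rep_len2(hpa),
    hp_g_L = rep_len2(hp), pdo_g_L = rep_len2(pdo)),
    mode = "fedbatch", biomass = x)
}

ph7_test_schedule <- function() feed_schedule(data.frame(
  start_h = c(1, 11, 21), end_h = c(11, 21, 31),
  feed_conc_g_L = 50, feed_rate_mL_h = c(12, 31.1, 50)))

# Single-step fed-batch config at a given feed mass rate (g/h), used for
# feed-response properties.
single_step_config <- function(feed_g_h, t_end = 15, ...) {
  sched <- feed_schedule(data.frame(
    start_h = 1, end_h = t_end, feed_conc_g_L = 50,
    feed_rate_mL_h = feed_g_h / 50 * 1000))
  sim_config(mode = "fedbatch", V0 = 1, conc0 = c(glycerol = 2),
             biomass = 6, schedule = sched,
             params = kinetic_params(...), grid = 0.25)
}

# Cached noiseless scenario runs (simulation is deterministic, so share
# across tests in a file).
.sim_cache <- new.env(parent = emptyenv())
cached_run <- function(name, grid = 0.25) {
  key <- paste0(name, "_", grid)
  if (is.null(.sim_cache[[key]])) {
    cfg <- calibrate_scenario(name, grid = grid)
    .sim_cache[[key]] <- list(cfg = cfg, ts = simulate_reactor(cfg))
  }
  .sim_cache[[key]]
}
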