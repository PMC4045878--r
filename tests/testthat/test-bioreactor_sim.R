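# Kinetic rate laws and the reactor ODE simulator.

test_that("GDH rate law saturates, vanishes at zero substrate and obeys inhibition", {
  p <- kinetic_params()
  expect_equal(gdh_rate(0, 0, 0, p), 0)
  p_nosub <- kinetic_params(Ki_gly = Inf)
  expect_equal(gdh_rate(1e5, 0, 0, p_nosub), p_nosub$vmax_gdh,
               tolerance = 1e-3)
  # non-increasing in 1,3PDO at fixed glycerol
  r <- vapply(c(0, 2, 5, 10, 20, 50), function(pdo)
    gdh_rate(10, pdo, 0, p), numeric(1))
  expect_true(all(diff(r) < 0))
  # substrate inhibition: rate declines again at very high glycerol
  expect_lt(gdh_rate(400, 0, 0, p), gdh_rate(20, 0, 0, p))
  # toxic 3HPA shuts GDH off unless a scavenger is active
  expect_lt(gdh_rate(10, 0, 8, p), 0.01 * p$vmax_gdh)
  expect_gt(gdh_rate(10, 0, 8, p, scavenger_active = TRUE),
            0.5 * p$vmax_gdh)
  expect_error(gdh_rate(-1, 0, 0, p), "non-negative")
})

test_that("branch rates are redox-coupled with a transient cofactor drain", {
  p <- kinetic_params()
  expect_equal(unname(branch_rates(0, 0, p)[c("r2", "r3")]), c(0, 0))
  # saturation below the PduP threshold at quasi-steady cofactors
  p_sat <- kinetic_params(Km_hpa = 1e-4, pdup_inhibition_smooth = FALSE)
  r <- branch_rates(0.5, 0, p_sat)
  expect_equal(unname(r["r2"]), p$vmax_branch, tolerance = 1e-3)
  expect_equal(unname(r["r2"]), unname(r["r3"]))
  # carryover NADH adds to the reductive branch only
  r2 <- branch_rates(0.5, 0.05, p)
  expect_equal(unname(r2["r2"] - r2["r3"]), unname(r2["drain"]))
  expect_gt(r2[["drain"]], 0)
  # PduP inhibition above the threshold reduces the coupled rate
  # (Km small so both points are saturated and only the penalty differs)
  p_km <- kinetic_params(Km_hpa = 1e-4)
  expect_lt(branch_rates(2, 0, p_km)[["r3"]],
            branch_rates(0.3, 0, p_km)[["r3"]] + 1e-9)
})

test_that("an empty reactor with no feed stays constant", {
  sched <- feed_schedule(data.frame(start_h = 1, end_h = 5,
                                    feed_conc_g_L = 0, feed_rate_mL_h = 0))
  cfg <- sim_config(mode = "fedbatch", V0 = 1, conc0 = c(glycerol = 0),
                    biomass = 6, schedule = sched, grid = 0.5)
  ts <- simulate_reactor(cfg)
  for (cc in c("glycerol_g_L", "hpa_g_L", "hp_g_L", "pdo_g_L"))
    expect_equal(ts[[cc]], rep(0, nrow(ts)))
  expect_equal(ts$volume_L, rep(1, nrow(ts)))
})

test_that("simulated runs conserve the C3 backbone and the volume balance", {
  run <- cached_run("wt_ph7")
  ts <- run$ts; cfg <- run$cfg
  # C3 conservation at the final sample (all consumed glycerol accounted)
  y_all <- cumulative_molar_yield(ts, schedule = cfg$schedule,
                                  species = c("hp", "pdo", "hpa_total"))
  expect_equal(y_all, 1, tolerance = 1e-6)
  # and at every intermediate sample from the start
  for (tf in c(5, 12, 21, 27)) {
    y <- cumulative_molar_yield(ts, pdu_window(0, tf),
                                schedule = cfg$schedule,
                                species = c("hp", "pdo", "hpa_total"))
    expect_equal(y, 1, tolerance = 1e-6)
  }
  # exact volume bookkeeping V(t) = V0 + sum(F_vol * elapsed)
  elapsed <- vapply(ts$time_h, function(t)
    sum(cfg$schedule$F_vol_L_h *
          pmax(0, pmin(t, cfg$schedule$end_h) - cfg$schedule$start_h)),
    numeric(1))
  expect_equal(ts$volume_L, cfg$V0 + elapsed, tolerance = 1e-9)
})

test_that("product equimolarity holds up to the carryover pool drawdown", {
  run <- cached_run("mutant_ph7")
  ts <- run$ts; cfg <- run$cfg
  mol <- function(cc, mm) ts[[cc]] * ts$volume_L / mm
  surplus <- mol("pdo_g_L", 76.09) - mol("hp_g_L", 90.08)  # mol
  pool_mol <- cfg$params$nadh_pool * cfg$biomass / 1000
  expect_true(all(surplus <= pool_mol + 1e-6))
  # long-run product ratio approaches 1
  expect_equal(product_molar_ratio(ts), 1, tolerance = 0.01)
})

test_that("steady-step uptake tracks the feed rate until capacity is exceeded", {
  feeds <- c(0.3, 0.6, 1.2, 1.6)
  q_S <- numeric(0); v4 <- numeric(0)
  for (f in feeds) {
    cfg <- single_step_config(f)
    ts <- simulate_reactor(cfg)
    rep <- estimate_step_fluxes(ts, cfg$schedule)
    q_S <- c(q_S, rep$q_S); v4 <- c(v4, rep$v4)
  }
  expect_true(all(diff(abs(q_S)) > 0))
  # below branch capacity uptake equals supply ...
  expect_equal(abs(q_S[1:3]), feeds[1:3] / 6 * 1000, tolerance = 0.01)
  # ... beyond it (2 * vmax_branch ~ 2.5 mmol/g_CDW.h) 3HPA accumulates
  expect_lt(v4[2], 0.02)
  expect_gt(v4[4], 0.1)
})

test_that("halving solver tolerances leaves sampled concentrations unchanged", {
  cfg1 <- calibrate_scenario("mutant_ph7")
  cfg2 <- cfg1; cfg2$rtol <- cfg1$rtol / 2; cfg2$atol <- cfg1$atol / 2
  t1 <- simulate_reactor(cfg1); t2 <- simulate_reactor(cfg2)
  for (cc in c("glycerol_g_L", "hpa_g_L", "hp_g_L", "pdo_g_L")) {
    denom <- pmax(abs(t1[[cc]]), 0.01)
    expect_lt(max(abs(t1[[cc]] - t2[[cc]]) / denom), 1e-3)
  }
})

test_that("scavenger batch keeps free 3HPA low until the scavenger exhausts", {
  run <- cached_run("wt_batch_scavenger")
  ts <- run$ts
  protected <- ts$scavenger_g_L > 0.5
  expect_true(all(ts$hpa_g_L[protected] < 0.1))
  # complexed 3HPA is the dominant product and conversion completes
  expect_lt(min(ts$glycerol_g_L), 0.5)
  expect_gt(max(ts$hpa_complex_g_L), 30)
  # total 3HPA formed cannot exceed glycerol consumed (C3 conservation)
  consumed_mol <- (50 - ts$glycerol_g_L) * ts$volume_L / 92.09
  hpa_mol <- (ts$hpa_g_L + ts$hpa_complex_g_L) * ts$volume_L / 74.08
  expect_true(all(hpa_mol <= consumed_mol + 1e-9))
})

test_that("without scavenger, toxic 3HPA self-terminates the batch", {
  cfg <- sim_config(mode = "batch", V0 = 0.5, conc0 = c(glycerol = 50),
                    biomass = 6, schedule = NULL,
                    params = kinetic_params(vmax_gdh = 17.9,
                                            vmax_branch = 1.475),
                    t_end = 6, grid = 0.25)
  ts <- simulate_reactor(cfg)
  expect_gt(max(ts$hpa_g_L), cfg$params$hpa_toxic_threshold)
  # GDH shut-off leaves most glycerol unconsumed at the end
  expect_gt(min(ts$glycerol_g_L), 25)
  # uptake over the final hour collapses relative to the first hour
  drop_over <- function(i, j) ts$glycerol_g_L[i] - ts$glycerol_g_L[j]
  n <- nrow(ts)
  expect_lt(drop_over(n - 4, n), 0.2 * drop_over(1, 5))
})

test_that("scenario catalogue encodes the study protocols", {
  expect_setequal(list_scenarios(),
                  c("wt_ph7", "mutant_ph7", "wt_ph5", "mutant_ph5",
                    "wt_batch_scavenger", "mutant_batch_scavenger"))
  m7 <- calibrate_scenario("mutant_ph7")
  expect_equal(m7$schedule$feed_rate_mL_h, c(12, 31.1, 50))
  expect_equal(m7$schedule$start_h, c(1, 11, 21))
  expect_equal(m7$V0, 1)
  expect_equal(m7$conc0[["glycerol"]], 2)
  expect_equal(m7$biomass, 6)
  w5 <- calibrate_scenario("wt_ph5")
  expect_equal(w5$schedule$feed_rate_mL_h, c(12, 19.8, 38.1))
  b <- calibrate_scenario("wt_batch_scavenger")
  expect_equal(b$V0, 0.5)
  expect_equal(b$conc0[["scavenger"]], 50.6)
  expect_equal(b$mode, "batch")
  expect_error(calibrate_scenario("wt_ph9"), "wt_ph7")
})
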