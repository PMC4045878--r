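# Batch and variable-volume fed-batch rate equations.

test_that("batch volumetric rate reproduces the defining difference quotient", {
  s <- make_batch_series(t = c(0, 1, 2, 3), hpa = c(0, 9, 18, 26.2))
  expect_equal(batch_volumetric_rate(s, "hpa", pdu_window(0, 3)),
               26.2 / 3, tolerance = 1e-12)
  expect_equal(batch_volumetric_rate(s, "hp", pdu_window(0, 3)), 0)
  g <- make_batch_series(t = c(0, 2, 4, 6), glycerol = c(50, 34, 17, 0))
  expect_equal(batch_volumetric_rate(g, "glycerol", pdu_window(0, 6)),
               -50 / 6, tolerance = 1e-12)
  expect_error(batch_volumetric_rate(s, "hpa", pdu_window(10, 20)),
               "outside")
})

test_that("batch specific rate scales by cell density and keeps sign", {
  expect_equal(batch_specific_rate(26.2 / 3, 6), 1455.556, tolerance = 1e-4)
  expect_equal(batch_specific_rate(0, 6), 0)
  expect_equal(batch_specific_rate(-50 / 6, 6), -1388.889, tolerance = 1e-4)
  expect_error(batch_specific_rate(1, 0), "positive")
})

test_that("fed-batch production rate uses the variable-volume mass balance", {
  s <- make_fedbatch_series(t = c(0, 5, 10), V = c(1, 1.1, 1.2),
                            hp = c(0, 2, 4))
  expect_equal(fedbatch_production_rate(s, "hp", pdu_window(0, 10)),
               (4 * 1.2 - 0) / 10, tolerance = 1e-12)
  flat <- make_fedbatch_series(t = c(0, 5, 10), V = c(1, 1.25, 1.5),
                               pdo = c(3, 2.4, 2))  # P*V constant
  expect_equal(fedbatch_production_rate(flat, "pdo", pdu_window(0, 10)), 0,
               tolerance = 1e-12)
})

test_that("fed-batch consumption rate accounts for the fed substrate mass", {
  stp <- list(start_h = 0, end_h = 10, feed_conc_g_L = 50,
              F_vol_L_h = 0.032)  # 1.6 g/h
  s <- make_fedbatch_series(t = c(0, 5, 10), V = c(1, 1.16, 1.32),
                            glycerol = 0)
  expect_equal(
    fedbatch_consumption_rate(s, "glycerol", pdu_window(0, 10), stp),
    -1.6, tolerance = 1e-12)

  idle <- list(start_h = 0, end_h = 10, feed_conc_g_L = 0, F_vol_L_h = 0)
  c0 <- make_fedbatch_series(t = c(0, 5, 10), V = 1, glycerol = 5)
  expect_equal(
    fedbatch_consumption_rate(c0, "glycerol", pdu_window(0, 10), idle), 0)

  stp2 <- list(start_h = 0, end_h = 10, feed_conc_g_L = 50,
               F_vol_L_h = 0.012)  # 0.6 g/h
  s2 <- make_fedbatch_series(t = c(0, 10), V = c(1, 1.12),
                             glycerol = c(2, 0))
  expect_equal(
    fedbatch_consumption_rate(s2, "glycerol", pdu_window(0, 10), stp2),
    -0.8, tolerance = 1e-12)

  # window crossing a feed-rate change must be refused
  expect_error(
    fedbatch_consumption_rate(s, "glycerol", pdu_window(0, 10),
                              list(start_h = 0, end_h = 5,
                                   feed_conc_g_L = 50, F_vol_L_h = 0.032)),
    "feed-rate change")
})

test_that("fed-batch specific rate scales by biocatalyst amount", {
  expect_equal(fedbatch_specific_rate(-1.6, 6), -266.667, tolerance = 1e-4)
  expect_equal(fedbatch_specific_rate(0.3, 6), 50)
  expect_equal(fedbatch_specific_rate(-2.5, 6), -416.667, tolerance = 1e-4)
  expect_error(fedbatch_specific_rate(1, -2), "positive")
})

test_that("batch and fed-batch paths agree on constant-volume data", {
  t <- c(0, 2, 4, 6)
  hp <- c(0, 1.1, 2.3, 3.3)
  b <- make_batch_series(t, hp = hp, V = 0.5, X = 6)
  fb <- make_fedbatch_series(t, V = 0.5, hp = hp, x = 6 * 0.5)
  w <- pdu_window(0, 6)
  q_batch <- batch_specific_rate(batch_volumetric_rate(b, "hp", w), 6)
  q_fed <- fedbatch_specific_rate(fedbatch_production_rate(fb, "hp", w),
                                  6 * 0.5)
  expect_equal(q_batch, q_fed, tolerance = 1e-12)
})

test_that("endpoint rates ignore intermediate samples", {
  t1 <- c(0, 10)
  t2 <- c(0, 2.5, 5, 7.5, 10)
  mk <- function(t) make_fedbatch_series(
    t, V = 1 + 0.02 * t, hp = 1 + 0.3 * t + 0.05 * sin(t))
  w <- pdu_window(0, 10)
  expect_equal(fedbatch_production_rate(mk(t1), "hp", w),
               fedbatch_production_rate(mk(t2), "hp", w))
})

test_that("complete in-step consumption recovers the feed rate exactly", {
  cfg <- single_step_config(0.6)
  ts <- simulate_reactor(cfg)
  stp <- cfg$schedule[1, ]
  r <- fedbatch_consumption_rate(ts, "glycerol", pdu_window(10, 15), stp)
  expect_equal(r, -stp$F_mass_g_h, tolerance = 5e-3)
})

test_that("molar yields and product ratio follow from V*C differences", {
  # equimolar lossless conversion of 0.6 g/h glycerol feed over 10 h
  mm <- c(gly = 92.09, hp = 90.08, pdo = 76.09)
  fed_mol <- 6 / mm[["gly"]]
  V <- c(1, 1.12)
  hp_f <- fed_mol / 2 * mm[["hp"]] / V[2]
  pdo_f <- fed_mol / 2 * mm[["pdo"]] / V[2]
  s <- make_fedbatch_series(t = c(0, 10), V = V, glycerol = 0,
                            hp = c(0, hp_f), pdo = c(0, pdo_f))
  sched <- feed_schedule(data.frame(start_h = 0, end_h = 10,
                                    feed_conc_g_L = 50, feed_rate_mL_h = 12))
  expect_equal(cumulative_molar_yield(s, schedule = sched), 1,
               tolerance = 1e-12)
  expect_equal(product_molar_ratio(s), 1, tolerance = 1e-12)

  # diverting 10 mol% of consumption into 3HPA forces yield 0.90
  hpa_f <- fed_mol * 0.1 * 74.08 / V[2]
  s2 <- make_fedbatch_series(t = c(0, 10), V = V, glycerol = 0,
                             hpa = c(0, hpa_f),
                             hp = c(0, hp_f * 0.9), pdo = c(0, pdo_f * 0.9))
  expect_equal(cumulative_molar_yield(s2, schedule = sched), 0.9,
               tolerance = 1e-12)
  expect_equal(cumulative_molar_yield(s2, schedule = sched,
                                      species = c("hp", "pdo", "hpa_total")),
               1, tolerance = 1e-12)

  # final titers 10.6 g/L 3HP and 9.0 g/L 1,3PDO at equal volume
  s3 <- make_fedbatch_series(t = c(0, 10), V = 1, glycerol = c(20, 0),
                             hp = c(0, 10.6), pdo = c(0, 9.0))
  expect_equal(product_molar_ratio(s3), 0.99486, tolerance = 1e-4)

  s4 <- make_fedbatch_series(t = c(0, 10), V = 1, glycerol = c(20, 10),
                             hp = c(0, 5))
  expect_error(product_molar_ratio(s4), "1,3PDO")
})

test_that("regression estimator matches endpoint slopes on linear data", {
  t <- seq(0, 10, by = 0.5)
  s <- make_fedbatch_series(t, V = 1 + 0.012 * t, hp = 0.25 * t)
  w <- pdu_window(0, 10)
  ep <- fedbatch_production_rate(s, "hp", w)
  rg <- fedbatch_production_rate(s, "hp", w, estimator = "regression")
  expect_equal(rg, ep, tolerance = 1e-6)
})
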