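# Deterministic kinetic ODE simulator of resting-cell glycerol
# biotransformation: multi-step variable-volume fed-batch (3HP + 1,3PDO
# co-production) and constant-volume batch with a carbohydrazide 3HPA
# scavenger (3HPA production). Biomass is constant (resting cells); the
# state carries moles of each extracellular species, the reactor volume
# and the intracellular reduced-cofactor carryover pool.

#' Kinetic parameters of the resting-cell simulator
#'
#' Rate-law constants for the glycerol dehydratase (GDH) step and the
#' redox-coupled branch pair. GDH follows substrate-inhibition (Haldane)
#' kinetics with non-competitive 1,3PDO inhibition and a shut-off above a
#' toxic free-3HPA concentration; the two branches share a saturable
#' capacity and are stoichiometrically redox-coupled (`r2 = r3`) once the
#' cofactor pool carried over from growth has been drawn down.
#'
#' @param vmax_gdh Maximum specific glycerol dehydration rate
#'   (mmol/g_CDW.h).
#' @param Km_gly GDH affinity constant for glycerol (g/L).
#' @param Ki_gly Substrate-inhibition constant of GDH for glycerol (g/L).
#' @param Ki_pdo Inhibition constant of GDH for 1,3PDO (g/L).
#' @param vmax_branch Shared maximum specific rate of each branch
#'   (mmol/g_CDW.h): max v2 = max v3.
#' @param Km_hpa Branch affinity constant for free 3HPA (g/L).
#' @param hpa_pdup_threshold Free-3HPA concentration above which the
#'   oxidative branch enzyme (PduP) is inhibited (g/L; default 0.6).
#' @param pdup_inhibition_floor Residual branch activity fraction well
#'   above the threshold, in (0, 1]; 1 disables the penalty.
#' @param pdup_inhibition_width Width of the smooth (logistic) inhibition
#'   transition (g/L); keeps the right-hand side Lipschitz.
#' @param pdup_inhibition_smooth If `FALSE`, use a hard threshold instead
#'   of the logistic penalty.
#' @param hpa_toxic_threshold Free-3HPA concentration at which GDH activity
#'   is lost when no scavenger is active (g/L).
#' @param hpa_toxic_width Width of the smooth GDH shut-off (g/L).
#' @param nadh_pool Initial intracellular reduced-cofactor carryover from
#'   the growth phase (mmol/g_CDW); drives the early excess of 1,3PDO over
#'   3HP.
#' @param nadh_drain_k First-order drawdown rate constant of the carryover
#'   pool (1/h).
#' @param scavenger_stoich Moles of aldehyde bound per mole of scavenger.
#' @param k_bind Second-order rate constant of the irreversible
#'   3HPA-scavenger complexation (L/mol.h); large by default so free 3HPA
#'   stays far below the inhibition thresholds while scavenger remains.
#' @param scavenger_active_floor Free scavenger concentration (g/L) above
#'   which the culture is considered protected from 3HPA toxicity.
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(vmax_gdh = 17.2,
                           Km_gly = 0.2,
                           Ki_gly = 150,
                           Ki_pdo = 50,
                           vmax_branch = 1.25,
                           Km_hpa = 0.1,
                           hpa_pdup_threshold = 0.6,
                           pdup_inhibition_floor = 0.9,
                           pdup_inhibition_width = 0.1,
                           pdup_inhibition_smooth = TRUE,
                           hpa_toxic_threshold = 5,
                           hpa_toxic_width = 0.2,
                           nadh_pool = 0.05,
                           nadh_drain_k = 2,
                           scavenger_stoich = 1,
                           k_bind = 1e4,
                           scavenger_active_floor = 0.5) {
  p <- list(vmax_gdh = vmax_gdh, Km_gly = Km_gly, Ki_gly = Ki_gly,
            Ki_pdo = Ki_pdo, vmax_branch = vmax_branch, Km_hpa = Km_hpa,
            hpa_pdup_threshold = hpa_pdup_threshold,
            pdup_inhibition_floor = pdup_inhibition_floor,
            pdup_inhibition_width = pdup_inhibition_width,
            pdup_inhibition_smooth = pdup_inhibition_smooth,
            hpa_toxic_threshold = hpa_toxic_threshold,
            hpa_toxic_width = hpa_toxic_width,
            nadh_pool = nadh_pool, nadh_drain_k = nadh_drain_k,
            scavenger_stoich = scavenger_stoich, k_bind = k_bind,
            scavenger_active_floor = scavenger_active_floor)
  caps <- c("vmax_gdh", "Km_gly", "Ki_gly", "Ki_pdo", "vmax_branch",
            "Km_hpa", "nadh_pool", "nadh_drain_k", "k_bind")
  if (any(unlist(p[caps]) < 0))
    stop("capacities and kinetic constants must be non-negative")
  if (hpa_pdup_threshold <= 0 || hpa_toxic_threshold <= 0)
    stop("inhibition thresholds must be positive")
  if (pdup_inhibition_floor <= 0 || pdup_inhibition_floor > 1)
    stop("pdup_inhibition_floor must lie in (0, 1]")
  class(p) <- "kinetic_params"
  p
}

#' Specific glycerol dehydration rate (GDH)
#'
#' Haldane substrate-inhibition kinetics in glycerol, non-competitive
#' inhibition by 1,3PDO, and a smooth shut-off when free 3HPA reaches the
#' toxic threshold with no active scavenger present.
#'
#' @param S Glycerol concentration (g/L).
#' @param PDO 1,3PDO concentration (g/L).
#' @param A_free Free 3HPA concentration (g/L).
#' @param p A [kinetic_params()] object.
#' @param scavenger_active Logical; an active aldehyde scavenger exempts
#'   the cells from the 3HPA toxicity shut-off.
#' @return Rate in mmol/g_CDW.h, in `[0, vmax_gdh]`.
#' @export
gdh_rate <- function(S, PDO, A_free, p, scavenger_active = FALSE) {
  if (any(c(S, PDO, A_free) < 0)) stop("concentrations must be non-negative")
  sat <- S / (p$Km_gly + S + S^2 / p$Ki_gly)
  pdo_inh <- p$Ki_pdo / (p$Ki_pdo + PDO)
  gate <- if (scavenger_active) 1 else
    1 / (1 + exp((A_free - p$hpa_toxic_threshold) / p$hpa_toxic_width))
  p$vmax_gdh * sat * pdo_inh * gate
}

# Logistic PduP inhibition penalty in (floor, 1]; optionally a hard step.
pdup_penalty <- function(A, p) {
  if (p$pdup_inhibition_smooth) {
    p$pdup_inhibition_floor + (1 - p$pdup_inhibition_floor) /
      (1 + exp((A - p$hpa_pdup_threshold) / p$pdup_inhibition_width))
  } else {
    ifelse(A < p$hpa_pdup_threshold, 1, p$pdup_inhibition_floor)
  }
}

#' Specific rates of the redox-coupled 3HPA branches
#'
#' The oxidative (3HP, `r3`) and reductive (1,3PDO, `r2`) branches share a
#' saturable capacity in free 3HPA with a smooth PduP inhibition penalty
#' above the threshold concentration. Because the branches cycle one
#' NADH/NAD+ pair, `r2 = r3` at the cofactor quasi-steady state; while the
#' reduced-cofactor pool carried over from growth remains, `r2` carries an
#' additional drain term that consumes the excess NADH (early transient
#' 1,3PDO surplus).
#'
#' @param A_free Free 3HPA concentration (g/L).
#' @param nadh Current carryover pool (mmol/g_CDW).
#' @param p A [kinetic_params()] object.
#' @return Named numeric `c(r2 = ..., r3 = ..., drain = ...)` in
#'   mmol/g_CDW.h; `r2 = r3 + drain`.
#' @export
branch_rates <- function(A_free, nadh, p) {
  if (A_free < 0 || nadh < 0) stop("inputs must be non-negative")
  sat <- A_free / (p$Km_hpa + A_free)
  r <- p$vmax_branch * sat * pdup_penalty(A_free, p)
  drain <- p$nadh_drain_k * nadh * sat
  c(r2 = r + drain, r3 = r, drain = drain)
}

#' Simulator configuration
#'
#' @param mode `"fedbatch"` or `"batch"`.
#' @param V0 Initial working volume (L).
#' @param conc0 Named initial concentrations in g/L; recognised names are
#'   `glycerol`, `hpa`, `hp`, `pdo`, `scavenger`, `hpa_complex` (missing
#'   names default to 0).
#' @param biomass Cell density X (g_CDW/L) in batch mode or total
#'   biocatalyst x (g_CDW) in fed-batch mode.
#' @param schedule A [feed_schedule()] (`NULL` for batch).
#' @param params A [kinetic_params()] object.
#' @param t_end Protocol end time (h); defaults to the schedule end.
#' @param grid Output sampling interval (h).
#' @param rtol,atol Relative and absolute (mol) solver tolerances.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mode = c("fedbatch", "batch"), V0, conc0, biomass,
                       schedule = NULL, params = kinetic_params(),
                       t_end = NULL, grid = 0.25,
                       rtol = 1e-8, atol = 1e-10) {
  mode <- match.arg(mode)
  known <- c("glycerol", "hpa", "hp", "pdo", "scavenger", "hpa_complex")
  unknown <- setdiff(names(conc0), known)
  if (length(unknown))
    stop("unknown initial species: ", paste(unknown, collapse = ", "))
  full <- setNames(numeric(length(known)), known)
  full[names(conc0)] <- unlist(conc0)
  if (any(full < 0)) stop("initial concentrations must be non-negative")
  if (V0 <= 0) stop("V0 must be positive")
  if (biomass <= 0) stop("biomass must be positive")
  if (is.null(t_end)) {
    if (is.null(schedule)) stop("t_end is required when there is no schedule")
    t_end <- max(schedule$end_h)
  }
  if (grid <= 0 || grid > t_end) stop("grid must lie in (0, t_end]")
  structure(list(mode = mode, V0 = V0, conc0 = full, biomass = biomass,
                 schedule = schedule, params = params, t_end = t_end,
                 grid = grid, rtol = rtol, atol = atol),
            class = "sim_config")
}

# Piecewise-constant feed profile: data.frame of segments with F_vol (L/h)
# and feed_conc (g/L) covering [0, t_end].
feed_segments <- function(schedule, t_end) {
  if (is.null(schedule) || nrow(schedule) == 0)
    return(data.frame(t0 = 0, t1 = t_end, F_vol = 0, feed_conc = 0))
  brk <- sort(unique(c(0, schedule$start_h, schedule$end_h, t_end)))
  brk <- brk[brk <= t_end + 1e-12]
  if (max(brk) < t_end) brk <- c(brk, t_end)
  seg <- data.frame(t0 = head(brk, -1), t1 = tail(brk, -1))
  mid <- (seg$t0 + seg$t1) / 2
  seg$F_vol <- 0; seg$feed_conc <- 0
  for (k in seq_len(nrow(schedule))) {
    in_step <- mid >= schedule$start_h[k] & mid < schedule$end_h[k]
    seg$F_vol[in_step] <- schedule$F_vol_L_h[k]
    seg$feed_conc[in_step] <- schedule$feed_conc_g_L[k]
  }
  seg[seg$t1 > seg$t0 + 1e-12, , drop = FALSE]
}

# ODE right-hand side. State y (mol except where noted):
# gly, hpa, cplx, hp, pdo, scv, nadh (mmol/g_CDW), V (L).
reactor_derivs <- function(t, y, parms) {
  p <- parms$params
  x <- parms$x_cdw
  mm <- parms$mm
  V <- y[["V"]]
  gL <- function(mol, m) max(mol, 0) * unname(m) / V
  S <- gL(y[["gly"]], mm["glycerol"])
  A <- gL(y[["hpa"]], mm["hpa"])
  PDO <- gL(y[["pdo"]], mm["pdo"])
  Scv <- gL(y[["scv"]], mm["carbohydrazide"])
  scav_active <- Scv >= p$scavenger_active_floor
  v1 <- gdh_rate(S, PDO, A, p, scavenger_active = scav_active)
  br <- branch_rates(A, max(y[["nadh"]], 0), p)
  # mmol/g_CDW.h -> mol/h for the whole reactor
  to_mol <- x / 1000
  v1m <- v1 * to_mol
  r2m <- br[["r2"]] * to_mol
  r3m <- br[["r3"]] * to_mol
  bind <- p$k_bind * max(y[["hpa"]], 0) * max(y[["scv"]], 0) / V
  gly_in <- parms$F_vol * parms$feed_conc / mm["glycerol"]
  list(c(gly = gly_in - v1m,
         hpa = v1m - r2m - r3m - bind,
         cplx = bind,
         hp = r3m,
         pdo = r2m,
         scv = -bind / p$scavenger_stoich,
         nadh = -br[["drain"]],
         V = parms$F_vol))
}

#' Simulate a resting-cell biotransformation run
#'
#' Integrates the reactor mass balances (`dV/dt = F_vol`; feed inflow plus
#' the stoichiometric combination of [gdh_rate()], [branch_rates()] and the
#' irreversible 3HPA-scavenger complexation) with a stiff-capable solver
#' (`deSolve::lsoda`), segment by segment over the piecewise-constant feed
#' profile, and samples the state on a fixed output grid. Deterministic
#' given the configuration; the C3 backbone is conserved by construction.
#'
#' @param cfg A [sim_config()].
#' @return A [pdu_timeseries()] on the output grid, with scavenger/complex
#'   columns when a scavenger is present. The attribute `solver` records
#'   tolerances and segment boundaries.
#' @export
simulate_reactor <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a 'sim_config'")
  p <- cfg$params
  net <- build_pdu_network()
  mm <- setNames(net$metabolites$molar_mass, net$metabolites$id)
  x_cdw <- if (cfg$mode == "batch") cfg$biomass * cfg$V0 else cfg$biomass
  # initial state in mol (complex column carries 3HPA mass-equivalents)
  y <- c(gly = cfg$conc0[["glycerol"]] * cfg$V0 / mm[["glycerol"]],
         hpa = cfg$conc0[["hpa"]] * cfg$V0 / mm[["hpa"]],
         cplx = cfg$conc0[["hpa_complex"]] * cfg$V0 / mm[["hpa"]],
         hp = cfg$conc0[["hp"]] * cfg$V0 / mm[["hp"]],
         pdo = cfg$conc0[["pdo"]] * cfg$V0 / mm[["pdo"]],
         scv = cfg$conc0[["scavenger"]] * cfg$V0 / mm[["carbohydrazide"]],
         nadh = p$nadh_pool,
         V = cfg$V0)
  grid_times <- seq(0, cfg$t_end, by = cfg$grid)
  if (max(grid_times) < cfg$t_end - 1e-9)
    grid_times <- c(grid_times, cfg$t_end)
  seg <- feed_segments(cfg$schedule, cfg$t_end)
  out <- matrix(NA_real_, nrow = length(grid_times), ncol = length(y) + 1,
                dimnames = list(NULL, c("time", names(y))))
  out[1, ] <- c(grid_times[1], y)
  for (k in seq_len(nrow(seg))) {
    inside <- grid_times > seg$t0[k] + 1e-12 & grid_times <= seg$t1[k] + 1e-12
    times <- sort(unique(c(seg$t0[k], grid_times[inside], seg$t1[k])))
    parms <- list(params = p, x_cdw = x_cdw, mm = mm,
                  F_vol = seg$F_vol[k], feed_conc = seg$feed_conc[k])
    sol <- deSolve::lsoda(y, times, reactor_derivs, parms,
                          rtol = cfg$rtol, atol = cfg$atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failed near t = ", round(max(sol[, "time"]), 4), " h")
    neg <- sol[, names(y)][, c("gly", "hpa", "cplx", "hp", "pdo", "scv")] <
      -1e-6
    if (any(neg))
      stop("negative state encountered at t = ",
           round(sol[which(rowSums(neg) > 0)[1], "time"], 4),
           " h; check kinetic parameters")
    keep <- match(round(grid_times[inside], 10), round(sol[, "time"], 10))
    out[inside, ] <- sol[keep, c("time", names(y)), drop = FALSE]
    y <- sol[nrow(sol), names(y)]
  }
  V <- out[, "V"]
  df <- data.frame(time_h = out[, "time"],
                   volume_L = V,
                   glycerol_g_L = pmax(out[, "gly"], 0) * mm[["glycerol"]] / V,
                   hpa_g_L = pmax(out[, "hpa"], 0) * mm[["hpa"]] / V,
                   hp_g_L = pmax(out[, "hp"], 0) * mm[["hp"]] / V,
                   pdo_g_L = pmax(out[, "pdo"], 0) * mm[["pdo"]] / V)
  has_scav <- cfg$conc0[["scavenger"]] > 0 || cfg$conc0[["hpa_complex"]] > 0
  if (has_scav) {
    df$scavenger_g_L <- pmax(out[, "scv"], 0) * mm[["carbohydrazide"]] / V
    df$hpa_complex_g_L <- pmax(out[, "cplx"], 0) * mm[["hpa"]] / V
  }
  ts <- pdu_timeseries(df, mode = cfg$mode, biomass = cfg$biomass)
  attr(ts, "solver") <- list(rtol = cfg$rtol, atol = cfg$atol,
                             segments = seg, nadh_final = y[["nadh"]])
  ts
}

#' Simulate a batch run with in situ 3HPA complexation
#'
#' Convenience wrapper over [simulate_reactor()] for the constant-volume
#' batch protocol with a carbohydrazide scavenger: free 3HPA is bound
#' irreversibly (1:1 by default) into a complex that is exempt from the
#' inhibition terms, so GDH keeps running while free scavenger remains;
#' once the scavenger exhausts, free 3HPA accumulates and the toxicity
#' shut-off re-engages.
#'
#' @param cfg A [sim_config()] in batch mode with a positive initial
#'   scavenger concentration.
#' @return A [pdu_timeseries()].
#' @export
simulate_batch_scavenger <- function(cfg) {
  if (cfg$mode != "batch")
    stop("simulate_batch_scavenger requires a batch-mode configuration")
  if (cfg$conc0[["scavenger"]] <= 0)
    stop("no scavenger in the initial state; use simulate_reactor()")
  simulate_reactor(cfg)
}
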