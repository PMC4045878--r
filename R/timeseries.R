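# Reactor time-series and feed-schedule containers plus their plain-text
# formats (CSV dialect and YAML/JSON configs).

# Canonical CSV column order; scavenger columns optional.
ts_columns <- c("time_h", "volume_L", "glycerol_g_L", "hpa_g_L", "hp_g_L",
                "pdo_g_L")
ts_columns_opt <- c("scavenger_g_L", "hpa_complex_g_L")

# Map CSV column -> metabolite id.
ts_species_map <- c(glycerol_g_L = "glycerol", hpa_g_L = "hpa",
                    hp_g_L = "hp", pdo_g_L = "pdo",
                    scavenger_g_L = "carbohydrazide",
                    hpa_complex_g_L = "hpa_complex")

#' Construct a reactor time series
#'
#' A sampled reactor state: time (h), working volume (L) and species
#' concentrations (g/L), plus the operating mode and biocatalyst amount
#' needed to convert volumetric/absolute rates into specific rates.
#'
#' @param data A data.frame with columns `time_h`, `volume_L`,
#'   `glycerol_g_L`, `hpa_g_L`, `hp_g_L`, `pdo_g_L` and optionally
#'   `scavenger_g_L`, `hpa_complex_g_L`. Time must be strictly increasing,
#'   volumes positive, concentrations non-negative.
#' @param mode `"batch"` (constant volume) or `"fedbatch"`.
#' @param biomass Biocatalyst amount: cell density X in g_CDW/L for batch
#'   mode, total cell dry weight x in g_CDW for fed-batch mode.
#' @return A data.frame of class `pdu_timeseries` with attributes `mode`
#'   and `biomass`.
#' @export
pdu_timeseries <- function(data, mode = c("fedbatch", "batch"), biomass) {
  mode <- match.arg(mode)
  missing_cols <- setdiff(ts_columns, names(data))
  if (length(missing_cols))
    stop("time series is missing columns: ",
         paste(missing_cols, collapse = ", "))
  keep <- c(ts_columns, intersect(ts_columns_opt, names(data)))
  data <- as.data.frame(data)[, keep]
  if (nrow(data) < 1) stop("time series must contain at least one sample")
  if (any(diff(data$time_h) <= 0))
    stop("time_h must be strictly increasing")
  if (any(data$volume_L <= 0)) stop("volume_L must be positive")
  conc <- as.matrix(data[, setdiff(keep, c("time_h", "volume_L"))])
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (mode == "batch" && diff(range(data$volume_L)) > 1e-9)
    stop("batch mode requires a constant volume")
  if (!is.numeric(biomass) || length(biomass) != 1 || biomass <= 0)
    stop("biomass must be a single positive number")
  structure(data, mode = mode, biomass = biomass,
            class = c("pdu_timeseries", "data.frame"))
}

ts_mode <- function(series) attr(series, "mode")
ts_biomass <- function(series) attr(series, "biomass")

#' @export
print.pdu_timeseries <- function(x, ...) {
  cat(sprintf("Reactor time series (%s mode, biomass %.3g %s): %d samples, %.2f-%.2f h\n",
              ts_mode(x), ts_biomass(x),
              if (ts_mode(x) == "batch") "g_CDW/L" else "g_CDW",
              nrow(x), min(x$time_h), max(x$time_h)))
  NextMethod()
}

#' Read a reactor time series from delimited text
#'
#' Parses the package CSV dialect (`time_h,volume_L,glycerol_g_L,hpa_g_L,
#' hp_g_L,pdo_g_L[,scavenger_g_L,hpa_complex_g_L]`; decimal point, UTF-8,
#' one row per sample).
#'
#' @param path Path to the CSV file.
#' @inheritParams pdu_timeseries
#' @return A `pdu_timeseries`.
#' @export
read_timeseries <- function(path, mode = c("fedbatch", "batch"), biomass) {
  df <- read.csv(path, check.names = TRUE)
  unknown <- setdiff(names(df), c(ts_columns, ts_columns_opt))
  if (length(unknown))
    stop("unknown species column(s) in '", path, "': ",
         paste(unknown, collapse = ", "))
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric values in '", path, "', column(s) ",
         paste(names(df)[bad], collapse = ", "),
         " (first data line is line 2)")
  pdu_timeseries(df, mode = mode, biomass = biomass)
}

#' Write a reactor time series as delimited text
#'
#' @param series A `pdu_timeseries`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a feeding schedule
#'
#' Ordered, non-overlapping glycerol feeding steps defining a
#' variable-volume fed-batch protocol. The mass feed rate of each step is
#' derived as `F_mass = feed_conc_g_L * feed_rate_mL_h / 1000` g/h.
#'
#' @param steps A data.frame with columns `start_h`, `end_h`,
#'   `feed_conc_g_L`, `feed_rate_mL_h` (one row per step).
#' @return A data.frame of class `feed_schedule` with added columns
#'   `step` (id), `F_vol_L_h` and `F_mass_g_h`.
#' @examples
#' feed_schedule(data.frame(start_h = 1, end_h = 11,
#'                          feed_conc_g_L = 50, feed_rate_mL_h = 12))
#' @export
feed_schedule <- function(steps) {
  req <- c("start_h", "end_h", "feed_conc_g_L", "feed_rate_mL_h")
  if (!all(req %in% names(steps)))
    stop("feed schedule needs columns: ", paste(req, collapse = ", "))
  steps <- as.data.frame(steps)[, req]
  steps <- steps[order(steps$start_h), , drop = FALSE]
  if (any(steps$end_h <= steps$start_h))
    stop("each feed step must have end_h > start_h")
  if (any(steps$feed_rate_mL_h < 0) || any(steps$feed_conc_g_L < 0))
    stop("feed rates and concentrations must be non-negative")
  if (nrow(steps) > 1 &&
      any(steps$start_h[-1] < steps$end_h[-nrow(steps)] - 1e-9))
    stop("feed steps must not overlap")
  steps$step <- seq_len(nrow(steps))
  steps$F_vol_L_h <- steps$feed_rate_mL_h / 1000
  steps$F_mass_g_h <- steps$feed_conc_g_L * steps$F_vol_L_h
  rownames(steps) <- NULL
  structure(steps, class = c("feed_schedule", "data.frame"))
}

#' Read a feeding schedule from a structured config file
#'
#' Accepts YAML or JSON containing a list of steps, each with `start_h`,
#' `end_h`, `feed_conc_g_L`, `feed_rate_mL_h` (optionally nested under a
#' top-level `steps` key).
#'
#' @param path Path to the config file.
#' @return A `feed_schedule`.
#' @export
read_feed_schedule <- function(path) {
  cfg <- read_structured_config(path)
  if (!is.null(cfg$steps)) cfg <- cfg$steps
  if (is.data.frame(cfg)) return(feed_schedule(cfg))
  feed_schedule(do.call(rbind, lapply(cfg, function(s)
    data.frame(start_h = s$start_h, end_h = s$end_h,
               feed_conc_g_L = s$feed_conc_g_L,
               feed_rate_mL_h = s$feed_rate_mL_h))))
}

#' Write a feeding schedule to a structured config file
#'
#' @param schedule A `feed_schedule`.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_feed_schedule <- function(schedule, path) {
  steps <- lapply(seq_len(nrow(schedule)), function(i)
    list(start_h = schedule$start_h[i], end_h = schedule$end_h[i],
         feed_conc_g_L = schedule$feed_conc_g_L[i],
         feed_rate_mL_h = schedule$feed_rate_mL_h[i]))
  write_structured_config(list(steps = steps), path)
  invisible(path)
}

# --- shared structured-config helpers (YAML or JSON by extension) ----------

read_structured_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: '", path, "'")
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else
    yaml::read_yaml(path)
}

write_structured_config <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else
    yaml::write_yaml(x, path)
  invisible(path)
}

# --- analysis windows -------------------------------------------------------

#' Define an analysis window
#'
#' A `[t_start, t_end]` interval (h) selecting the initial and final samples
#' used by the endpoint rate equations. Endpoints snap to the nearest
#' recorded sample; no interpolation is performed.
#'
#' @param t_start,t_end Window bounds in hours, `t_end > t_start`.
#' @return A list of class `pdu_window`.
#' @export
pdu_window <- function(t_start, t_end) {
  if (!is.finite(t_start) || !is.finite(t_end) || t_end <= t_start)
    stop("window requires finite t_end > t_start")
  structure(list(t_start = t_start, t_end = t_end), class = "pdu_window")
}

# Snap window endpoints to nearest samples; returns row indices (i, f).
snap_window <- function(series, w) {
  if (!inherits(w, "pdu_window")) w <- pdu_window(w[[1]], w[[2]])
  t <- series$time_h
  span <- range(t)
  if (w$t_end < span[1] - 1e-9 || w$t_start > span[2] + 1e-9)
    stop("window [", w$t_start, ", ", w$t_end,
         "] lies outside the time series span [", span[1], ", ", span[2], "]")
  i <- which.min(abs(t - w$t_start))
  f <- which.min(abs(t - w$t_end))
  if (f <= i)
    stop("window snaps to fewer than 2 samples; widen the window or sample",
         " more densely")
  c(i = i, f = f)
}
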