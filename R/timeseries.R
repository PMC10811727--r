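# Reactor time-series container and file formats.

TS_COLUMNS <- c("time_h", "no3_mmolN_l", "no2_mmolN_l", "nh4_mmolN_l",
                "n2_mmolN_total", "alkane_mmol_total", "co2_mmol_total")

#' Batch-incubation time series
#'
#' Measured profiles of a sealed anoxic incubation. Dissolved nitrogen
#' species are concentrations per litre of liquid; N2, alkane and CO2 are
#' vessel-total inventories (headspace + dissolved), N2 expressed as mmol N.
#'
#' @param time_h Sampling times in hours, strictly increasing.
#' @param no3,no2,nh4 mmol N per litre liquid.
#' @param n2_total Vessel-total mmol N as N2.
#' @param alkane_total Vessel-total mmol alkane molecules.
#' @param co2_total Vessel-total mmol CO2.
#' @param geometry A [vessel_geometry()].
#' @param n_carbons Carbon number of the fed alkane.
#' @return A `nitralk_timeseries`, a data frame with attributes `geometry`
#'   and `n_carbons`.
#' @export
reactor_timeseries <- function(time_h, no3, no2, nh4, n2_total, alkane_total,
                               co2_total, geometry, n_carbons) {
  stopifnot(inherits(geometry, "nitralk_geometry"))
  cols <- list(time_h = time_h, no3_mmolN_l = no3, no2_mmolN_l = no2,
               nh4_mmolN_l = nh4, n2_mmolN_total = n2_total,
               alkane_mmol_total = alkane_total, co2_mmol_total = co2_total)
  len <- unique(vapply(cols, length, integer(1)))
  if (length(len) != 1L)
    stop("all series must have equal length", call. = FALSE)
  if (len == 0L) stop("time series is empty", call. = FALSE)
  if (any(diff(time_h) <= 0))
    stop("time_h must be strictly increasing", call. = FALSE)
  for (nm in names(cols))
    if (any(cols[[nm]] < 0))
      stop("negative value in column '", nm, "'", call. = FALSE)
  df <- as.data.frame(cols)
  structure(df, geometry = geometry,
            n_carbons = as.integer(n_carbons),
            class = c("nitralk_timeseries", "data.frame"))
}

#' Read a reactor time series from CSV
#'
#' Expects the columns
#' `time_h,no3_mmolN_l,no2_mmolN_l,nh4_mmolN_l,n2_mmolN_total,alkane_mmol_total,co2_mmol_total`
#' and validates the schema (monotone time, non-negative values), reporting
#' the offending column and row in errors.
#'
#' @param path CSV file.
#' @param geometry A [vessel_geometry()] for the vessel the series came from.
#' @param n_carbons Carbon number of the fed alkane.
#' @return A `nitralk_timeseries`.
#' @export
read_timeseries <- function(path, geometry, n_carbons) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TS_COLUMNS, names(df))
  if (length(miss))
    stop("time-series CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("time-series CSV '", path, "' is empty",
                           call. = FALSE)
  bad <- which(diff(df$time_h) <= 0)
  if (length(bad))
    stop("time_h not strictly increasing at data row ", bad[1] + 1L,
         " of '", path, "'", call. = FALSE)
  for (nm in TS_COLUMNS) {
    neg <- which(df[[nm]] < 0)
    if (length(neg))
      stop("negative ", nm, " at data row ", neg[1], " of '", path, "'",
           call. = FALSE)
  }
  reactor_timeseries(df$time_h, df$no3_mmolN_l, df$no2_mmolN_l,
                     df$nh4_mmolN_l, df$n2_mmolN_total,
                     df$alkane_mmol_total, df$co2_mmol_total,
                     geometry, n_carbons)
}

#' Write a reactor time series to CSV
#'
#' Emits exactly the schema [read_timeseries()] expects, so write/read
#' round-trips are identities.
#'
#' @param ts A `nitralk_timeseries`.
#' @param path Output file.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.csv(as.data.frame(ts)[TS_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' Plain declarative `key = value` text with `#` comments. Units are part of
#' the key names. Recognised keys: `v_gas_l`, `v_liq_l`, `temp_K`,
#' `n_carbons`, `threshold_mmolN_l`, `solubility_csv`, `formation_csv`,
#' `ph`, `seed`.
#'
#' @param path Config file.
#' @return A named list with `geometry` assembled, numeric values parsed,
#'   and referenced tables loaded (defaults where not given).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$",
                                      lines[i]))[[1]]
    if (length(m) == 0L)
      stop("cannot parse config line: '", lines[i], "'", call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) {
      if (is.null(default))
        stop("config '", path, "' lacks required key '", key, "'",
             call. = FALSE)
      return(default)
    }
    as.numeric(kv[[key]])
  }
  cfg <- list(
    geometry = vessel_geometry(num("v_gas_l"), num("v_liq_l"), num("temp_K")),
    n_carbons = as.integer(num("n_carbons")),
    threshold = num("threshold_mmolN_l", 0.05),
    pH = num("ph", 7),
    seed = as.integer(num("seed", 1)))
  cfg$solubilities <- if (!is.null(kv$solubility_csv)) {
    p <- kv$solubility_csv
    if (!file.exists(p)) stop("solubility_csv not found: ", p, call. = FALSE)
    read_solubilities(p)
  } else default_solubilities()
  cfg$formation <- if (!is.null(kv$formation_csv)) {
    p <- kv$formation_csv
    if (!file.exists(p)) stop("formation_csv not found: ", p, call. = FALSE)
    read_formation_energies(p)
  } else formation_energy_table()
  cfg
}
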