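# 13C / 15N tracer bookkeeping.
#
# All quantities are carried in atom units (umol 13C atoms, umol 15N atoms)
# except the N2 isotopologues, which are molecule counts: 29N2 carries one
# 15N atom, 30N2 carries two. Molecule -> atom conversion happens once, at
# ingestion, so downstream arithmetic cannot pick up factor-of-two errors.

#' Isotope tracer inventories of a labelling experiment
#'
#' @param c13_co2_produced umol 13C atoms recovered as 13CO2.
#' @param c13_alkane_consumed umol 13C atoms consumed as labelled alkane.
#' @param n2_29,n2_30 umol of the single- and double-labelled N2
#'   isotopologue molecules produced.
#' @param nh4_15 umol 15N produced as 15NH4+.
#' @param no3_15_consumed umol 15N consumed as 15NO3-.
#' @param no2_15 umol 15N present as 15NO2- at the end of the test.
#' @return A `nitralk_isotopes` list.
#' @export
isotope_series <- function(c13_co2_produced = 0, c13_alkane_consumed = 0,
                           n2_29 = 0, n2_30 = 0, nh4_15 = 0,
                           no3_15_consumed = 0, no2_15 = 0) {
  vals <- c(c13_co2_produced, c13_alkane_consumed, n2_29, n2_30, nh4_15,
            no3_15_consumed, no2_15)
  if (any(vals < 0)) stop("isotope inventories must be non-negative",
                          call. = FALSE)
  structure(list(c13_co2_produced = c13_co2_produced,
                 c13_alkane_consumed = c13_alkane_consumed,
                 n2_29 = n2_29, n2_30 = n2_30, nh4_15 = nh4_15,
                 no3_15_consumed = no3_15_consumed, no2_15 = no2_15),
            class = "nitralk_isotopes")
}

#' 13C recovery: labelled CO2 over labelled alkane carbon consumed
#'
#' @param s A [isotope_series()].
#' @return Fraction of consumed 13C recovered as 13CO2.
#' @examples
#' c13_recovery(isotope_series(c13_co2_produced = 40,
#'                             c13_alkane_consumed = 60))  # 0.667
#' @export
c13_recovery <- function(s) {
  if (s$c13_alkane_consumed <= 0)
    stop("no labelled alkane consumption; 13C recovery undefined",
         call. = FALSE)
  s$c13_co2_produced / s$c13_alkane_consumed
}

#' 15N recovery into N2 isotopologues and ammonium
#'
#' 15N produced counts one atom per 29N2 molecule, two per 30N2 molecule,
#' one per 15NH4+.
#'
#' @param s A [isotope_series()].
#' @return List with `n15_produced` (umol 15N) and `fraction` of the
#'   consumed 15NO3-.
#' @export
n15_recovery <- function(s) {
  if (s$no3_15_consumed <= 0)
    stop("no labelled nitrate consumption; 15N recovery undefined",
         call. = FALSE)
  produced <- s$n2_29 + 2 * s$n2_30 + s$nh4_15
  list(n15_produced = produced, fraction = produced / s$no3_15_consumed)
}

#' Random-pairing N2 isotopologue fractions
#'
#' Null expectation for 28/29/30-N2 when N atoms pair at random from a pool
#' with 15N atom fraction `p15`: the binomial fractions
#' ((1-p)^2, 2p(1-p), p^2).
#'
#' @param p15 15N atom fraction of the nitrogen pool, 0 to 1.
#' @return Named numeric vector `c(n2_28, n2_29, n2_30)` summing to 1.
#' @examples
#' pairing_fractions(0.01)  # 29N2 fraction 0.0198
#' @export
pairing_fractions <- function(p15) {
  if (!is.numeric(p15) || p15 < 0 || p15 > 1)
    stop("p15 must lie in [0, 1]", call. = FALSE)
  c(n2_28 = (1 - p15)^2, n2_29 = 2 * p15 * (1 - p15), n2_30 = p15^2)
}

ISO_COLUMNS <- c("time_h", "c13co2_umol", "c13alkane_umol", "n2_29_umol",
                 "n2_30_umol", "nh4_15_umol", "no3_15_umol", "no2_15_umol")

#' Read an isotope time series CSV and reduce it to tracer inventories
#'
#' Expects columns
#' `time_h,c13co2_umol,c13alkane_umol,n2_29_umol,n2_30_umol,nh4_15_umol,no3_15_umol,no2_15_umol`
#' where `c13alkane_umol` is umol of labelled alkane molecules and the rest
#' are as named. Consumption is first-minus-last, production last-minus-
#' first; the alkane molecule count is converted to carbon atoms here.
#'
#' @param path CSV file.
#' @param carbons_per_molecule Carbons per labelled alkane molecule.
#' @return A [isotope_series()].
#' @export
read_isotope_series <- function(path, carbons_per_molecule) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(ISO_COLUMNS, names(df))
  if (length(miss))
    stop("isotope CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lastv <- function(x) x[length(x)]
  isotope_series(
    c13_co2_produced = lastv(df$c13co2_umol) - df$c13co2_umol[1],
    c13_alkane_consumed =
      (df$c13alkane_umol[1] - lastv(df$c13alkane_umol)) * carbons_per_molecule,
    n2_29 = lastv(df$n2_29_umol) - df$n2_29_umol[1],
    n2_30 = lastv(df$n2_30_umol) - df$n2_30_umol[1],
    nh4_15 = lastv(df$nh4_15_umol) - df$nh4_15_umol[1],
    no3_15_consumed = df$no3_15_umol[1] - lastv(df$no3_15_umol),
    no2_15 = lastv(df$no2_15_umol))
}
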