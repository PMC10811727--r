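# Independent oracles used by the tests. These deliberately avoid the
# package's balancing and ledger code paths: compositions and electron
# prices are written out by hand, and balanced equations are found by
# bounded enumeration rather than by construction.

# element counts (C, H, O, N) and charge, by hand
.oracle_comp <- function(name) {
  switch(name,
         "CH4"   = list(e = c(1, 4, 0, 0),  z = 0),
         "C2H6"  = list(e = c(2, 6, 0, 0),  z = 0),
         "C3H8"  = list(e = c(3, 8, 0, 0),  z = 0),
         "C4H10" = list(e = c(4, 10, 0, 0), z = 0),
         "CO2"   = list(e = c(1, 0, 2, 0),  z = 0),
         "H2O"   = list(e = c(0, 2, 1, 0),  z = 0),
         "H+"    = list(e = c(0, 1, 0, 0),  z = +1),
         "NO3-"  = list(e = c(0, 0, 3, 1),  z = -1),
         "NO2-"  = list(e = c(0, 0, 2, 1),  z = -1),
         "NH4+"  = list(e = c(0, 4, 0, 1),  z = +1),
         "N2"    = list(e = c(0, 0, 0, 2),  z = 0),
         stop("oracle knows no species ", name))
}

# Brute-force search for the minimal-integer balanced equation
#   a ALK + b FROM + h H+ -> d CO2 + e TO + w H2O
# (h and w signed; a negative h means H+ on the product side). Enumerates
# alkane and N-oxyanion coefficients up to `bound`, solves the remaining
# coefficients from the element balances, and keeps the first fully
# balanced solution with gcd 1, scanning in order of increasing a + b so
# minimality is by construction.
oracle_min_reaction <- function(alkane, from, to, bound = 30) {
  ca <- .oracle_comp(alkane); cf <- .oracle_comp(from); ct <- .oracle_comp(to)
  gcd2 <- function(a, b) if (b == 0) abs(a) else gcd2(b, a %% b)
  best <- NULL
  for (s in 2:(2 * bound)) for (a in seq_len(min(s - 1, bound))) {
    b <- s - a
    if (b > bound) next
    d <- ca$e[1] * a                      # C balance
    e_to <- b * cf$e[4] / ct$e[4]         # N balance
    if (e_to != round(e_to)) next
    # O balance fixes water, then H balance fixes protons
    w <- b * cf$e[3] - d * 2 - e_to * ct$e[3]
    h <- d * 0 + e_to * ct$e[2] + w * 2 - a * ca$e[2] - b * cf$e[2]
    charge <- h * 1 + a * ca$z + b * cf$z - e_to * ct$z
    if (charge != 0) next
    coefs <- c(a, b, h, d, e_to, w)
    if (Reduce(gcd2, abs(coefs[coefs != 0])) != 1) next
    best <- c(alkane = a, from = b, h_plus = h, co2 = d, to = e_to, h2o = w)
    break
  }
  best
}

# Per-timestep electron ledger: walks the series incrementally and prices
# each transformation on the alternative route (2 e- per NO3- consumed, to
# whatever it became, plus 3 e- per N2-N and 6 e- per NH4+-N formed from
# nitrite). Valid for series in which all N flows NO3- -> NO2- -> {N2,NH4+}
# or NO3- -> {N2,NH4+} directly, i.e. any noise-free run of this chemistry.
oracle_electron_ledger <- function(ts) {
  v_liq <- attr(ts, "geometry")$v_liq
  no3 <- ts$no3_mmolN_l * v_liq
  n2 <- ts$n2_mmolN_total
  nh4 <- ts$nh4_mmolN_l * v_liq
  e <- 0
  for (i in seq_len(nrow(ts) - 1L)) {
    e <- e + 2 * (no3[i] - no3[i + 1L]) +       # NO3- -> NO2- leg
      3 * (n2[i + 1L] - n2[i]) +                # NO2- -> N2
      6 * (nh4[i + 1L] - nh4[i])                # NO2- -> NH4+
  }
  e
}

# small constructed series builder (vessel: 1 l liquid, 1 l headspace)
make_ts <- function(time_h, no3, no2 = 0 * time_h, nh4 = 0 * time_h,
                    n2 = 0 * time_h, alkane, co2 = 0 * time_h,
                    v_liq = 1, n_carbons = 2) {
  reactor_timeseries(time_h, no3, no2, nh4, n2, alkane, co2,
                     geometry = vessel_geometry(1, v_liq, 308.15),
                     n_carbons = n_carbons)
}
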