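# Gibbs free energies of coupled reactions from standard formation energies.

#' Gas constant, J mol-1 K-1
#' @export
R_GAS <- 8.314462618

#' Standard temperature, K
#' @export
T_STANDARD <- 298.15

#' Curated standard Gibbs formation-energy table
#'
#' Standard Gibbs free energies of formation at 298.15 K (1 atm gases, 1 M
#' aqueous solutes, pure liquid water), in kJ/mol, for every species used by
#' the alkane / N-oxyanion couples. Aqueous ions follow the classic
#' biochemical compilation of Thauer, Jungermann & Decker (1977); gases and
#' liquid water follow CODATA/CRC values. Reference-state elements (N2, H2,
#' O2, H+) are zero by definition. Override any entry by editing the
#' returned data frame or by loading a user table with
#' [read_formation_energies()].
#'
#' @return A data frame with columns `species`, `phase`, `dgf_kj_per_mol`,
#'   `source`.
#' @export
formation_energy_table <- function() {
  tab <- rbind(
    data.frame(species = "C2H6",  phase = "gas",     dgf_kj_per_mol = -32.0,
               source = "CRC Handbook, ethane(g)"),
    data.frame(species = "C3H8",  phase = "gas",     dgf_kj_per_mol = -23.4,
               source = "CRC Handbook, propane(g)"),
    data.frame(species = "C4H10", phase = "gas",     dgf_kj_per_mol = -17.0,
               source = "CRC Handbook, n-butane(g)"),
    data.frame(species = "CH4",   phase = "gas",     dgf_kj_per_mol = -50.8,
               source = "CRC Handbook, methane(g)"),
    data.frame(species = "CO2",   phase = "gas",     dgf_kj_per_mol = -394.36,
               source = "CODATA, CO2(g)"),
    data.frame(species = "CO2",   phase = "aqueous", dgf_kj_per_mol = -386.0,
               source = "Thauer et al. 1977, CO2(aq)"),
    data.frame(species = "H2O",   phase = "liquid",  dgf_kj_per_mol = -237.13,
               source = "CODATA, H2O(l)"),
    data.frame(species = "NO3-",  phase = "aqueous", dgf_kj_per_mol = -111.34,
               source = "Thauer et al. 1977, NO3-(aq)"),
    data.frame(species = "NO2-",  phase = "aqueous", dgf_kj_per_mol = -37.2,
               source = "Thauer et al. 1977, NO2-(aq)"),
    data.frame(species = "NH4+",  phase = "aqueous", dgf_kj_per_mol = -79.37,
               source = "Thauer et al. 1977, NH4+(aq)"),
    data.frame(species = "N2",    phase = "gas",     dgf_kj_per_mol = 0,
               source = "reference-state element"),
    data.frame(species = "H2",    phase = "gas",     dgf_kj_per_mol = 0,
               source = "reference-state element"),
    data.frame(species = "O2",    phase = "gas",     dgf_kj_per_mol = 0,
               source = "reference-state element"),
    data.frame(species = "H+",    phase = "aqueous", dgf_kj_per_mol = 0,
               source = "convention, H+(aq)"))
  tab
}

#' Read / write a formation-energy table as CSV
#'
#' Columns: `species,phase,dgf_kj_per_mol,source`.
#'
#' @param path File path.
#' @return `read_formation_energies()` returns the table data frame.
#' @export
read_formation_energies <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "phase", "dgf_kj_per_mol")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("formation-energy CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"source" %in% names(tab)) tab$source <- NA_character_
  tab
}

#' @rdname read_formation_energies
#' @param table A formation-energy data frame.
#' @export
write_formation_energies <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

.dgf_lookup <- function(table, name, phase) {
  hit <- table$species == name & table$phase == phase
  if (!any(hit))
    stop("no formation energy for species '", name, "' (", phase, ")",
         call. = FALSE)
  table$dgf_kj_per_mol[which(hit)[1]]
}

#' Standard Gibbs free energy of a reaction
#'
#' Sum of signed stoichiometric coefficients times standard formation
#' energies: products minus reactants, at 298.15 K standard states, with no
#' pH correction.
#'
#' @param reaction A `nitralk_full_reaction`.
#' @param table Formation-energy table; defaults to the shipped one.
#' @return kJ per reaction as written.
#' @export
delta_g0 <- function(reaction, table = formation_energy_table()) {
  coef <- reaction$stoich
  if (length(coef) == 0L) return(0)
  sum(vapply(names(coef), function(nm) {
    sp <- reaction$species[[nm]]
    coef[[nm]] * .dgf_lookup(table, sp$name, sp$phase)
  }, numeric(1)))
}

#' pH-corrected Gibbs free energy (dG0')
#'
#' Corrects the standard reaction energy to a stated pH by assigning H+ an
#' activity of 10^-pH while all other species remain at standard states:
#' dG0' = dG0 + nu(H+) * R * T * ln(10^-pH), where nu(H+) is the net signed
#' H+ coefficient (produced positive). Reactions with no net H+ are
#' unaffected, as is any reaction at pH 0.
#'
#' @param reaction A `nitralk_full_reaction`.
#' @param table Formation-energy table.
#' @param pH Proton activity exponent, 0 to 14; default 7 (the biochemical
#'   standard state).
#' @param T Temperature in kelvin used in the correction term; default
#'   298.15 K.
#' @return An object of class `nitralk_thermo` with fields `delta_g0`,
#'   `delta_g0_prime` (kJ per reaction as written), `per_mol_donor`
#'   (kJ per mol of the donor species), `pH` and `T`.
#' @examples
#' rx <- couple(alkane_oxidation_half(2), nitrogen_reduction_half("NO2->N2"))
#' delta_g0_prime(rx)$per_mol_donor  # approx -1661 kJ/mol ethane
#' @export
delta_g0_prime <- function(reaction, table = formation_energy_table(),
                           pH = 7, T = T_STANDARD) {
  if (!is.numeric(pH) || pH < 0 || pH > 14)
    stop("pH must lie in [0, 14]", call. = FALSE)
  g0 <- delta_g0(reaction, table)
  nu_h <- if ("H+" %in% names(reaction$stoich)) reaction$stoich[["H+"]] else 0
  g0p <- g0 + nu_h * (R_GAS / 1000) * T * log(10^(-pH))
  donor_coef <- abs(reaction$stoich[[reaction$donor]])
  structure(list(delta_g0 = g0, delta_g0_prime = g0p,
                 per_mol_donor = g0p / donor_coef,
                 donor = reaction$donor, pH = pH, T = T),
            class = "nitralk_thermo")
}

#' @export
print.nitralk_thermo <- function(x, ...) {
  cat(sprintf(
    "<thermo> dG0 = %.1f kJ; dG0' (pH %.3g, %.2f K) = %.1f kJ; %.1f kJ/mol %s\n",
    x$delta_g0, x$pH, x$T, x$delta_g0_prime, x$per_mol_donor, x$donor))
  invisible(x)
}

#' Feasibility table for an alkane across all N-oxyanion couples
#'
#' Convenience wrapper evaluating the coupled reaction and its dG0' for each
#' reduction couple.
#'
#' @param n_carbons Alkane chain length.
#' @param couples Character vector of couples (default: all five).
#' @inheritParams delta_g0_prime
#' @return Data frame with the equation text, dG0, dG0' and kJ per mol
#'   alkane for each couple.
#' @export
thermo_summary <- function(n_carbons,
                           couples = c("NO3->NO2", "NO3->N2", "NO2->N2",
                                       "NO3->NH4", "NO2->NH4"),
                           table = formation_energy_table(),
                           pH = 7, T = T_STANDARD) {
  don <- alkane_oxidation_half(n_carbons)
  rows <- lapply(couples, function(cp) {
    rx <- couple(don, nitrogen_reduction_half(cp))
    th <- delta_g0_prime(rx, table, pH = pH, T = T)
    data.frame(couple = cp, equation = format_reaction(rx),
               delta_g0_kj = th$delta_g0,
               delta_g0_prime_kj = th$delta_g0_prime,
               kj_per_mol_alkane = th$per_mol_donor)
  })
  do.call(rbind, rows)
}
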