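# Half-reaction construction and coupling.
#
# Convention: stoichiometric coefficients are signed (negative = consumed,
# positive = produced). Half-reactions are completed deterministically in
# the standard aqueous way: O balanced with H2O, then H with H+, then charge
# with electrons. Half-reaction coefficients are integer multiples of 1/2
# (the only fraction arises from N2 when normalising to one N atom), so all
# arithmetic below is exact in double precision; full reactions are reduced
# to minimal integers by gcd.

.gcd2 <- function(a, b) if (b == 0) abs(a) else .gcd2(b, a %% b)
.gcd <- function(x) Reduce(.gcd2, abs(x))
.lcm2 <- function(a, b) abs(a / .gcd2(a, b) * b)

# Complete a partial stoichiometry (named coef vector + parallel species
# list) with H2O, H+ and e-. Returns list(coef, species, electrons).
.complete_half <- function(coef, spl) {
  elem_sum <- function(el)
    sum(vapply(seq_along(coef),
               function(i) coef[[i]] * spl[[i]]$elements[[el]], numeric(1)))
  add <- function(coef, spl, sp, dc) {
    if (sp$name %in% names(coef)) {
      coef[[sp$name]] <- coef[[sp$name]] + dc
    } else {
      coef[[sp$name]] <- dc
      spl[[sp$name]] <- sp
    }
    list(coef = coef, spl = spl)
  }
  r <- elem_sum("O")
  if (r != 0) { u <- add(coef, spl, known_species("H2O"), -r); coef <- u$coef; spl <- u$spl }
  r <- elem_sum("H")
  if (r != 0) { u <- add(coef, spl, known_species("H+"), -r); coef <- u$coef; spl <- u$spl }
  chg <- sum(vapply(seq_along(coef),
                    function(i) coef[[i]] * spl[[i]]$charge, numeric(1)))
  # releasing one electron removes one negative charge from the species side
  list(coef = coef, species = spl, electrons = chg)
}

.new_half_reaction <- function(coef, species, electrons, principal) {
  keep <- coef != 0
  structure(list(stoich = coef[keep], species = species[keep],
                 electrons = electrons, principal = principal),
            class = "nitralk_half_reaction")
}

#' Alkane oxidation half-reaction
#'
#' Complete oxidation of the n-alkane to CO2, normalised to 1 mol alkane:
#' CnH2n+2 + 2n H2O -> n CO2 + (6n+2) H+ + (6n+2) e-.
#'
#' @param n_carbons Chain length, 1 to 6.
#' @param co2_phase Phase assigned to the CO2 product; the gas-phase default
#'   matches the convention of the coupled equations this package targets.
#' @return A `nitralk_half_reaction` with `electrons = 6n + 2` (released).
#' @examples
#' alkane_oxidation_half(2)  # ethane: 14 electrons
#' @export
alkane_oxidation_half <- function(n_carbons, co2_phase = c("gas", "aqueous")) {
  co2_phase <- match.arg(co2_phase)
  alk <- alkane_species(n_carbons)
  n <- as.integer(n_carbons)
  co2 <- known_species("CO2", phase = co2_phase)
  coef <- c(-1, n); names(coef) <- c(alk$name, co2$name)
  spl <- list(alk, co2); names(spl) <- names(coef)
  h <- .complete_half(coef, spl)
  stopifnot(h$electrons == 6L * n + 2L)
  .new_half_reaction(h$coef, h$species, h$electrons, alk$name)
}

#' Nitrogen-oxyanion reduction half-reaction
#'
#' Element- and charge-balanced reduction half-reaction for one of the five
#' couples linking nitrate, nitrite, dinitrogen and ammonium, normalised to
#' 1 mol N. Electron demands per N: NO3->NO2 2, NO3->N2 5, NO2->N2 3,
#' NO3->NH4 8, NO2->NH4 6.
#'
#' @param couple One of `"NO3->NO2"`, `"NO3->N2"`, `"NO2->N2"`,
#'   `"NO3->NH4"`, `"NO2->NH4"`.
#' @return A `nitralk_half_reaction` with negative `electrons` (consumed).
#' @examples
#' nitrogen_reduction_half("NO3->NO2")
#' @export
nitrogen_reduction_half <- function(couple) {
  couples <- list(
    "NO3->NO2" = c("NO3-", "NO2-"),
    "NO3->N2"  = c("NO3-", "N2"),
    "NO2->N2"  = c("NO2-", "N2"),
    "NO3->NH4" = c("NO3-", "NH4+"),
    "NO2->NH4" = c("NO2-", "NH4+"))
  if (!is.character(couple) || length(couple) != 1L ||
      !couple %in% names(couples))
    stop("unknown couple '", couple, "'; expected one of ",
         paste(names(couples), collapse = ", "), call. = FALSE)
  from <- known_species(couples[[couple]][1])
  to <- known_species(couples[[couple]][2])
  # normalise to 1 mol N: N2 gets coefficient 1/2
  coef <- c(-1, 1 / to$elements[["N"]])
  names(coef) <- c(from$name, to$name)
  spl <- list(from, to); names(spl) <- names(coef)
  h <- .complete_half(coef, spl)
  stopifnot(h$electrons < 0)
  .new_half_reaction(h$coef, h$species, h$electrons, from$name)
}

#' Electron demand per N of a reduction couple
#'
#' @param couple As in [nitrogen_reduction_half()].
#' @return Positive electrons consumed per N atom.
#' @export
couple_electrons_per_n <- function(couple) {
  -nitrogen_reduction_half(couple)$electrons
}

#' Couple a donor and an acceptor half-reaction into a full reaction
#'
#' Scales both halves by the least common multiple of their electron counts
#' so that electrons cancel, sums species (netting H2O and H+ that appear on
#' both sides to one side) and reduces all coefficients to minimal integers.
#'
#' @param donor Half-reaction releasing electrons (`electrons > 0`).
#' @param acceptor Half-reaction consuming electrons (`electrons < 0`).
#' @return A `nitralk_full_reaction` with fields `stoich` (signed minimal
#'   integers), `species`, `donor` and `electrons_per_donor`.
#' @examples
#' couple(alkane_oxidation_half(2), nitrogen_reduction_half("NO3->NO2"))
#' @export
couple <- function(donor, acceptor) {
  stopifnot(inherits(donor, "nitralk_half_reaction"),
            inherits(acceptor, "nitralk_half_reaction"))
  if (donor$electrons <= 0 || acceptor$electrons >= 0)
    stop("couple() needs an electron-releasing donor and an ",
         "electron-consuming acceptor", call. = FALSE)
  e_d <- donor$electrons
  e_a <- -acceptor$electrons
  l <- .lcm2(e_d, e_a)
  sd_ <- l / e_d
  sa_ <- l / e_a
  coef <- sd_ * donor$stoich
  spl <- donor$species
  for (nm in names(acceptor$stoich)) {
    dc <- sa_ * acceptor$stoich[[nm]]
    if (nm %in% names(coef)) {
      if (!identical(spl[[nm]]$phase, acceptor$species[[nm]]$phase))
        stop("species '", nm, "' appears in both halves with different phases",
             call. = FALSE)
      coef[[nm]] <- coef[[nm]] + dc
    } else {
      coef[[nm]] <- dc
      spl[[nm]] <- acceptor$species[[nm]]
    }
  }
  coef <- coef[abs(coef) > 1e-9]
  if (max(abs(coef - round(coef))) > 1e-9)
    stop("internal error: non-integer coefficients after electron cancellation")
  coef <- round(coef)
  g <- .gcd(coef)
  coef <- coef / g
  structure(
    list(stoich = coef, species = spl[names(coef)],
         donor = donor$principal,
         electrons_per_donor = as.integer(e_d / abs(donor$stoich[[donor$principal]]))),
    class = "nitralk_full_reaction")
}

#' Element and charge conservation residuals of a reaction
#'
#' All residuals are exactly zero for a balanced reaction; non-zero entries
#' localise the defect. Works on half-reactions too, in which case the
#' explicit electron count enters the charge residual.
#'
#' @param reaction A `nitralk_full_reaction` or `nitralk_half_reaction`.
#' @return Named numeric vector with one residual per supported element plus
#'   `"charge"` (products minus reactants).
#' @export
check_balance <- function(reaction) {
  coef <- reaction$stoich
  spl <- reaction$species
  res <- vapply(SUPPORTED_ELEMENTS, function(el)
    if (length(coef) == 0L) 0 else
      sum(vapply(seq_along(coef),
                 function(i) coef[[i]] * spl[[i]]$elements[[el]], numeric(1))),
    numeric(1))
  chg <- if (length(coef) == 0L) 0 else
    sum(vapply(seq_along(coef),
               function(i) coef[[i]] * spl[[i]]$charge, numeric(1)))
  if (inherits(reaction, "nitralk_half_reaction"))
    chg <- chg - reaction$electrons  # released electrons carry charge away
  c(res, charge = chg)
}

#' @export
print.nitralk_half_reaction <- function(x, ...) {
  cat("<half-reaction> ", format_reaction(x), "\n", sep = "")
  cat(sprintf("  electrons: %+g (%s)\n", x$electrons,
              if (x$electrons > 0) "released" else "consumed"))
  invisible(x)
}

#' @export
print.nitralk_full_reaction <- function(x, ...) {
  cat("<reaction> ", format_reaction(x), "\n", sep = "")
  cat(sprintf("  donor: %s, %d e- per mol donor\n",
              x$donor, x$electrons_per_donor))
  invisible(x)
}
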