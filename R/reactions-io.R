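# Plain-text rendering and parsing of reactions, e.g.
#   "3 C2H6 + 14 NO2- + 14 H+ -> 6 CO2 + 7 N2 + 16 H2O"

.format_side <- function(coef, include_e = 0) {
  parts <- character(0)
  for (nm in names(coef)) {
    k <- coef[[nm]]
    parts <- c(parts, if (k == 1) nm else paste(format(k), nm))
  }
  if (include_e != 0)
    parts <- c(parts, if (include_e == 1) "e-" else paste(include_e, "e-"))
  paste(parts, collapse = " + ")
}

#' Render a reaction as a plain-text equation
#'
#' @param reaction A full or half reaction.
#' @return A single string, reactants then `"->"` then products; electrons
#'   of a half-reaction are written explicitly as `e-`.
#' @examples
#' format_reaction(couple(alkane_oxidation_half(2),
#'                        nitrogen_reduction_half("NO2->N2")))
#' @export
format_reaction <- function(reaction) {
  coef <- reaction$stoich
  lhs <- -coef[coef < 0]
  rhs <- coef[coef > 0]
  e <- if (inherits(reaction, "nitralk_half_reaction")) reaction$electrons else 0
  paste(.format_side(lhs, include_e = if (e < 0) -e else 0),
        "->",
        .format_side(rhs, include_e = if (e > 0) e else 0))
}

.parse_species_token <- function(tok) {
  m <- regmatches(tok, regexec("^([A-Za-z0-9]+?)(\\d*)([+-]?)$", tok))[[1]]
  if (length(m) == 0L) stop("cannot parse species token '", tok, "'", call. = FALSE)
  # trailing digits belong to the formula unless followed by a sign
  formula <- if (nzchar(m[4])) m[2] else paste0(m[2], m[3])
  chg_mag <- if (nzchar(m[4]) && nzchar(m[3])) as.integer(m[3]) else
    if (nzchar(m[4])) 1L else 0L
  charge <- if (m[4] == "-") -chg_mag else chg_mag
  if (!nzchar(m[4])) formula <- tok
  db <- .species_db()
  if (tok %in% names(db)) return(db[[tok]])
  pieces <- regmatches(formula,
                       gregexpr("([A-Z][a-z]?)(\\d*)", formula))[[1]]
  if (paste(pieces, collapse = "") != formula)
    stop("cannot parse formula '", formula, "' in token '", tok, "'",
         call. = FALSE)
  counts <- integer(0)
  for (p in pieces) {
    el <- gsub("[0-9]", "", p)
    k <- gsub("[^0-9]", "", p)
    k <- if (nzchar(k)) as.integer(k) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + k
  }
  species(tok, counts, charge = charge, phase = "aqueous")
}

#' Parse a plain-text equation into a full reaction
#'
#' Inverse of [format_reaction()] for full (electron-free) reactions.
#' Species named in the built-in registry get their registered phase and
#' composition; unknown tokens are parsed as C/H/O/N formulas with an
#' optional trailing charge sign and default to the aqueous phase.
#'
#' @param text Equation string, sides separated by `"->"` or `"="`.
#' @param donor Optional donor species name; defaults to the first reactant.
#' @return A `nitralk_full_reaction` (electrons_per_donor `NA` unless it can
#'   be inferred from a C/H/O-only donor).
#' @export
parse_reaction <- function(text, donor = NULL) {
  sides <- strsplit(text, "->|=", fixed = FALSE)[[1]]
  if (length(sides) != 2L)
    stop("equation must have exactly one '->'", call. = FALSE)
  parse_side <- function(s, sign) {
    terms <- strsplit(s, " + ", fixed = TRUE)[[1]]
    terms <- trimws(terms[nzchar(trimws(terms))])
    coef <- numeric(0); spl <- list()
    for (tm in terms) {
      m <- regmatches(tm, regexec("^(\\d+)\\s+(.*)$", tm))[[1]]
      k <- if (length(m)) as.numeric(m[2]) else 1
      tok <- if (length(m)) m[3] else tm
      sp <- .parse_species_token(tok)
      if (sp$name %in% names(coef)) coef[[sp$name]] <- coef[[sp$name]] + sign * k
      else { coef[[sp$name]] <- sign * k; spl[[sp$name]] <- sp }
    }
    list(coef = coef, spl = spl)
  }
  l <- parse_side(sides[1], -1)
  r <- parse_side(sides[2], +1)
  coef <- l$coef
  spl <- l$spl
  for (nm in names(r$coef)) {
    if (nm %in% names(coef)) coef[[nm]] <- coef[[nm]] + r$coef[[nm]]
    else { coef[[nm]] <- r$coef[[nm]]; spl[[nm]] <- r$spl[[nm]] }
  }
  coef <- coef[coef != 0]
  if (is.null(donor)) donor <- names(l$coef)[1]
  sp_d <- spl[[donor]]
  epd <- NA_integer_
  if (!is.null(sp_d) && sp_d$elements[["N"]] == 0L && sp_d$charge == 0L &&
      sp_d$elements[["C"]] > 0L)
    epd <- alkane_electrons(sp_d$elements[["C"]])
  structure(list(stoich = coef, species = spl[names(coef)], donor = donor,
                 electrons_per_donor = epd),
            class = "nitralk_full_reaction")
}
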