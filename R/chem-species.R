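#' @keywords internal
"_PACKAGE"

# Elements supported by the balancer. The N-oxyanion / alkane chemistry this
# package targets never leaves C/H/O/N.
SUPPORTED_ELEMENTS <- c("C", "H", "O", "N")

#' Define a chemical species
#'
#' A species is identified by its name together with its phase; the same
#' formula in two phases (e.g. CO2 gas vs. dissolved CO2) is two distinct
#' species with distinct formation energies.
#'
#' @param name Species label, conventionally the formula with a trailing
#'   charge sign (e.g. `"NO3-"`, `"NH4+"`, `"C2H6"`).
#' @param elements Named integer vector of element counts; names must be a
#'   subset of C, H, O, N.
#' @param charge Integer net charge in elementary-charge units.
#' @param phase One of `"gas"`, `"aqueous"`, `"liquid"`.
#' @return An object of class `nitralk_species`.
#' @examples
#' species("NO3-", c(N = 1, O = 3), charge = -1, phase = "aqueous")
#' @export
species <- function(name, elements, charge = 0L,
                    phase = c("aqueous", "gas", "liquid")) {
  phase <- match.arg(phase)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  elements <- elements[elements != 0]
  if (length(elements) == 0L)
    stop("species '", name, "' must contain at least one atom", call. = FALSE)
  if (!all(names(elements) %in% SUPPORTED_ELEMENTS))
    stop("unsupported element(s) in '", name, "': ",
         paste(setdiff(names(elements), SUPPORTED_ELEMENTS), collapse = ", "),
         " (supported: ", paste(SUPPORTED_ELEMENTS, collapse = ", "), ")",
         call. = FALSE)
  if (any(elements < 0) || any(elements != round(elements)))
    stop("element counts must be non-negative integers", call. = FALSE)
  structure(
    list(name = name,
         elements = vapply(SUPPORTED_ELEMENTS, function(e)
           if (e %in% names(elements)) as.integer(elements[[e]]) else 0L,
           integer(1)),
         charge = as.integer(charge),
         phase = phase),
    class = "nitralk_species")
}

#' @export
print.nitralk_species <- function(x, ...) {
  chg <- if (x$charge == 0L) "" else sprintf(" charge %+d", x$charge)
  cat(sprintf("<species> %s (%s)%s\n", x$name, x$phase, chg))
  invisible(x)
}

# Built-in registry of the species used by the alkane / N-oxyanion couples.
.species_db <- function() {
  list(
    "H2O"  = species("H2O",  c(H = 2, O = 1),        0L, "liquid"),
    "H+"   = species("H+",   c(H = 1),              +1L, "aqueous"),
    "NO3-" = species("NO3-", c(N = 1, O = 3),       -1L, "aqueous"),
    "NO2-" = species("NO2-", c(N = 1, O = 2),       -1L, "aqueous"),
    "NH4+" = species("NH4+", c(N = 1, H = 4),       +1L, "aqueous"),
    "N2"   = species("N2",   c(N = 2),               0L, "gas"),
    "CO2"  = species("CO2",  c(C = 1, O = 2),        0L, "gas"),
    "H2"   = species("H2",   c(H = 2),               0L, "gas"),
    "O2"   = species("O2",   c(O = 2),               0L, "gas"),
    "CH4"    = species("CH4",    c(C = 1, H = 4),    0L, "gas"),
    "C2H6"   = species("C2H6",   c(C = 2, H = 6),    0L, "gas"),
    "C3H8"   = species("C3H8",   c(C = 3, H = 8),    0L, "gas"),
    "C4H10"  = species("C4H10",  c(C = 4, H = 10),   0L, "gas"),
    "C5H12"  = species("C5H12",  c(C = 5, H = 12),   0L, "gas"),
    "C6H14"  = species("C6H14",  c(C = 6, H = 14),   0L, "gas")
  )
}

#' Look up a built-in species by name
#'
#' @param name Name as in the registry, e.g. `"NO3-"`, `"C2H6"`.
#' @param phase Optional phase override (used e.g. for dissolved CO2).
#' @return A `nitralk_species`.
#' @export
known_species <- function(name, phase = NULL) {
  db <- .species_db()
  if (!name %in% names(db))
    stop("unknown species '", name, "'; known: ",
         paste(names(db), collapse = ", "), call. = FALSE)
  sp <- db[[name]]
  if (!is.null(phase)) sp$phase <- match.arg(phase, c("gas", "aqueous", "liquid"))
  sp
}

#' The n-alkane CnH2n+2 as a species
#'
#' @param n_carbons Chain length, 1 to 6.
#' @return A gas-phase `nitralk_species`.
#' @export
alkane_species <- function(n_carbons) {
  if (!is.numeric(n_carbons) || length(n_carbons) != 1L ||
      n_carbons != round(n_carbons) || n_carbons < 1 || n_carbons > 6)
    stop("n_carbons must be an integer in 1..6", call. = FALSE)
  n <- as.integer(n_carbons)
  species(sprintf("C%dH%d", n, 2L * n + 2L),
          c(C = n, H = 2L * n + 2L), 0L, "gas")
}

#' Electron yield of complete alkane oxidation to CO2
#'
#' CnH2n+2 donates 6n + 2 electrons when fully oxidised to CO2.
#'
#' @param n_carbons Chain length.
#' @return Integer electron count per molecule.
#' @export
alkane_electrons <- function(n_carbons) {
  stopifnot(n_carbons >= 1, n_carbons == round(n_carbons))
  as.integer(6 * n_carbons + 2)
}
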