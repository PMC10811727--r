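# Headspace / dissolved gas partitioning: ideal gas law + Henry's law.

#' Ideal gas constant in l atm mol-1 K-1
#' @export
R_ATM <- 0.082057

#' Sealed-vessel geometry
#'
#' @param v_gas_l Headspace volume, litres.
#' @param v_liq_l Liquid volume, litres.
#' @param temp_K Incubation temperature, kelvin.
#' @return A `nitralk_geometry` object.
#' @examples
#' vessel_geometry(v_gas_l = 0.3, v_liq_l = 0.82, temp_K = 308.15)
#' @export
vessel_geometry <- function(v_gas_l, v_liq_l, temp_K) {
  if (!all(c(v_gas_l, v_liq_l, temp_K) > 0))
    stop("vessel volumes and temperature must be strictly positive",
         call. = FALSE)
  structure(list(v_gas = v_gas_l, v_liq = v_liq_l, T = temp_K),
            class = "nitralk_geometry")
}

#' Henry's-law solubility of a gas
#'
#' Concentration-form Henry constant `c = h_cp * p` with a van 't Hoff
#' temperature dependence `h_cp(T) = h_cp_ref * exp(K * (1/T - 1/298.15))`.
#'
#' @param species Gas name.
#' @param h_cp_ref mol l-1 atm-1 at 298.15 K.
#' @param vant_hoff_K Temperature coefficient, kelvin (0 disables the
#'   correction).
#' @return A `nitralk_solubility` object.
#' @export
gas_solubility <- function(species, h_cp_ref, vant_hoff_K = 0) {
  if (h_cp_ref <= 0) stop("h_cp_ref must be > 0", call. = FALSE)
  structure(list(species = species, h_cp_ref = h_cp_ref,
                 vant_hoff_K = vant_hoff_K),
            class = "nitralk_solubility")
}

#' Default Henry constants for the reactor gases
#'
#' h_cp at 298.15 K and van 't Hoff coefficients from the Sander (2015)
#' compilation, converted to mol l-1 atm-1. User-overridable via
#' [read_solubilities()].
#'
#' @return Data frame with columns `species`, `h_cp_mol_per_l_atm`,
#'   `vant_hoff_K`, `source`.
#' @export
default_solubilities <- function() {
  data.frame(
    species = c("C2H6", "C3H8", "C4H10", "CO2", "N2"),
    h_cp_mol_per_l_atm = c(1.9e-3, 1.5e-3, 1.2e-3, 3.4e-2, 6.5e-4),
    vant_hoff_K = c(2400, 2700, 3100, 2400, 1300),
    source = rep("Sander 2015 compilation", 5))
}

#' Read / write a solubility table as CSV
#'
#' Columns: `species,h_cp_mol_per_l_atm,vant_hoff_K,source`.
#'
#' @param path File path.
#' @export
read_solubilities <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "h_cp_mol_per_l_atm", "vant_hoff_K")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("solubility CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab
}

#' @rdname read_solubilities
#' @param table Solubility data frame.
#' @export
write_solubilities <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Look up a gas solubility from a table
#'
#' @param species Gas name.
#' @param table Solubility table data frame.
#' @return A `nitralk_solubility`.
#' @export
solubility_for <- function(species, table = default_solubilities()) {
  hit <- which(table$species == species)
  if (!length(hit))
    stop("no Henry constant for '", species, "'", call. = FALSE)
  gas_solubility(species, table$h_cp_mol_per_l_atm[hit[1]],
                 table$vant_hoff_K[hit[1]])
}

#' Henry constant at temperature
#'
#' @param sol A `nitralk_solubility`.
#' @param T Temperature, kelvin.
#' @return mol l-1 atm-1 at `T`.
#' @export
henry_at_T <- function(sol, T) {
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  sol$h_cp_ref * exp(sol$vant_hoff_K * (1 / T - 1 / T_STANDARD))
}

.new_inventory <- function(p, geom, sol) {
  h <- henry_at_T(sol, geom$T)
  n_head <- p * geom$v_gas / (R_ATM * geom$T) * 1000  # mol -> mmol
  c_diss <- h * p * 1000                              # mol/l -> mmol/l
  structure(list(species = sol$species, p = p, n_headspace = n_head,
                 c_dissolved = c_diss,
                 n_total = n_head + c_diss * geom$v_liq),
            class = "nitralk_inventory")
}

#' Vessel-total gas inventory from a headspace partial pressure
#'
#' Headspace moles by the ideal gas law, dissolved pool by Henry's law at
#' the vessel temperature; the total is their sum.
#'
#' @param p Partial pressure, atm.
#' @param geom A [vessel_geometry()].
#' @param sol A [gas_solubility()].
#' @return A `nitralk_inventory` with fields `p` (atm), `n_headspace`
#'   (mmol), `c_dissolved` (mmol/l) and `n_total` (mmol).
#' @examples
#' g <- vessel_geometry(0.3, 0.82, 308.15)
#' inventory_from_pressure(1, g, gas_solubility("C2H6", 1.9e-3, 2400))
#' @export
inventory_from_pressure <- function(p, geom, sol) {
  if (p < 0) stop("pressure must be non-negative", call. = FALSE)
  .new_inventory(p, geom, sol)
}

#' Equilibrium partial pressure from a vessel-total inventory
#'
#' Inverts [inventory_from_pressure()]: the unique pressure solving the
#' linear gas-liquid equilibrium
#' `n_total = p * (v_gas / (R T) + h_cp(T) * v_liq)`.
#'
#' @param n_total Vessel-total amount, mmol.
#' @inheritParams inventory_from_pressure
#' @return A `nitralk_inventory`.
#' @export
pressure_from_total <- function(n_total, geom, sol) {
  if (n_total < 0) stop("n_total must be non-negative", call. = FALSE)
  h <- henry_at_T(sol, geom$T)
  cap <- geom$v_gas / (R_ATM * geom$T) * 1000 + h * 1000 * geom$v_liq
  .new_inventory(n_total / cap, geom, sol)
}

#' @export
print.nitralk_inventory <- function(x, ...) {
  cat(sprintf(
    "<gas inventory> %s: p = %.4g atm, headspace %.4g mmol, dissolved %.4g mmol/l, total %.4g mmol\n",
    x$species, x$p, x$n_headspace, x$c_dissolved, x$n_total))
  invisible(x)
}
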