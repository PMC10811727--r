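Package: nitralk
Title: Stoichiometry, Thermodynamics and Mass Balances for
    Nitrate-Driven Anaerobic Alkane Oxidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of anoxic batch
    incubations in which short-chain gaseous alkanes (ethane, propane,
    butane) are oxidised to CO2 with nitrate or nitrite as the terminal
    electron acceptor. Builds and balances redox half-reactions and
    couples them into minimal-integer full reactions; evaluates standard
    and pH-corrected Gibbs free energies (dG0') from a curated,
    user-overridable formation-energy table; converts between headspace
    partial pressures and vessel-total gas inventories with the ideal gas
    law and Henry's law; segments two-phase nitrate-reduction time series
    and computes nitrogen balances, denitrification/DNRA electron
    balances and DNRA rates; performs 13C/15N tracer recovery
    bookkeeping; and simulates batch reactors with seeded measurement
    noise so every pipeline stage can be tested against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
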