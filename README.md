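# nitralk

Stoichiometry, thermodynamics and mass balances for nitrate-driven
anaerobic oxidation of short-chain gaseous alkanes (ethane, propane,
butane).

## What it is for

Anaerobic bacteria can oxidise gaseous alkanes to CO₂ using nitrate or
nitrite as the terminal electron acceptor. Establishing that this is what
a sealed batch incubation is actually doing requires a chain of
quantitative arguments: the redox stoichiometry must balance, the coupled
reactions must be exergonic, gas inventories must account for both the
monitored headspace and the dissolved pool, the nitrogen products must
match the oxyanion drawdown, the electrons accepted by nitrogen must match
the electrons the consumed alkane can donate, and isotope labels must end
up in the predicted products. `nitralk` implements that chain for
researchers analysing (or simulating) such incubations:

* **Redox stoichiometry** — balanced half-reactions for
  CₙH₂ₙ₊₂ → n CO₂ (6n+2 electrons) and the five N-oxyanion couples
  (NO₃⁻→NO₂⁻, NO₃⁻→N₂, NO₂⁻→N₂, NO₃⁻→NH₄⁺, NO₂⁻→NH₄⁺; 2/5/3/8/6
  electrons per N), coupled into minimal-integer full reactions.
* **Thermodynamics** — ΔG° and pH-corrected ΔG°′ =
  ΔG° + ν(H⁺)·RT·ln 10⁻ᵖᴴ per reaction and per mole of alkane, from a
  curated, user-overridable formation-energy table.
* **Gas partitioning** — headspace (ideal gas) + dissolved (Henry's law)
  vessel-total inventories, invertible to machine precision.
* **Balances** — two-phase segmentation of nitrate reduction, nitrogen
  recovery, the denitrification/DNRA electron split against the maximum
  alkane electron yield, and the DNRA rate from the Phase-2 ammonium
  slope.
* **Isotope tracing** — ¹³CO₂ and ¹⁵N (²⁹N₂/³⁰N₂/¹⁵NH₄⁺) recoveries on a
  declared atom basis, plus the random-pairing isotopologue null.
* **Synthetic reactor** — a seeded generator of two-phase batch profiles
  with known ground truth, so every estimator is testable end to end.

## Worked example

Couple ethane oxidation to nitrite reduction and evaluate its energetics:

```r
library(nitralk)
rx <- couple(alkane_oxidation_half(2), nitrogen_reduction_half("NO2->N2"))
format_reaction(rx)
#> [1] "3 C2H6 + 14 H+ + 14 NO2- -> 6 CO2 + 16 H2O + 7 N2"
delta_g0_prime(rx)
#> <thermo> dG0 = -5543.4 kJ; dG0' (pH 7, 298.15 K) = -4984.1 kJ; -1661.4 kJ/mol C2H6
```

Every coefficient is exact and `check_balance(rx)` returns all-zero
element and charge residuals. The −1661 kJ per mole of ethane says the
reaction is strongly exergonic at biochemical standard conditions.

Simulate an ethane-fed incubation (2 mmol N/l nitrate, ~1 atm ethane,
35 °C, realistic measurement noise) and run the balance analysis:

```r
params <- scenario_library(seed = 42)[["ethane-like"]]
sim <- simulate_reactor(params)
seg <- segment_phases(sim$timeseries, threshold = 0.15)
electron_balance(sim$timeseries, seg)
#> <balance report>
#>   N: produced 1.956, consumed 2.020 mmol N/l (recovery 96.9%)
#>   e-: denitrification 5.597 + DNRA 3.878 + residual NO2- 0.058 = 9.532 of 8.834 mmol e- (107.9%)
#>   DNRA rate: 0.109 mmol N/l/day
```

Reading the report: 96.9% of the consumed N-oxyanions reappeared as
N₂ + NH₄⁺ (a closed nitrogen balance, within noise of the true 100%);
the electrons accepted by nitrogen amount to 107.9% of what the measured
ethane drawdown can donate (true value 100% — single-replicate scatter is
dominated by the alkane inventory noise, and the estimator is unbiased
across seeds); and ammonium appeared at 0.109 mmol N/l/day during
Phase 2 (true configured rate 0.110). The generator's ground truth is in
`sim$truth`.

A thin command-line wrapper over the same functions ships in
`inst/cli/nitralk-cli.R` (`simulate`, `balance`, `thermo`, `stoich`,
`isotope`, `run` subcommands); CSV schemas and the `key = value` run
configuration format are documented in `?read_timeseries`,
`?read_isotope_series` and `?read_run_config`, with an example
configuration in `inst/extdata/ethane_run.cfg`.

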