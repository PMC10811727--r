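---
title: "Stoichiometry, thermodynamics and mass balances for nitrate-driven anaerobic alkane oxidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometry, thermodynamics and mass balances for nitrate-driven anaerobic alkane oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitralk)
```

## The system being modelled

Short-chain gaseous alkanes (ethane, propane, butane) can be oxidised to
CO~2~ by anaerobic bacteria using nitrate or nitrite as the terminal
electron acceptor. In sealed batch incubations this chemistry shows a
characteristic two-phase structure: while nitrate is present it is reduced
to nitrite and N~2~ with little ammonium formation (Phase 1); once nitrate
is depleted, the accumulated nitrite is reduced further, partly to N~2~
(denitrification) and partly to ammonium (dissimilatory nitrate/nitrite
reduction to ammonium, DNRA; Phase 2). `nitralk` implements the
quantitative core of the analysis of such incubations:

1. **Redox stoichiometry** — balanced half-reactions for alkane oxidation
   and the five N-oxyanion reduction couples, coupled into minimal-integer
   full reactions.
2. **Thermodynamics** — standard (ΔG°) and pH-corrected (ΔG°′) reaction
   energies per mole of alkane from a curated formation-energy table.
3. **Gas partitioning** — conversion between headspace partial pressures
   and vessel-total inventories (headspace + dissolved) via the ideal gas
   law and Henry's law.
4. **Balances** — phase segmentation, nitrogen recovery, the
   denitrification/DNRA electron split against the alkane's electron
   yield, and the DNRA rate.
5. **Isotope tracing** — ^13^C and ^15^N tracer recovery bookkeeping.
6. **A synthetic reactor** — a generator of two-phase batch profiles with
   known ground truth, used throughout the test suite.

## Redox stoichiometry

Half-reactions are completed by a fixed, deterministic convention for
aqueous redox chemistry: oxygen is balanced with H~2~O, hydrogen with
H^+^, and charge with electrons. Complete oxidation of
C~n~H~2n+2~ to CO~2~ yields 6n + 2 electrons per molecule
(14 for ethane, 26 for butane); the reduction couples demand 2
(NO~3~^−^→NO~2~^−^), 5 (NO~3~^−^→N~2~), 3 (NO~2~^−^→N~2~), 8
(NO~3~^−^→NH~4~^+^) and 6 (NO~2~^−^→NH~4~^+^) electrons per N.
`couple()` scales the two halves by the least common multiple of their
electron counts, cancels electrons, nets H~2~O/H^+^ appearing on both
sides to one side, and divides by the greatest common divisor:

```{r}
rx <- couple(alkane_oxidation_half(2), nitrogen_reduction_half("NO2->N2"))
format_reaction(rx)
check_balance(rx)
```

Half-reaction coefficients are integer multiples of one half (the half
arises only from normalising N~2~ to one N atom), so all coefficient
arithmetic is exact; full reactions are integer by construction. The test
suite confirms each of the six published-style coupled equations against a
bounded brute-force integer enumeration that knows nothing about the
balancing algorithm.

## Thermodynamics

Reaction energies are assembled from standard Gibbs formation energies at
298.15 K (1 atm gases, 1 M solutes, pure liquid water). No single
authoritative table exists for this mixed organic/inorganic chemistry, so
the package ships a small curated one (`formation_energy_table()`):
aqueous N species from the classic biochemical compilation of Thauer,
Jungermann & Decker (1977), gases and liquid water from CODATA/CRC values.
Every entry carries a provenance note and the whole table is
user-overridable through a CSV (`read_formation_energies()`), because
reasonable compilations differ by a few kJ/mol for the aqueous ions —
enough to move coupled-reaction energies by a few percent.

The biochemical-standard correction sets the H^+^ activity to 10^−pH^
while other species stay at standard states:

$$\Delta G^{\circ\prime} \;=\; \Delta G^{\circ} \;+\;
  \nu_{\mathrm{H^+}}\, R\,T \ln 10^{-\mathrm{pH}}$$

where $\nu_{\mathrm{H^+}}$ is the net signed proton coefficient. At the
defaults (pH 7, 298.15 K) the five couples for ethane and butane are all
strongly exergonic:

```{r}
thermo_summary(2)[, c("couple", "kj_per_mol_alkane")]
```

ΔG°′ conventionally refers to 25 °C even though these incubations run at
35 °C; the temperature of the correction term is exposed as a parameter
for sensitivity analysis, but formation energies themselves are treated as
temperature-independent (no van 't Hoff extrapolation — a documented
non-goal). CO~2~ is treated as gas phase by default, consistent with how
these coupled equations are conventionally written and with acidified
headspace CO~2~ quantification; `alkane_oxidation_half(n, co2_phase =
"aqueous")` switches to the dissolved pool.

## Gas partitioning

A gas in a sealed vessel is split between the headspace (ideal gas law)
and the liquid (Henry's law, concentration form $c = H^{cp} p$ with a van
't Hoff temperature correction):

$$n_{\mathrm{total}} \;=\; p\left(\frac{V_{\mathrm{gas}}}{R\,T}
  + H^{cp}(T)\, V_{\mathrm{liq}}\right)$$

Both directions are closed-form (`inventory_from_pressure()`,
`pressure_from_total()`) and round-trip to machine precision. Shipped
Henry constants come from the Sander (2015) compilation. At ≤1.2 atm no
fugacity correction is warranted. Dissolved CO~2~ is carried as CO~2~(aq)
only; carbonate speciation is deliberately out of scope, which
understates the total dissolved inorganic carbon pool at circumneutral pH
— a known limitation that does not affect the nitrogen or electron
balances.

## Nitrogen and electron balances

All balances are computed on vessel-total mmol (concentrations ×
V~liq~); per-litre outputs divide by V~liq~ at the end. Mixing the two
bases is the dominant failure mode for this kind of calculation, so
conversions happen in exactly one place.

**Segmentation.** The Phase-1/Phase-2 boundary is the first sample at
which nitrate reads below a threshold and stays below it. The default
threshold (0.05 mmol N/l) suits clean or near-clean data. For noisy data
the threshold must sit above the nitrate noise floor (≥3σ), otherwise a
single noisy late sample can postpone the boundary arbitrarily; the
replicate-recovery analyses in the test suite use 0.15 mmol N/l against a
noise σ of 0.04.

**Nitrogen balance.** Nitrogen appearing in end products (ΔNH~4~^+^ +
ΔN~2~-N) over nitrogen leaving the oxyanion pool (−ΔNO~3~^−^ −
ΔNO~2~^−^), both per litre liquid.

**Electron ledger.** Only end-member pools are observable, so the ledger
is declared explicitly: every N ending as N~2~ cost 5 e^−^ (the 2 e^−^
nitrate→nitrite leg plus 3 e^−^ nitrite→N~2~, or the direct Phase-1
route, which is the same total); every N ending as NH~4~^+^ cost 8 e^−^;
nitrite still present at the end cost its 2 e^−^ production leg but
belongs to neither pathway. Ammonium formed during Phase 1 (nominally
negligible) is conservatively priced at the full 8 e^−^. Summing the
phase-wise increments telescopes to an endpoint form, which makes every
balance quantity invariant to the density of interior samples — a
property the tests assert directly. The sum of the three pools over the
maximum electron yield of the measured alkane drawdown, (6n+2) ×
Δalkane, is the electron-balance fraction. The decomposition is checked
against an independent per-timestep ledger that prices the same
transformations on the alternative route (2 e^−^ per nitrate consumed
plus 3/6 e^−^ per N~2~/NH~4~^+^ formed from nitrite).

**DNRA rate.** The least-squares slope of NH~4~^+^ against time over
Phase 2, converted to mmol N/l/day. When the nitrate-depletion transition
is observed inside the series, the transition sample itself is excluded
from the regression: depletion happens somewhere within the preceding
sampling interval, so ammonium production ran for only part of it, and
keeping that sample biases the slope low by an amount set by the sampling
grid. For exactly linear Phase-2 data the exclusion changes nothing.

## Isotope tracing

All tracer quantities are handled in atom units (μmol ^13^C, μmol ^15^N);
the only molecule-based inputs, the N~2~ isotopologues, are converted at
ingestion (one ^15^N per ^29^N~2~, two per ^30^N~2~). ^13^C recovery is
labelled CO~2~ over labelled alkane carbon consumed; ^15^N recovery sums
^29^N~2~, ^30^N~2~ and ^15^NH~4~^+^ against consumed ^15^NO~3~^−^.
`pairing_fractions()` provides the random-pairing null — binomial
fractions ((1−p)², 2p(1−p), p²) for ^28/29/30^N~2~ at ^15^N atom fraction
p — for interpreting isotopologue ratios; at the ~1% labelling typical of
these experiments essentially all labelled N~2~ is ^29^N~2~.
Natural-abundance background subtraction is not applied (labelled pools
are reported directly).

## The synthetic reactor

The generator emulates the two-phase batch profiles: zero-order nitrate
reduction at rate r~1~ split between N~2~ and nitrite (fraction
`f_n2_p1` to N~2~), then zero-order nitrite reduction at r~2~ split
between ammonium (`f_nh4_p2`) and N~2~, with the alkane drawn down at
every step so donated electrons exactly meet the nitrogen demand and n
CO~2~ produced per alkane. Zero-order kinetics were chosen because the
observed batch profiles are near-linear within each phase and no kinetic
constants are available for these enrichments; saturating (Monod) kinetics
are out of scope. The simulator conserves nitrogen and electrons to
machine precision at every step, which is what makes it a usable oracle:
any estimator applied to its noise-free output must return recovery and
electron fractions of exactly 1.

Three presets (`scenario_library()`) describe the study conditions:

* **ethane-like** — 2.0 mmol N/l nitrate into a vessel with 0.3 l
  headspace over 0.82 l culture at 35 °C, ~1 atm ethane,
  r~1~ = 0.012 mmol N/l/h, 30% of Phase-1 N to N~2~,
  r~2~ = 0.010 mmol N/l/h with 46% to ammonium (DNRA rate
  0.11 mmol N/l/day), sampled every 12 h for 300 h.
* **butane-like** — 1.6 mmol N/l nitrate, 0.15 l headspace over 0.5 l
  culture, ~1 atm butane, a faster Phase 2 (r~2~ = 0.045 mmol N/l/h) with
  71% to ammonium (DNRA rate 0.77 mmol N/l/day), sampled every 8 h.
* **no-dnra** — ethane-like with all Phase-2 nitrite routed to N~2~.

Measurement noise is additive Gaussian, truncated at zero, independent
per analyte, and fully determined by the stored seed. The defaults
(`default_noise_sd()`) put ~2% of signal on the aqueous N species
(σ = 0.04/0.04/0.02 mmol N/l) and ~0.5% of the inventory on the
vessel-total gases (σ = 0.02 mmol N~2~, 0.06 mmol alkane/CO~2~),
reflecting ion-chromatography versus replicate-GC precision. The gas
noise level matters: endpoint alkane consumption is a small difference
between two large inventories (~0.7 of ~13 mmol in the ethane preset), so
per-cent-of-inventory noise in the alkane column dominates the replicate
scatter of the electron-balance fraction.

An optional `uncoupled_sink` fraction diverts part of the donated
electrons away from nitrogen, generating datasets whose true electron
fraction is 1 − sink; the tests use it to show the estimator is not
trivially pinned at 1 (a configured 0.8 is recovered within ±0.02 across
200 replicates).

**What the generator does not emulate.** Biomass growth and carbon
assimilation (real incubations recover only ~70–80% of alkane carbon as
CO~2~; the simulator routes all of it there), pH drift, kinetic
saturation, gas-transfer limitation, and replicate-bottle hierarchies.
Estimator tests passing on synthetic data therefore demonstrate
correctness of the accounting, not that real incubations satisfy the
accounting's assumptions.

## Numerical choices and degenerate inputs

* Stoichiometric arithmetic is exact (integers and exact halves); gcd
  reduction at the end; a coupling that fails integrality by more than
  10^−9^ aborts rather than rounding silently.
* The gas constant is 8.314462618 J mol^−1^ K^−1^ (0.082057 l atm
  mol^−1^ K^−1^ in pressure form); energies are reported in kJ.
* Zero net oxyanion drawdown makes the nitrogen recovery undefined; the
  electron balance still reports (with NA nitrogen fields), since
  nitrate fully accumulated as nitrite is a legitimate electron sink.
* Zero alkane drawdown, empty series, non-monotone time and negative
  concentrations are rejected with named errors.
* Simulated noise is truncated at zero, which introduces a small positive
  bias only where the clean signal sits within ~2σ of zero (depleted
  pools); the replicate tests show the effect is negligible at the study
  conditions.
* Test problem sizes: simulations integrate 300 h at dt = 0.25 h and the
  replicate analyses use 200 seeded runs — small enough for an
  interactive test cycle, large enough for a Monte-Carlo standard error
  near 0.01 on the electron fraction.

## Known limitations

* Reproduction of published coupled-reaction energies is limited by the
  formation-energy compilation (different standard tables move the
  nitrate→nitrite couples by 1–4%); the shipped table reproduces five of
  the six anchor values to ≲0.1% and the butane/nitrate→nitrite couple to
  ~2%.
* The electron ledger assumes all reduced N originated from the nitrate
  pool via nitrite or directly — appropriate for these incubations, wrong
  for systems with anammox or nitrification.
* The DNRA rate is a single-slope summary; it underestimates the true
  rate if Phase 2 extends past nitrite depletion into a plateau (crop the
  series, or sample only the active window, as the presets do).
* The segmentation rule is threshold-based and intentionally simple;
  change-point methods would be more robust at very coarse sampling but
  are not implemented.
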