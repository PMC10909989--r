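---
title: "Kinetic modelling of extracellular acidification assays with ecaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of extracellular acidification assays with ecaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecaflux)
```

## The model and its assumptions

Kinetic glycolysis assays report extracellular acidification (ECA) of the
culture medium as a fluorescence signal sampled a few hundred times over
roughly two hours. In starved cells fed a single glucose bolus the signal is
dominated by exported lactate, and shows two phases: a rise while glucose
lasts, and a decline once the reservoir empties and lactate is re-imported
and consumed. `ecaflux` models this with a deliberately small mass-action
network — eight species, seven reactions, four of them reversible — rather
than an enzyme-resolved glycolysis model. The reduction reflects what the
assay can actually constrain: end-point kinetics, not intermediate
metabolite levels.

The assumptions worth keeping in mind:

* **Mass-action rate laws with capacity throttles.** Glucose uptake is
  `k_in * Glu_ex * (Capacity_G - Glu)` and pyruvate entry into the
  mitochondrion is `kf_4 * Pyr * (Capacity_M - TCA) - kr_4 * TCA`. The
  capacities are *constant boundary quantities*, not state variables: they
  throttle influx (the factor vanishes as the pool fills) but are never
  consumed. `Capacity_G` governs the phase-1 rise; `Capacity_M` governs the
  phase-2 lactate consumption.
* **Single carbon source, closed mass balance.** Every reaction transfers
  one unit of mass 1:1, so the stoichiometry columns each sum to zero and
  the total over the eight species is invariant — numerically useful (a
  solver check with a known exact answer) and biologically a statement that
  CO2 loss, gluconeogenesis and biomass dilution are out of scope.
* **Lumped mitochondria.** The entire TCA cycle plus oxidative
  phosphorylation is one pool draining irreversibly into two sinks (`OxPP`,
  `CellComponents`). With equal drain rates (`kf_5 = kf_6`, as in all three
  published fits) the two sinks accumulate identically.
* **Drug action as dimensionless dose factors.** Oligomycin multiplies the
  glycolytic forward rate by `(1 + oligo*i2)` and the OxPP drain by
  `(1 - oligo*i2)`; 2-deoxyglucose subtracts `dg2*i1` from the glycolytic
  forward factor. One shared `i2` serves both oligomycin roles. Doses are
  model units on 0–10; wet-lab concentrations (2 μM oligomycin, 100 mM
  2DG) have no established mapping to model units, and the package
  deliberately does not invent one.
* **Units.** Concentrations in μm, time in minutes; rate constants are
  carried numerically as model units without dimensional analysis of the
  composite capacity terms. Compartment volumes are fixed at 1 and never
  enter the equations.

Three presets encode the published cell-line fits: `A549` (the reference),
`LLCMK2` (lower uptake `k_in` = 1e-4 and doubled lactate re-import
`kr_3` = 0.2) and `HepG2` (lower uptake, reduced capacities 350/40 and a
tenfold lower oligomycin sensitivity `i2` = 0.01). All start from 20 000 μm
extracellular glucose with every cellular pool at zero.

## The modulation-factor clamp

The printed forward law of the glucose→pyruvate step turns negative once
`dg2 * i1 > 1 + oligo * i2` — at doses beyond the published 0–10 range an
inhibitor would drive the enzyme backwards. The package clamps the factor
at zero from below: `max(0, 1 + oligo*i2 - dg2*i1)`. Within the published
dose range and sensitivities the clamp is inactive (at `i1 = 0.1`, dose 10
lands exactly on zero), so published behaviour is unchanged; beyond it the
forward flux simply stops. The clamp applies only to the forward term — the
reverse term `kr_1 * Pyr` is never modulated. The clamp is the package's
own declared choice.

## Numerical integration

The capacity terms create fast transients at `t ≈ 0` (uptake starts at
1200 μm/min into empty pools), so `simulate_eca()` uses a stiff-capable
adaptive solver (`deSolve::lsoda`) with `rtol = 1e-8` and
`atol = 1e-10 * glu_ex0`. Three safeguards follow each run:

* conservation: the row sums must stay within 1e-6 (relative) of the
  initial glucose;
* nonnegativity: no projection is applied *during* integration (it would
  silently break conservation); instead the trajectory is asserted
  post-hoc to stay above `-1e-6 * glu_ex0`. The rate laws are
  self-limiting, so in practice negativity never exceeds round-off;
* an independent check in the test suite compares the final state against
  a hand-coded fixed-step explicit-Euler integration at `dt = 1e-3` min,
  agreeing within 0.1% per species for all three presets.

The default output grid mirrors the instrument: 400 cycles at 0.35 min
(0 to 139.65 min). The horizon is extensible; metrics are stable under grid
refinement to well below 0.01%.

Trajectory summaries quantify the two phases: the extracellular lactate
peak (global maximum, earliest index on ties) and the glucose exhaustion
time, defined as the first time `Glu_ex` drops below 1% of its initial
value. "Nearly exhausted" names no threshold by itself; 1% is the
package's convention, with the degenerate zero-glucose run defined as
exhausted at the start.

## Assay preprocessing

Plate-reader wells are normalized by a matched cell-free control via
pointwise **division**: any multiplicative instrument drift shared by the
wells cancels exactly, which is the reason cell-free controls are run at
all. Subtraction is available behind a method tag but is not the default,
and division-then-replicate-averaging is the package's declared order
(neither choice is standardized for this assay). Note that dividing by a
cell-free
well whose signal is the sensor offset `b` rescales the affine
signal-lactate map from `(a, b)` to `(a/b, 1)`; the calibration machinery
profiles the affine map out, so this rescaling is harmless.

ECAR is estimated as the slope of a centered sliding-window ordinary
least-squares fit (default 7 samples ≈ 2.45 min) — robust to
point-to-point noise where a two-point difference is not; edge windows are
truncated one-sided. Phase metrics use the field's convention of phase 1
below 70 min and phase 2 above 90 min, with the peak located on a 5-point
moving average (earliest time on ties).

## Calibration

The cell-line parameterisations the presets encode were obtained by best
fit without a stated objective or optimizer; the package declares one:
profiled-affine least squares. For a
candidate parameter vector the model is simulated under each curve's dose,
the affine map from simulated `Lac_ex` to the observed signal is profiled
out by inner OLS (one map per curve), and the summed residual sum of
squares is minimized over the free parameters by L-BFGS-B on a log10 scale
within box bounds, from multiple starts drawn log-uniformly within the
bounds using a recorded seed. The default free set is exactly the
parameters that differ between the published cell-line fits
(`k_in`, `Capacity_G`, `Capacity_M`, `kr_3`, `i2`); default bounds span a
factor of ten either side of the base value, comfortably containing all
published variation. Failed simulations contribute a large finite penalty.
Identical problems and seeds give bit-identical results. If a fitted affine
slope would be nonpositive, it is pinned at a tiny positive value and
flagged degenerate rather than silently inverting the signal.

The test suite exercises recovery: a single free rate (`kr_3`, truth 0.2)
is recovered exactly from noiseless synthetic data and within 10% at 1%
multiplicative noise; the capacity pair (350, 40) is recovered within 10%
at 1% noise when fitted jointly on the three plate conditions (shared
kinetic parameters, one affine map per curve) with 10 multistarts. A
single-condition fit of the pair is noticeably less precise along
`Capacity_M` — one reason the assay's parallel control/stimulated/inhibited
plate design matters.

## Sensitivity and dose protocols

One-at-a-time sweeps scale a single parameter by factors 0.50–1.50 in
steps of 0.10 — five decrements, the baseline, five increments: eleven
simulations, the ±10%-step eleven-run one-at-a-time protocol. Whether the
eleven runs include the baseline is a convention; this factor grid is the
package's declared reading. Dose sweeps default
to integer doses 0–10 with the other modulator held at zero; dose 0 is
bit-identical to the control run.

Two measured deviations from naive expectations are worth recording. The
glucose-pyruvate reverse rate `kr_1` is inert at ±10% (peak change 0.02%)
but its influence grows to ~0.12% at the ±50% factor extremes — "no
effect" is a ±10% statement. And the 140-min endpoint of the OxPP sink is
*not* monotone in 2DG dose: mild inhibition slows the flux without
preventing it from reaching the sinks within the horizon, so terminal OxPP
rises ~2% up to dose 5 before collapsing at strong inhibition. The lactate
peak, by contrast, is cleanly monotone in both drugs.

## The synthetic-data generator

`generate_eca_dataset()` emulates the statistical structure the analysis
assumes: latent `Lac_ex` kinetics per condition from the model; an affine
sensor map (defaults `a` = 0.004 RFU/μm, `b` = 10 RFU, chosen to put
signals in a plate-reader-typical few-tens-of-RFU range); a linear drift
profile applied multiplicatively and *shared by every well including the
cell-free controls*, so cell-free normalization cancels it exactly;
independent multiplicative Gaussian noise per well and time point (default
σ = 1%, a declared convention — the instrument's true noise is unknown);
triplicate wells on the 400-cycle grid. Default condition doses are 5 model
units for both drug conditions (mid-range of the sweep domain). Everything
is seeded; a seed is mandatory.

What it does **not** emulate — and hence what passing tests do not show
about real plates: the pre-starvation initial ECA spike from cellular
carbon reserves, CO2-driven acidification, additive background, plate-edge
and temperature effects, and autocorrelated sensor noise. Parameter
recovery on this generator demonstrates that the calibration machinery is
correct under the model's own assumptions, not that the model is identified
on any given real dataset.

## Interchange formats

Parameter sets serialize to a flat `key = value` TOML file using the
published table names (`Glu_ex` for the initial glucose). The model exports
to SBML Level 3 Version 2 core with the capacities as constant
boundary-condition species, modulators as constant species referenced
inside the kinetic-law MathML (doses are constant over a run, so no events
are needed), and the printed rate laws stated verbatim in MathML; the
exported clamp-free laws are the printed ones, the clamp being a runtime
guard outside the published dose range. Import reconstructs parameters and
network from any structurally equivalent document, warns on unknown
extras, and names missing elements in its errors. Round trips are
bit-lossless on parameters and preserve simulations to 1e-8 relative.
Trajectory and kinetic CSVs are written at 17 significant digits so
re-reading is lossless.

## Problem sizes

The test suite and acceptance script run simulations on the full 400-point
instrument grid; calibration unit tests use a 100-point grid at 1.4-min
spacing (the latent kinetics are fully resolved there), while the
acceptance-level recovery experiments fit the full 400-point curves with
10 multistarts. The Euler oracle uses 139 650 fixed steps per run.

## Known limitations

* Model units: rate constants are not dimensionally decomposable, and
  wet-lab drug doses have no defined mapping to model units.
* Calibration is local multistart least squares — no global optimality or
  posterior uncertainty; identifiability beyond the recovery tests is not
  analysed.
* The ECA signal is attributed entirely to lactate; CO2/bicarbonate
  acidification is out of scope, as are gluconeogenesis and enzyme-level
  glycolysis.
* No mid-run events (drug addition during acquisition) and no stochastic
  simulation.
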