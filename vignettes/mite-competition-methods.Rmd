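---
title: "Methods: stage-structured competition of inducer and suppressor mites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-structured competition of inducer and suppressor mites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitecomp)
```

## The biological problem

Some spider mite strains ("suppressors") secrete salivary effectors that
down-regulate tomato's induced defences; others ("inducers") trigger them.
Suppression is a common good: it improves the shared leaf for every mite
on it, including competing inducers. Whether suppressors can displace
inducers therefore hinges on the balance between the demographic cost
structure of each strain and the benefit `b` that inducers skim off the
suppressed plant — and that balance shifts with temperature, because
development, mortality and fecundity all respond to it. This package
implements the analysis pipeline for that question: assay metrics →
demographic rates → a two-strain competition model run under temperature
schedules.

## Assay metrics and their mortality correction

Leaflet assays confine ~14 mated adult females for 2 days and tally alive
females, dead females, eggs and feeding damage only at the end. Deaths are
therefore interval-censored: a female found dead may have stopped laying
at any point. Under roughly constant daily mortality, crediting each dead
female with half the assay duration is the natural midpoint correction,
and all three per-capita metrics use it:

* daily survival `1 - (dead / days) / (dead + alive)`,
* fecundity `(eggs / (alive + dead/2)) / days`,
* damage per female `area / (alive + dead/2)` (per assay, not per day).

`assay_days` is a field (default 2) rather than a constant: the formulas
generalise, and the synthetic generator can emulate longer assays. Assays
shorter than one day are rejected — the daily-survival formula can leave
[0, 1] there, and the daily observation design makes them meaningless.
Damage areas exist only for photographed leaflets, so a missing
`damage_area` fails loudly per record (scalar API) or yields `NA` per row
(table API), never silently.

Damage is calibrated from pixels using the adult mite body length
(0.4 mm) measured in pixels on each image; gene expression uses delta-Ct
normalisation with an amplification base defaulting to 2 (perfect
doubling) — the efficiency model is a choice, not a measurement, and the
base is exposed as an argument. Scaled expression divides by the lowest
per-gene group mean, so the lowest group reads exactly 1 and the rest are
fold changes; the operation is idempotent.

## From observations to rates

Development rate is mean-then-invert (`1 / mean(days to adult)`),
matching the `1/days` form in which such rates are conventionally
reported. Mortality conversions expose an explicit `convention` argument:
`"log"` (`mu = -log(s)`, the exact continuous-time rate consistent with an
ODE; the default) and `"linear"` (`mu = 1 - s`, its first-order
approximation). How the published rates were originally derived from
survival proportions is not stated, and at the survival levels involved
the two conventions differ by under a percent, so the package makes the
choice explicit rather than guessing silently. Net reproduction multiplies
fecundity by the proportion of female offspring. Generation time (egg to
first oviposition) is computed as a descriptive statistic only; the model
does not use it.

`mite_params_registry()` ships the published rate sets for both strains at
25 °C and 32 °C with `C = 1000`, `b = 1.25`. The registry is the single
source of truth for reference simulations; estimation functions process
raw (or synthetic) data and are never substituted for it implicitly. All
four registry sets satisfy the viability condition `r e > mu v`.

## The competition model

The right-hand side is implemented exactly in the printed stage-structured
form (see the README for the equations), with three deliberate choices:

* **Density dependence is the clamped-logistic form**
  `r max(0, 1 - N/C)` with `N` the total over both strains and stages.
  The prose label "Michaelis–Menten" does not match the printed equations;
  we verified that a saturating `C/(C+N)` form lets totals blow far past
  the carrying capacity, contradicting the reported dynamics, so the
  printed form governs.
* **`b` multiplies inducer reproduction unconditionally**, exactly as
  printed. One could argue it should vanish when suppressors are absent;
  in every scenario analysed suppressors are present, and `b` sits in the
  config so a density-dependent variant can be explored without touching
  the solver.
* **Maturation is a source term only**: the printed juvenile equations do
  not subtract `e N_1`. We checked the conventional variant with the
  outflow; for these parameter sets it changes the headline outcomes by
  under a day, and the printed form is what we implement.

The single-strain equilibrium `N* = C (1 - v mu / (r e))` (stage split
`N1/N2 = mu/e`) is exposed both as a user-facing function and as the
closed-form oracle for the long-run convergence tests.

## Temperature regimes

Schedules are ordered half-open segments `[start, end)` tiling
`[0, season)`; the switch day belongs to the new temperature, which makes
lookups deterministic with no double counting. A "month" is
operationalised as the 4-week cycle implied by the week arithmetic of the
heatwave scenarios: `hw1` = 3 weeks at 25 °C + 1 week at 32 °C repeating,
`hw2` = alternating fortnights, both truncated at day 98. Switching is
instantaneous — a deliberate simplification; real heatwaves ramp.

## Simulation and event detection

Integration is `deSolve::lsoda` (adaptive, stiff/non-stiff switching) with
`rtol = 1e-8`, `atol = 1e-10`, run segment by segment with the state
carried across switches unchanged; the 0.1-day output grid is cosmetic
(halving it moves finals by under 1e-4 relative). The crossover day —
first time total suppressor density strictly exceeds total inducer
density — is located on the grid and refined by bisection on the ODE to
0.01 days. Persistence compares each strain's final total against a
threshold of 1 individual/plant; it is purely a reporting rule and never
feeds back into the continuous dynamics.

Initial conditions: the published scenarios state only totals (90
inducers, 10 suppressors). We allocate both entirely to the adult
compartments, because the corresponding experiments infest plants with
mated adult females. Sensitivity: moving the split between all-juvenile,
50:50 and equilibrium allocations shifts the constant-32 °C crossover
within roughly 23–25 days and the two-week-heatwave crossover within
50–52 days, so the qualitative ordering of scenarios is unaffected. With
the registry rates and the adult allocation the package computes a
constant-32 °C crossover of 24.4 days, a two-week-heatwave crossover of
51.1 days, and an end-of-season inducer density of 1.6 individuals/plant
at constant 32 °C — the same quantities `scripts/acceptance.R` writes out.

## The synthetic-data generator

`generator_spec()` emulates the two assay designs, not any particular
dataset. Defaults are fixed once at values a mite life-history study would
call typical, echoing inducer-like biology at 25 °C: 14 females/leaflet
for 2 days, daily adult survival 0.95, 12 eggs/female/day, 70 % female
offspring, egg-to-adult development around 12.3 days; 5–7 eggs per leaf
disc observed daily.

Distributional choices: deaths follow a per-day binomial thinning; egg
counts are negative-binomial (`size = 10`), because field counts of this
kind are over-dispersed relative to Poisson — no dispersion estimates
exist for these assays, so the value is an artifact choice, exposed as a
parameter; damage areas are Gamma (`shape = 5`). Dead females contribute
half the assay's exposure when the generator sets expected egg and damage
totals — the same convention the metrics divide by — so fecundity and
damage-rate estimates are unbiased for the generating values by
construction.

Disc cohorts draw independent Gamma stage-to-stage durations (cumulative
ages are therefore strictly increasing within an individual), observed on
a daily grid (`ceiling(age)`), with geometric daily juvenile survival and
Bernoulli sex. The disc record keeps the day the *first* individual
reached each stage, mirroring the field protocol. That first-individual
convention is a minimum statistic, so the development-time estimate is
pulled below the per-egg mean by roughly `1.27 sd` for cohorts of 5–7;
with the default stage synchrony (`stage_cv = 0.05`, giving an egg-to-adult
sd of ~0.3 days — development of same-aged eggs at constant temperature is
highly synchronous) the pull is a few tenths of a day and partially
cancels against the daily-grid rounding, leaving the development-rate
estimate within ~1 % of the generating value. At much larger cohort sizes
or spreads the bias would dominate; that is a property of the sampling
design being emulated, not an estimator bug, and the recovery report makes
it visible.

What the generator does *not* emulate: the block/random-effect structure
of the real experimental design, plant-to-plant heterogeneity,
within-assay temporal trends, and qPCR data beyond trivial fixtures.
Passing recovery tests therefore show the pipeline is internally
consistent and unbiased under its own assumptions — they do not validate
the distributional assumptions against real data.

## Problem sizes and numerical budgets

Test and acceptance runs use: 98-day seasons on a 0.1-day output grid;
single-strain convergence runs to t = 500; a fixed-step Euler oracle at
h = 1e-3 as the independent integrator cross-check (agreement within
0.5 % at t = 98); recovery at 1000 leaflets / 200 discs, where every
recovered parameter sits within 5 % relative error. These sizes keep the
full suite in the tens of seconds while leaving Monte-Carlo standard
errors well below the tolerances they are checked against.

## Known limitations

* Continuous densities: extinction is a reporting threshold, not an
  absorbing state; densities below one individual/plant still grow
  deterministically.
* No between-strain mating, spatial structure, demographic stochasticity,
  plant-quality dynamics, or thermal performance curves — temperature acts
  only by swapping discrete rate sets.
* The published crossover narrative ("about four weeks", "about two
  months") is figure-granular; the package reports continuous,
  bisection-refined crossover days, which land a few days earlier than
  those round-number readings under every initial-stage allocation we
  probed.
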