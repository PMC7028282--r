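---
title: "Combining handprint and footprint into a single score: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining handprint and footprint into a single score: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsbr)
```

## The problem

Endpoint life-cycle impact assessment reports the environmental *footprint*
of a product or service as damage to three Areas of Protection (AoP):
Human Health in disability-adjusted life years (DALY), Ecosystems in
species.yr, and Resources in USD surplus extraction cost.  A pharmaceutical
treatment also has a *handprint*: the patient-health burden of the treated
cohort, likewise measured in DALY, which treatment reduces relative to a
no-treatment comparator.  The question the package answers is whether that
health benefit outweighs the environmental burden, in one interpretable
number per comparison.

Both handprint and footprint are stored as **burdens** (non-negative
values); a benefit only ever arises from comparing two scenarios.  This
keeps the algebra uniform — no signed burdens, no special-casing of the
beneficial side.

## The aggregation pipeline

For a scenario with footprint $f = (f_{HH}, f_{ECO}, f_{RES})$ and
handprint $h$ (DALY), given a footprint normalization set
$N = (N_{HH}, N_{ECO}, N_{RES})$ (category totals per year), a handprint
normalization factor $N_h$ (total global disease burden per year) and
weights $w$ with $\sum w = 1$:

$$\mathrm{SiSc} = w_{HH}\left(\frac{h}{N_h} + \frac{f_{HH}}{N_{HH}}\right)
 + w_{ECO}\frac{f_{ECO}}{N_{ECO}} + w_{RES}\frac{f_{RES}}{N_{RES}}$$

Normalization is **external** (division by a reference total, so the
normalized value is the scenario's share of a real-world burden) and
**separate** for handprint and footprint: the footprint's Human Health
damage travels an environmental cause–effect chain and is normalized
against environmentally attributable health damage, while the handprint is
direct patient burden, normalized against the all-cause global burden of
disease.  The two are added on Human Health only *after* weighting
(`combine_hh()`).  Internal normalization (ranking alternatives within the
study) is deliberately not offered — it cannot express relative
significance against a global total.

Two scenarios are compared through the Relative Sustainability Benefit
Rate,

$$\mathrm{RSBR} = \frac{\mathrm{SiSc}_{comparator} -
\mathrm{SiSc}_{treatment}}{\mathrm{SiSc}_{comparator}} \times 100\ (\%),$$

positive when treatment carries the lower burden.  Results tables in this
field conventionally print the negated value (a burden *reduction* shows as
negative); `table_sign = TRUE` applies that display convention, the core
always computes the equation as written.

**Combined or separate.**  When treatment lowers the handprint but raises
the footprint (the usual trade-off), a single combined rate expresses the
net benefit.  When both move in the same direction, the combined rate is
dominated by the larger absolute term — in practice the handprint, which
exceeds the weighted footprint by orders of magnitude — and would
misrepresent the footprint's own, often larger, *relative* change.
`decide_rsbr_mode()` therefore reports the rates separately exactly when
both deltas are nonzero with equal sign; a zero or absent delta on either
side falls back to combined.

**Degenerate inputs.**  A comparator single score of zero makes the rate
undefined; it is reported as `NA`, never $\pm\infty$.  Footprint entries
marked missing (not assessed) are distinct from zero in storage and I/O,
but contribute zero to score sums — the convention of the reference report,
which prints an all-zero row for the unassessed comparator footprint.
Weighting sets whose weights do not sum to 1 within $10^{-9}$ are rejected
rather than renormalized: silent repair would hide data errors in
user-supplied panel sets.

## Built-in case studies and derived reference factors

Two pharmaceutical cases ship with the package (`builtin_case()`): a
mebendazole mass-drug-administration programme against soil-transmitted
helminthiases in 8 million Vietnamese children over five years, and
once-monthly paliperidone palmitate maintenance treatment of 1000 Belgian
patients with schizophrenia for one year (comparator: treatment
interruption).  Their footprint and handprint burdens are transcribed from
the published tables of the underlying studies.

The numeric normalization-factor tables of the reference frameworks
(ReCiPe endpoint sets, PROSUITE, the year-by-year global burden of disease)
are not bundled.  Instead, `reference_factors()` derives each factor as
(raw burden) ÷ (printed normalized value) from one row of the published
reference run — the comparator row where possible; the STH footprint uses
the treatment row because its comparator footprint was never assessed.
This reproduces the reference report's own rows without inventing external
data, at a price: printed cells carry three significant figures, so derived
factors inherit up to ~0.5% rounding error, and the two cases imply
slightly different Human Health footprint factors (about 8.29e7 vs 8.72e7
DALY/yr).  Regression tests therefore compare pipeline output to printed
cells at 1.5% relative tolerance (signed rates at 0.15 percentage points).
One cell group is irreconcilable beyond rounding: the schizophrenia
treatment footprint's Human Health column implies a normalization factor 5%
away from the comparator row's, and the printed handprint-normalized values
of that case imply arm-specific factors.  Those cells are checked from the
printed normalized rows directly rather than through the derived factors,
and the published handprint-rate figures that depend on them are not
reproduction targets.

## Value-choice uncertainty

Normalization and weighting are value choices, not measurements.  The
package treats them as a discrete uncertainty space: pools of candidate
sets (`factor_pools()`), sampled hierarchically per iteration
(`sample_iteration()`): footprint and handprint normalization sets
uniformly from their pools; the weighting set by first picking one of the
three main families — Eco-Indicator 99, the Itsubo country panels, EC-JRC
Environmental Footprint — uniformly, then a sub-set uniformly within the
family.  With the canonical pool structure (4 footprint NF, 4 handprint
NF, families of 4/19/3 weighting sub-sets) each family has probability
33.33%, each Eco-Indicator sub-set 8.33%, each Itsubo sub-set ≈1.75%, and
the Cartesian product over the three handprint variants (base/min/max) has
4 × 4 × 26 × 3 = 1248 combinations.  The EC-JRC family size of 3 is
inferred from the published totals (26 sub-sets, 4 + 19 known), and the
pool constructor records the structure explicitly so users can change it.

`run_monte_carlo()` (default 10,000 iterations) re-runs the entire
pipeline per draw and summarizes median, extremes and 2.5/97.5 percentiles
(linear interpolation between closest ranks, `stats::quantile` type 7 —
the published analysis reports only median/min/max, so any consistent
percentile method serves; the most common one is used and documented
here).  How the three handprint variants entered the published iteration
scheme is not stated; they are sampled uniformly per iteration by default,
with a `variant` argument to pin one.  This only affects the sampled
median — exact extremes always come from `enumerate_combinations()`, which
evaluates every combination and whose value set provably brackets any
sample from the same pools (a tested invariant).  Iterations with an
undefined rate are excluded from percentiles and reported as a count.
All sampling uses R's seeded Mersenne-Twister stream; identical seeds give
byte-identical outputs.

`one_way_sensitivity()` (default 2,000 iterations) attributes single-score
spread to one side of the value-choice space: either the normalization
sets are held at a reference and weighting is sampled, or vice versa.  The
published design does not state whether the fixed side is a single
reference set or re-drawn once per run; the reference-set reading is
implemented, as it makes the two axes directly comparable.

**Synthetic pools.**  The actual factor tables behind the published
sensitivity analysis live in supplementary material that is not bundled.
`synthetic_pools()` generates pools with exactly the canonical structure
but synthetic values: normalization factors log-uniformly perturbed within
a factor of 3 around the derived reference (published factor families for
the same category differ by roughly that order), weights drawn uniformly
on the simplex.  Such pools exercise every code path and preserve all
structural properties (combination count, sampling law, bracketing), but
their medians and ranges are *not* the published ones; passing tests on
them demonstrates correctness of the machinery, not agreement of
uncertainty intervals with the published run.  Real tables can be supplied
in the same JSON schema via `read_factor_pools()`.

## The cohort state-transition engine

Handprints originate upstream in disease models.  `markov_model()` defines
a cohort Markov model — health states with disability weights in \[0, 1\],
a row-stochastic per-cycle transition matrix (rows must sum to 1 within
$10^{-9}$; absorbing states must self-transition with probability 1), a
cycle length in years, a horizon in cycles, an initial distribution and a
cohort size.  `run_cohort()` propagates expected occupancy (no
microsimulation; parameter uncertainty is handled downstream through the
min/base/max handprint variants) and accumulates

* YLD: occupancy × disability weight × cycle length, accruing on the
  occupancy at the **start** of each cycle (one convention must be fixed;
  this one makes the one-state model's closed form $n \cdot dw \cdot t$
  exact), and
* YLL: each entry into a death state × that state's remaining life
  expectancy, which defaults to zero — mortality parameters are only
  counted when the user supplies them.

A half-cycle correction (halving the first and last cycle's YLD accrual)
is available behind an explicit flag and off by default: the cited disease
models' cycle conventions are not described, so the engine defaults to the
simplest reading and leaves standard health-economics practice opt-in.
`constant_burden()` covers comparators in which the initial disease state
simply persists (cases × dw × years, provably equal to an identity-matrix
cohort run), and `handprint_from_models()` pairs two arms into
`handprint_estimate` objects, deriving min/max by rescaling all disability
weights ±20% by default — a deliberately simple one-parameter sensitivity,
not a reconstruction of any published model's analysis.  The bundled
presets (`markov_preset()`) are structurally analogous to the worm-burden
and relapse models behind the case studies but carry synthetic parameters;
the published transition matrices live in their original sources and are
not transcribed.

## Numerical and testing choices

Validation failures raise a dedicated condition class
(`rsbr_validation_error`), which the command-line wrapper maps to exit
status 2.  Scores agree with the direct closed-form
$\sum_a w_a f_a / N_a + w_{HH} h / N_h$ to $10^{-12}$ relative on 1000
random cases; the two-state geometric cohort model matches its analytic
YLD to $10^{-10}$; long-run cohort distributions match the stationary left
eigenvector of the transition matrix to $10^{-8}$.  The test suite sizes
its simulations for quick default runs: 100,000 draws for the sampling-law
check (binomial tolerance ±0.5 percentage points on 8.33% and 33.33%),
10,000-iteration Monte Carlo only where a median must sit between
enumeration order statistics, 2,000 and below elsewhere.  Output
formatting defaults to three significant figures in scientific notation,
the precision of the reference tables.

## Known limitations

* Derived reference factors inherit the three-significant-figure rounding
  of their source cells; analyses needing the genuine ReCiPe/PROSUITE/GBD
  totals must supply them.
* The discrete pool design captures *which* published value-choice sets
  are plausible, not parametric uncertainty within a set; inventory-data
  uncertainty (upstream of the endpoint results) is out of scope entirely,
  as is computing footprints from inventories.
* Monetization, distance-to-target and multi-criteria alternatives to
  panel weighting are not implemented.
* The cohort engine is expectation-level: no individual-level variability,
  no probabilistic transition sampling, no discounting of future DALYs.
* With weights fixed and one AoP dominant (as in both built-in cases,
  where the handprint dominates Human Health), combined rates track the
  dominant term; the separate-mode rule mitigates, but cannot remove, the
  compensatory nature of weighted sums.
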