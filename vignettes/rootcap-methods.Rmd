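---
title: "Soil-water-corrected root capacitance: models and design"
author: "rootcap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil-water-corrected root capacitance: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootcap)
```

## The measurement problem

Root electrical capacitance (C_R, nanofarads) — the parallel capacitance
measured at 1 kHz between a ground electrode in the soil and a clamp on the
plant stem — is a rapid, non-destructive proxy for the size and activity of
the absorbing root surface. Its major confounder is soil water content: C_R
rises roughly exponentially with the relative water saturation of the soil
around the roots (θ_rel, volumetric water content divided by the soil's
saturation water content, here 0.476 cm³ cm⁻³). Field campaigns measure on
days with very different moisture, so raw C_R values from different days —
or from plots with heterogeneous moisture — are not comparable.

`rootcap` implements the correction pipeline: calibrate the moisture
dependence in pots, invert it, and express every field reading as the
*apparent saturation capacitance* C_R\*, the capacitance the same root
system would show in fully water-saturated soil.

## Calibration model

For one pot-grown plant measured repeatedly while the soil is wetted up
from near wilting point to saturation, the relative capacitance is

$$C_{rel}(\theta_{rel}) = \frac{C_R(\theta_{rel})}{C_R(1)} = a\,e^{b\,\theta_{rel}},$$

where the plant's own saturated reading C_R(1) removes its size. All
fitting happens on the natural-log scale, where the model is exactly
linear: `fit_plant()` is OLS of log C_rel on θ_rel, and `fit_species()`
pools plants either by a precision-weighted mean of per-plant coefficients
(the classical two-stage estimate of a random-intercept model; the default)
or by a full REML linear mixed-effects fit (`nlme::lme`) with a per-plant
random intercept. After C_rel normalisation the between-plant intercept
variance is small by construction, so the two routes agree closely; the
two-stage route is the default because it is exactly reproducible by a
hand calculation and is what the unit tests check against a brute-force
least-squares oracle.

One structural consequence of self-normalisation is worth stating plainly:
because every plant's series passes through (θ_rel = 1, C_rel = 1) exactly,
the effective generating intercept is $a = e^{-b}$ — the fitted $a$ and $b$
are not free of each other, and $a\,e^{b}\approx 1$ always holds (the
package enforces agreement within 5% as a sanity invariant). The shipped
species presets are maize $a = 0.130$, $b = 2.028$ and soybean $a = 0.244$,
$b = 1.392$.

## Inversion and its constants

Solving the calibration for the saturated capacitance gives the
normalisation applied to every field reading:

$$C_R^* = C_R \cdot k\, e^{-b\,\theta_{rel}}, \qquad k = 1/a.$$

The presets ship in two variants, because the published soybean inversion
constant (4.107) was evidently derived from an unrounded intercept and is
not exactly $1/0.244 = 4.098$:

* `source = "printed"` — the constants exactly as published
  (maize $k = 7.692$; soybean $k = 4.107$), used when reproducing published
  day-mean values;
* `source = "derived"` — $k = 1/a$ at machine precision, used when internal
  consistency matters (e.g. the round-trip identity
  `apparent_capacitance(c_star * a * exp(b*θ), θ) == c_star`).

The choice is an explicit argument everywhere; nothing selects a constants
source silently.

**Jensen gap.** Day means of C_R\* should be means of per-reading
transforms. When only day-level summary means survive (as for the reference
campaigns), applying the inversion to the day means incurs a Jensen error
from the exponential. At the campaign noise levels (θ_rel CV ≤ ~12.5%, C_R
CV ≤ ~26%, with the two dependent through the moisture response) the
relative gap stays below 2% — `jensen_gap()` computes it, and the test
suite verifies the bound across simulated campaigns. This is what makes
day-mean reproduction a valid check at the 0.5% tolerance used for the
worked conversions.

## Field statistics

The field stage mirrors standard agronomic practice:

* **Poolability** (`check_poolability`): one-way ANOVA across the three
  replicate row-segments/plots; pooling to n = 48/day is recommended iff
  p ≥ 0.05.
* **Two-sample comparisons** (`compare_consecutive`,
  `compare_treatments`): an F-test on the variances at α = 0.05 routes to
  Student's t (variances compatible) or Welch's t. The pre-test α is a
  package choice (the convention leaves it unstated); 0.05 is used for
  uniformity.
* **Multi-group comparisons** (`compare_groups`): Bartlett's pre-test
  routes to one-way ANOVA with the Tukey–Kramer post-test (group sizes
  differ between interim and final harvests, 18 vs 30) or Kruskal–Wallis
  with Dunn's post-test. Dunn's pairwise p-values are Bonferroni-adjusted —
  the most common convention where none is prescribed. Dunn's statistic is
  implemented in-package (rank-sum z with tie correction) since no
  installed dependency provides it.
* **Stars**: strict thresholds (`***` p < 0.001, `**` p < 0.01, `*`
  p < 0.05, otherwise NS; p = 0.05 exactly is NS).
* No multiplicity correction is applied across the nine consecutive-day
  comparisons of a season — they are reported as raw per-pair tests, which
  is a documented limitation, not an oversight.
* **Age/species screen** (`test_age_species_effects`): an ML mixed model of
  log C_rel on θ_rel × age × species with per-plant random intercepts.
  Besides the per-term marginal F table, the decision-relevant output is a
  *joint* likelihood-ratio test per factor (all age terms at once, all
  species terms at once): with four separate age terms each tested at
  α = 0.05, the family-wise false-positive rate would approach 20%, so the
  per-term table alone would wrongly "find" age effects in a fifth of
  calibrations.

## Synthetic data: what it emulates, and what it does not

`sim_config()` fixes the study conditions; the generators are deterministic
given a seed.

| Parameter | Default | Why |
|---|---|---|
| `n_plants` | 15/species | pot experiment size |
| `theta_grid` | 10 levels, 0.20 → 1 | wetting-up protocol from near wilting point to saturation |
| `sigma_ln` | 0.10 | lognormal measurement noise on ln C_R, sized to the published per-plant ln-scale fit quality |
| `rdm_range` | 0.37–11.10 g (maize), 0.32–6.21 g (soybean) | harvested root-mass ranges |
| `mass_noise` | 0.19 | gives mass-calibration R² centred near 0.85 |
| `field_days` | reference campaign table | empirical seasonal C_R\* template (lookup, not a parametric curve — the seasonal shape is an observation, not a model) |
| `n_per_day` | 48 (3 groups × 16) | field sampling design |
| `sigma_plant` | 0.10 | between-plant size spread, matching day-level C_R\* CVs of ~10–15% |
| `treatment_uplift` | +5% in days 50–90 | mid-season AMF effect of the size seen at the 4-node/early-flowering stages |
| `soil_sigma` | 0.125 | reproduces the soil power law's ln-scale R² ≈ 0.93 |

The measurement-noise model (multiplicative lognormal) is a package choice
consistent with ln-scale fitting; no noise model is prescribed by the
underlying protocol. The saturated pot reading receives noise like any
other reading and then *defines* the plant's normalizer, exactly as in the
real protocol — which is why recovery tests compare the fitted intercept to
$e^{-b}$ rather than to the nominal generating $a$.

Features of real campaigns the generator deliberately does not emulate:

* within-day correlation between plant size and local moisture (bigger
  plants dry their soil faster); plant size and θ are drawn independently.
  One visible consequence: within-day C_R–θ_rel regressions on synthetic
  dry days (small θ spread) have lower R² than real campaigns show;
* weather-driven moisture dynamics — day means are inputs, not simulated;
* soil-type effects on the calibration (a single soil is assumed
  throughout);
* any mechanistic root growth; the seasonal profile is a lookup table.

Passing tests therefore demonstrate that the *pipeline* recovers what the
generator encodes under realistic noise — not that the calibration
transfers to other soils or species.

## Numerical choices and degenerate inputs

* All exponential/power fits are exact linearisations on the log scale; no
  nonlinear optimisation, hence no initialisation or convergence concerns.
* Fit statistics (R², slope p) are computed directly from the QR
  decomposition, so noise-free (perfect-fit) inputs are handled without
  special-casing.
* θ_rel readings marginally above 1 (≤ 1.02, instrument noise at
  saturation) are clamped to 1 with a warning at ingest; larger values are
  errors. θ_rel is a physical ceiling: `apparent_capacitance()` refuses
  θ_rel > 1 rather than extrapolate.
* Truncated-normal θ sampling uses rejection, keeping draws in (0, 1].
* Degenerate inputs fail loudly: fewer than 3 distinct θ levels, zero
  variance in a regressor, mixed species in one pooled fit, or a missing
  saturated reading are all errors, not silent NAs.
* Reported constants are rounded to 3 decimals only at presentation; full
  precision is kept internally (`inversion_constants(cal, digits = 3)`).

## Problem sizes

The test suite and the acceptance script run the pot recovery at 15 plants
× 10 θ levels × 20 seeded replicates per species, the soil recovery at
n = 300 × 20 replicates, the poolability type-I check at 1000 null
campaigns, and the age/species pattern at 100 seeded two-species
calibrations — sizes at which the stochastic checks have comfortable
binomial margins while the whole suite completes in well under a minute of
compute per module.

## Known limitations

* The calibration is species- and soil-specific; constants from this
  chernozem do not transfer elsewhere without re-calibration.
* C_R\* is a relative indicator: it does not convert to absolute absorbing
  root surface area or water-uptake volume.
* The soil-dominance precondition (soil capacitance ≫ root capacitance)
  weakens for the very largest maize root systems, where the ratio
  approaches ~8× rather than a full order of magnitude; the package checks
  it as a per-reading diagnostic rather than assuming it.
* Day-mean reproduction via the Jensen bound is only valid at the observed
  noise levels; campaigns with θ_rel CVs far above ~13% would need raw
  per-plant readings.
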