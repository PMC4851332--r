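---
title: "Demographic inference from summed radiocarbon date densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference from summed radiocarbon date densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdtools)
```

## The proxy and its model

Radiocarbon dates accumulate where people lived: under the core assumption
"more people = more sites = more dates", the density of `^14^C`
determinations over calendar time is a *relative* proxy for population
size. spdtools implements the full inferential chain for that proxy.

A determination is a conventional radiocarbon age (CRA) $x \pm e$ in
`^14^C` years BP. Because atmospheric `^14^C` varied, a calibration curve
$\mu(t) \pm \sigma_c(t)$ maps calendar years $t$ (cal BP, before AD 1950)
to `^14^C` years. `calibrate()` converts a CRA into a probability mass
function over an annual calendar grid by direct numerical integration,

$$p(t) \propto \phi\!\left(x;\ \mu(t),\ \sqrt{e^2 + \sigma_c(t)^2}\right),$$

normalised to sum to one over the grid. Masses are per *calendar year*
(the axis every later statistic lives on), not per `^14^C` year. On a toy
identity curve ($\mu(t) = t$, $\sigma_c = 0$) this reduces to a Gaussian
centred on the CRA, which gives the test-suite a closed form to check
against; real curves (e.g. IntCal13, read with `read_calcurve()`) produce
the familiar multimodal densities and plateaux.

The summed probability distribution (SPD) is the year-wise sum of the
calibrated densities, after one bias correction: dates are grouped into
**bins** — per-site clusters of CRAs within a 200 `^14^C`-year
complete-linkage cut (`make_bins()`) — and each bin contributes the
arithmetic *mean* of its members' densities (`bin_density()`). Binning
curbs "wealth bias": a heavily funded excavation that dated one occupation
forty times should not count forty times. The bin, not the date, is the
exchangeable unit of every test below.

An SPD is never interpreted visually alone. Calibration wiggles, sampling
error and taphonomic loss all generate peaks and troughs that are
indistinguishable by eye from demographic signal, so each apparent feature
is assessed against an explicit null.

## The Monte-Carlo null-model test

`model_test()` asks whether an observed SPD deviates from a fitted null
density more than simulation can explain:

1. Fit the null to the observed SPD (`fit_null()`): *uniform* (constant
   over the analysis range) or *exponential*, a proxy for both
   time-increasing taphonomic loss and long-term background growth.
2. Draw as many calendar years as there are observed **bins** from the
   null density, back-calibrate each into a simulated CRA
   (`sample_cra()`: Normal with variance $\sigma_c(t)^2 + e^2$, lab error
   resampled from the observed errors), re-calibrate, and sum — each
   simulated date its own bin. Repeat `nsim` times.
3. Standardise every curve by the per-year mean and standard deviation of
   the *ensemble* of observed plus simulated curves ("local z-scores"),
   which removes the null's trend and the wiggle structure all curves
   share.
4. The 95% envelope is the per-year 2.5th/97.5th percentile of the
   ensemble's z-scores. Observed excursions outside it are the
   significant local deviations; the global statistic is the total area
   outside the envelope, and its Monte-Carlo p-value is
   $(1 + \#\{\text{sim} \ge \text{obs}\})/(n_{\text{sim}} + 1)$ — the
   add-one estimator that can never report an impossible zero.

The observed curve is deliberately part of the reference ensemble. Under
the null it is exchangeable with the simulations, so scoring every curve
against the same ensemble makes the rank-based p-value exact (slightly
conservative) at *any* number of simulations. Excluding the observed
curve instead — scoring each simulation against an envelope that contains
itself while the observed curve is an outsider — biases simulated
statistics downward and measurably inflates the type-I error when
`nsim` is small (we measured an 11% rejection rate at a nominal 5% with
`nsim = 200`; at `nsim = 10{,}000` the two constructions are practically
indistinguishable). The permutation test applies the same principle.

Simulating *bins* rather than raw dates matters: simulating the raw date
count would re-inflate exactly the wealth bias the binning removed.

## The bin-label permutation test

`perm_test()` is a non-parametric comparison of two or more regional date
sets, with the null hypothesis that all sets' dates were drawn from
identically *shaped* calendar densities. The assignment of whole bins to
sets is randomly permuted (per-set bin counts kept exactly equal to the
observed ones), each set's SPD is rebuilt, and envelopes, local z-scores,
the area statistic and per-set p-values are computed exactly as above,
with the permutation distribution playing the role of the simulated null.
Because each set is standardised by its own permutation distribution, the
comparison is of SPD *shape*, so differences in research intensity
(sample size) between regions do not masquerade as demographic
divergence. A significant negative deviation says the focal set's decline
was stronger than the aggregate's at those years — not that its absolute
population was lower.

Two properties follow from the construction and are asserted by the test
suite: the aggregate SPD is invariant under every permutation, and with
exactly two sets the test is symmetric — both sets share one global
statistic and p-value, and their significant intervals mirror in sign.
Asymmetric pairwise comparisons only arise with three or more sets in one
run, where each focal set is compared against the pooled aggregate.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `h` | 200 `^14^C` yr | complete-linkage cut height for site binning |
| `range` | 7000–3000 cal BP | analysis window of every SPD and test |
| `nsim` | 10,000 | Monte-Carlo simulations / label permutations |
| `eps` | `1e-5` | calibration floor, fraction of the per-date peak |
| `delta13c_max` | −24 ‰ | strict upper bound on measured δ¹³C |
| `cra_window` | 7500–2500 `^14^C` BP | inclusive admission window for CRAs |
| `window` (rolling mean) | 200 yr | display smoothing; statistics use raw SPDs |

The date filters (`filter_criteria()`) encode the standard hygiene for
this proxy: AMS-only determinations, no marine material, and exclusion of
measured δ¹³C above −24‰ (possible marine-reservoir influence; a stricter
−26‰ variant is one argument away). A *missing* δ¹³C measurement is not
grounds for exclusion — absence of a measurement is not evidence of marine
carbon. The CRA admission window is deliberately wider than the analysis
range so that dates whose calibrated mass straddles the range edges still
contribute; mass outside the range is retained by the calibration but
excluded from all statistics.

## Numerical choices

* **Grids.** All densities live on annual grids stored in decreasing cal
  BP (the IntCal file convention). Curves are linearly interpolated to
  annual resolution in both $\mu$ and $\sigma_c$ — interpolation is exact
  at knots and bounded by bracketing knots.
* **Calibration support.** The normal integrand is evaluated only where
  $|\mu(t) - x| \le 8\sqrt{e^2+\sigma_{c,\max}^2}$ (located through a
  sorted-$\mu$ index); beyond that the integrand is below $e^{-32}$ of the
  peak, far under the `eps` floor. After flooring, the support is trimmed
  to the smallest contiguous window holding all non-zero mass. Repeated
  (CRA, error) pairs — ubiquitous in back-calibration loops — are
  calibrated once and cached per curve.
* **Binning determinism.** Complete linkage on one-dimensional CRAs is
  implemented directly (sorted clusters are contiguous, so the minimal
  complete-linkage distance is always between adjacent clusters). Ties at
  equal merge height resolve toward the pair with the smaller lowest CRA,
  which makes bin counts reproducible across platforms and independent of
  row order — a guarantee `stats::hclust` does not make under tied integer
  CRAs, which is why the package carries its own twenty-line
  agglomeration and uses `hclust` only as an independent cross-check in
  the tests.
* **Exponential fit.** The null rate is estimated by ordinary least
  squares of $\log(\text{SPD})$ on the calendar year, restricted to years
  with positive density — deterministic, exact on noise-free exponential
  input, and adequate for a smooth one-parameter null. Zero-density years
  are excluded rather than floored: a floored $\log(0+\delta) \approx
  -744$ would dominate the regression whenever the SPD has exact zeros
  near the range edges and drive the fitted rate to nonsense. An
  iteratively re-weighted fit was considered and rejected: the null only
  needs the trend, and determinism simplifies reproducibility. The fitted
  density $\propto e^{bt}$ is strictly positive over the whole range
  either way.
* **Degenerate years.** Years where the simulation (or permutation)
  standard deviation is zero contribute nothing to any statistic and are
  flagged in the result. In the permutation test the observed arrangement
  is included in the standardising distribution and the envelope, which
  guarantees a non-zero deviation wherever any arrangement puts mass and
  keeps the rank p-value exact.
* **Simulated CRAs** are rounded to integer `^14^C` years, matching the
  reporting convention of real determinations; the effect is far below
  any lab error.

## The synthetic-data generator

`demographic_curve()` + `simulate_dates()` generate date tables with
*known* demographic structure: calendar years drawn from a uniform,
exponential, rise–fall tent, step or custom density; back-calibrated
through any curve; lab errors resampled from a pool (default
{20, 25, 30, 40, 50} `^14^C` yr, typical AMS magnitudes); dates spread
over sites either multinomially or round-robin. `two_region_scenario()`
plants a localised divergence — a window whose density is scaled by a
multiplier in one region only — which is the package's power fixture: a
multiplier of 1 is the exchangeable null case, 0 carves a gap, 2 plants a
boom.

The generator emulates the mechanism the tests assume (dates drawn from a
calendar density and pushed through the measurement model). It does *not*
emulate several features of real archives: spatially heterogeneous
taphonomic loss, research-intensity fashions that concentrate dating
effort on particular periods, site-to-population ratio shifts from
changing mobility patterns, or reservoir-affected materials escaping the
δ¹³C screen. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under its own assumptions — not that
those assumptions hold for any particular archaeological record.

## Problem sizes and what the checks show

The package's self-checks run on a toy identity curve with study-scale
conditions: analysis range 7000–3000 cal BP, curves spanning 8000–2000
cal BP (the buffer mirrors the wider CRA admission window). Calibration
is verified against an independent brute-force integration on a 0.2-yr
grid (medians within ±1 yr); binning against exhaustive naive
agglomeration on all site tables of up to 7 dates. Type-I error of both
tests is measured at α = 0.05 over 200 replicates of 100 bins with 200
simulations each, and must land inside the 95% binomial interval around
0.05. Power is measured on the two-region scenario with a 500-year,
multiplier-0 gap and 400 dates per region: the permutation test must flag
a negative interval overlapping the gap in at least 80% of 50 replicates.
A known exponential growth rate of 0.001 per cal BP year must be
recovered within 20% from 1,000 dates. `scripts/acceptance.R` recomputes
all of these from scratch.

Two checks reproduce published counts and significance levels for the
eastern-Japan (Jomon) compilation those defaults were designed around;
they require the archived date table (zenodo doi:10.5281/zenodo.47339)
and an IntCal13 curve file, which cannot be redistributed here and are
expected as user-supplied files under `inst/extdata/` (see
`tests/testthat/test-acceptance.R` for the paths).

## Known limitations

* The SPD is a relative proxy; nothing here estimates absolute population
  size.
* Marine calibration curves, reservoir offsets (ΔR), post-bomb curves and
  Bayesian sequence modelling are out of scope.
* Short demographic events (≲ 100–200 yr) are generally undetectable:
  calibration spreads their signal below the wiggle noise floor.
* The exponential null absorbs *uniform* taphonomic loss; spatially
  divergent loss between regions would still masquerade as divergence.
* Permutation p-values are bounded below by $1/(n_{\text{sim}}+1)$;
  global shape tests can stay non-significant even when real local
  deviations exist, if the sets agree over most of the range.
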