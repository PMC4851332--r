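# spdtools

Demographic inference from densities of radiocarbon dates, for
archaeologists and palaeodemographers who use the summed probability
distribution (SPD) of calibrated ¹⁴C dates as a relative population
proxy — and who want statistical significance, not visual impressions.

## What it does

Under the proxy assumption *more people → more sites → more dates*, the
calendar-time density of ¹⁴C determinations tracks relative population
size. spdtools implements the full chain:

* **Calibration** by direct numerical integration: a conventional
  radiocarbon age (CRA) x ± e becomes a probability mass function over an
  annual cal BP grid, p(t) ∝ φ(x; μ(t), √(e² + σ_c(t)²)), where
  μ(t) ± σ_c(t) is the calibration curve (IntCal plain-text dialect
  supported; toy curves included for testing).
* **Screening and binning**: AMS-only / marine / δ¹³C / CRA-window
  filters, then per-site complete-linkage clustering of CRAs cut at
  h = 200 ¹⁴C yr. Each resulting *bin* contributes the pooled mean of its
  members' densities to the SPD, so intensively dated sites do not
  dominate ("wealth bias").
* **Monte-Carlo null-model test** (`model_test`): the observed SPD is
  compared against a fitted uniform or exponential null. Random calendar
  years are drawn from the null, "back-calibrated" into simulated CRAs,
  re-calibrated and summed, nsim times; observed and simulated SPDs are
  standardised to per-year z-scores; excursions outside the simulated 95%
  envelope are significant local deviations, and the total area outside
  the envelope gives a global Monte-Carlo p-value
  (1 + #{sim ≥ obs})/(nsim + 1).
* **Bin-label permutation test** (`perm_test`): a non-parametric
  comparison of two or more regional date sets. Bin-to-set labels are
  permuted (per-set bin counts preserved), per-set envelopes and z-scores
  are rebuilt from the permutation distribution, and each set gets local
  divergence intervals plus a global p-value. The comparison is of SPD
  *shape*, so unequal research intensity between regions does not fake a
  demographic divergence.
* **Synthetic data** (`simulate_dates`, `two_region_scenario`): date
  tables generated from known demographic curves (uniform, exponential,
  rise–fall, step, custom) through the same measurement model, for power
  studies and self-tests.
* **Pipeline + CLI** (`run_pipeline`, `exec/spdtool`): YAML-configured,
  seeded end-to-end runs writing CSV/JSON artifacts and a manifest.

## Worked example

```r
library(spdtools)

tc <- toy_identity_curve(8000, 2000, sigma = 5)   # mu(t) = t toy curve
calibrate(4500, 30, tc)
#> Calibrated density: 4645-4355 cal BP (291 yr support), median 4500 cal BP,
#>   95% range 4560-4440

# two regions sharing a rise-fall history, except a total collapse of
# region B between 5500 and 5000 cal BP
shared <- demographic_curve("rise_fall", c(7000, 3000))
sc  <- two_region_scenario(shared, window = c(5500, 5000), multiplier = 0,
                           n_per_region = 400, calcurve = tc, seed = 42)
res <- perm_test(bind_dates(sc$A, sc$B), tc, nsim = 1000, seed = 42)
res
#> Bin-label permutation test: 2 sets, 7000-3000 cal BP, nsim = 1000
#>   A: 188 bins (400 dates), global stat = 547.366, p = 0.000999
#>   B: 173 bins (400 dates), global stat = 547.366, p = 0.000999
res$sets$B$neg_intervals
#>   start  end
#> 1  5470 5038
```

The permutation test flags the planted 5500–5000 cal BP gap as a
significant negative divergence of region B (5470–5038 cal BP) at the
smallest p-value nsim = 1000 can resolve. With two sets the test is
symmetric by construction: both sets share the global statistic, and A's
positive intervals mirror B's negative ones.

```r
model_test(sc$A, tc, kind = "exponential", nsim = 1000, seed = 42)
#> Monte-Carlo exponential null-model test: 188 bins (400 dates), 7000-3000 cal BP
#>   nsim = 1000, global statistic = 198.278, p-value = 0.02697
#>   positive deviations (cal BP): 5124-5078, 4858-4845
#>   negative deviations (cal BP): 7000-6856, 6852-6851, 3398-3254, 3190-3000
```

Region A's rise-and-fall is itself significant against an exponential
null: positive deviations around its 5100–4850 cal BP peak, negative ones
at the range edges where the tent density vanishes.

## Layout

```
R/                 calcurve, dates_io, calibrate, spd, model_test,
                   perm_test, synthetic, pipeline, plot
exec/spdtool       command-line front-end
scripts/acceptance.R
tests/testthat/    unit, property and acceptance suites
vignettes/spd-inference.Rmd   methods and modelling choices
```
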