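# vwmtrain

Analysis toolkit for visual working memory (WM) training studies that
separate the **quantity** of WM representations (how many items are held)
from their **quality** (how precisely each is held). It is aimed at
researchers running pre/post continuous-reproduction and change-detection
designs who want the full inference pipeline — mixture-model fitting, robust
tests, Bayes factors, exclusions — as tested, scriptable code, plus a
trial-level simulator to power-check a design before collecting data.

## The models

**Standard mixture model (SMM).** A continuous-reproduction trial yields a
signed recall error *x* ∈ (−π, π] (response − target). Errors are modelled
as a two-component mixture of a von Mises distribution centred on the
target and a circular uniform:

    P(x) = (1 − g) · exp(κ·cos x) / (2π·I₀(κ)) + g / 2π

where *g* is the guess probability, κ the von Mises concentration, and
I₀ the modified Bessel function of order 0. Derived measures:

* probability in memory `Pm = 1 − g`;
* **capacity** `K = Pm × N` for set size *N* (quantity, in items);
* **precision** `SD⁻¹` with `SD = sqrt(−2 ln(I₁(κ)/I₀(κ)))` in degrees
  (quality; typical values 0.04–0.10 deg⁻¹).

Parameters are estimated per participant × phase × set-size cell by
maximum likelihood (bounded quasi-Newton from 8 deterministic starts).

**Pashler's k** for whole-display change detection:
`k = (H − FA)/(1 − FA) × N` from hit and false-alarm rates.

**Inference layer.** Yuen trimmed-mean t-tests (20% trimming; paired df =
h − 1), Algina–Keselman–Penfield robust effect sizes δ_t, Yates-corrected
2×2 chi-square, two-way mixed and fully repeated-measures ANOVAs with
generalized and partial eta squared, JZS t-test Bayes factors (Cauchy
r = 0.707), Gunel–Dickey contingency-table Bayes factors (Poisson
sampling, a = 1), and loudly-labelled BIC approximations for ANOVA-effect
Bayes factors.

## Worked example

```r
library(vwmtrain)
set.seed(1)

# 120 recall errors from a typical set-size-4 pre-test cell:
# 35% guesses, memory precision SD = 16 degrees
err <- simulate_errors(120, g = 0.35, kappa = sd_to_kappa(16))
fit <- fit_smm(err, set_size = 4)
print(fit)
#> Standard mixture model fit (120 trials)
#>   g = 0.252  (Pm = 0.748)
#>   kappa = 12.12  (SD = 16.8 deg, precision = 0.0595)
#>   capacity K = 2.99 of set size 4
#>   logLik = -116.05, converged = TRUE
```

The fit says: on ~75% of trials the probed item was in memory (capacity
≈ 3 of 4 items), and remembered items were reproduced with a circular SD
of ~17°, i.e. precision ≈ 0.06 deg⁻¹. (At n = 120 trials per cell,
single-cell estimates scatter around the generating values; group-level
analyses average over participants.)

Comparing a demographic composition across two groups (counts
female/male 8/22 vs 17/17):

```r
tab <- matrix(c(8, 17, 22, 17), 2, 2)
chi2_2x2(tab)
#> chi2_yates: statistic = 2.7309, df = 1, p = 0.09842
gd_contingency_bf(tab)
#> BF10 = 3.4  [gunel_dickey_poisson]  (substantial)
```

End-to-end on a synthetic study (experimental group improves only in
precision after training):

```r
cfg    <- study_sim_config(scenario = "quality_gain", seed = 42)
trials <- simulate_study(cfg)
report <- run_full_analysis(trials)
report$prepost_anova   # Time/Group/Time x Group per measure, eta^2, BFs
write_report(report, "report_dir")
```

## Command line

```sh
exec/vwmtrain simulate --config cfg.json --out trials.csv --seed 7
exec/vwmtrain fit      --trials trials.csv --out cells.csv
exec/vwmtrain analyze  --trials trials.csv --report out_dir
```

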