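---
title: "Methods: mixture-model analysis of visual WM training studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture-model analysis of visual WM training studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and problem

`vwmtrain` implements the computational core of a pre/post, two-group
visual working-memory (WM) training analysis. The scientific question it
serves is whether training improves the *quantity* of representations held
in visual WM (capacity) or their *quality* (precision), which dissociate
in continuous-reproduction data. The package provides the measurement
models, the robust frequentist and Bayesian inference layer, a trial-level
simulator stating the assumed data-generating world, and a pipeline that
runs the whole analysis graph on any trial table with the canonical
schema.

## Measurement models

### Standard mixture model

A continuous-reproduction trial yields a signed error
$x \in (-\pi, \pi]$. The standard mixture model treats each trial as
either a memory-based response (von Mises around the target, concentration
$\kappa$) or a random guess (circular uniform), with guess probability
$g$:

$$P(x) = (1-g)\,\frac{e^{\kappa\cos x}}{2\pi I_0(\kappa)} + \frac{g}{2\pi}.$$

Derived measures: $P_m = 1-g$, capacity $K = P_m \times N$ (bounded by the
set size $N$), and precision $SD^{-1}$ where
$SD = \sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}$.

**Units.** Internally all angles are radians; every user-facing quantity
is degrees. Precision is $1/SD$ **with $SD$ in degrees**: human data in
this paradigm give $SD \approx 11$–$21^\circ$, hence precision
$\approx 0.05$–$0.09\ \mathrm{deg}^{-1}$. Using radians would put
precision at 3–5 and silently change every downstream effect size, so the
unit is fixed and documented in all outputs.

### Fitting

Estimation is maximum likelihood, per participant × phase × set-size cell
(never pooled across participants — group tables are means of individual
estimates). The optimiser is L-BFGS-B in $(\mathrm{logit}\,g, \log\kappa)$
space with analytic gradients, bounds $g \in [10^{-6}, 1-10^{-6}]$,
$\kappa \in [10^{-3}, 500]$, started from the fixed lattice
$g \in \{.1,.5,.9\} \times \kappa \in \{2,8,32\}$ with the centre point
removed (8 starts). The multi-start matters because the likelihood has a
ridge along which high $g$ trades off against low $\kappa$; the lattice
brackets that ridge from both sides. The procedure is deterministic — no
RNG is consumed — so "deterministic given seed" holds trivially.

Cells with fewer than `min_trials = 30` usable trials raise an
insufficient-data error (the pipeline flags such cells rather than
fitting them); degenerate samples that push an estimate to a bound are
returned with `boundary = TRUE` and a warning. Estimation is ML rather
than MAP; a MAP variant with toolbox-style priors would slot into
`fit_smm()` as an alternative objective but is deliberately out of scope.

At the design's cell size ($n = 120$ trials) the estimator's bias envelope,
measured by simulation in the test suite, is $|E[\hat g] - g| < 0.05$ and
$|E[\hat\kappa]/\kappa - 1| < 15\%$ over $g \in [0.2, 0.4]$,
$\kappa \in [6, 12]$.

### Change detection

Whole-display change detection is summarised by Pashler's
$k = \frac{H - FA}{1 - FA} N$. The headline value is clamped to $[0, N]$
(the estimator's meaningful range) with the raw value retained. No
correction for $H = 1$ or $FA = 0$ is applied by default; a $1/(2n)$
log-linear adjustment is available behind a flag, favouring transparency
over silent correction. The generative counterpart in the simulator
places the changed item in memory with probability $k/N$ and otherwise
guesses "change" at rate $u$ (default 0.5, a free parameter of the
stated world); under this model the estimator is unbiased for any $u$,
which the test suite verifies.

## Inference layer

**Trimmed-mean tests.** Group comparisons use Yuen's t-test with 20%
trimming, the convention under which the paired test at $n = 30$ has
$df = 17$ and at $n = 34$ has $df = 21$ (df $= h - 1$,
$h = n - 2\lfloor 0.2n \rfloor$; a trimmed one-sample test on difference
scores would give the identical df, the paired variant is implemented).
At `tr = 0` the independent test reduces exactly to Welch's t-test,
which the tests exploit as an oracle. Effect sizes are
Algina–Keselman–Penfield $\delta_t = c(tr)\,(\bar X_{t1} - \bar X_{t2}) /
s_{w,\mathrm{pooled}}$, where $c(tr)$ is the winsorized SD of a standard
normal (0.642 at 20%), computed in closed form so other trim levels stay
on the Cohen's-d scale.

**Chi-square.** The 2×2 test uses the Yates correction with the
correction term clamped at zero, $\max(|O-E|-0.5, 0)$, so perfectly
proportional tables give exactly 0. On the demographic counts 8/22 vs
17/17 this yields 2.73, $p = .098$.

**ANOVAs.** The two-way mixed ANOVA (between: group; within: time) uses
the classical univariate decomposition with weighted (cell-size) means;
with one between factor and a balanced within factor the decomposition is
orthogonal, sums of squares are additive, and with 64 participants in two
groups and two time points every effect has $df = (1, 62)$. The
fully-within two-factor ANOVA tests each effect against its own
subject-interaction error term; dfs at $n = 30$ with 4×3 levels are
$(3,87)$, $(2,58)$, $(6,174)$. No sphericity correction is applied: the
two-level within factor needs none, and multi-level dfs are reported
uncorrected by design. Both effect-size conventions are reported:
$\eta^2_p = SS_e/(SS_e + SS_{err(e)})$ and, treating all factors as
manipulated, $\eta^2_G = SS_e/(SS_e + \sum SS_{\text{all error terms}})$,
so $\eta^2_p \ge \eta^2_G$ always.

**Bayes factors.** The t-test BF is the JZS default: a Cauchy
($r = 0.707$) prior on the standardized effect, integrated against the
noncentral-t likelihood by adaptive quadrature (relative tolerance
$10^{-9}$; the reported `error_pct` comes from the quadrature bound). The
contingency BF is the Gunel–Dickey default with prior concentration
$a = 1$; the Poisson sampling plan is the package default, with the
independent-multinomial (fixed row margins) plan also available. Under
the Poisson plan the alternative places independent Gamma$(a, b)$ priors
on the $I \times J$ cell rates with $b = IJa/n$; the compatible null
priors are Gamma$(IJa - (I-1)(J-1), b)$ on the total rate and
shifted-Dirichlet (concentration $Ja-(J-1)$, resp. $Ia-(I-1)$) priors on
the margins. The closed form is exact; the tests additionally verify it
against direct numerical integration of these marginal likelihoods.

**ANOVA Bayes factors are approximations.** Exact default ANOVA BFs
require integration over multivariate Cauchy g-priors; instead the
pipeline reports $BF_{10} = \exp((BIC_0 - BIC_1)/2)$ computed within each
effect's error stratum ($\Delta BIC = n\ln(SSE_{red}/SSE_{full}) +
df_1 \ln n$, $n = df_1 + df_2 + 1$). Every such value is tagged
`bic_approx` and must not be compared against Cauchy-prior ANOVA BFs;
they indicate direction and order of magnitude only.

**Evidence labels** follow the conventional bands (ambiguous to decisive),
applied symmetrically to $BF_{10}$ and $1/BF_{10}$, with half-open
intervals (the upper edge belongs to the lower band) so every positive
value maps to exactly one label.

## The synthetic world

`study_sim_config()` states the emulated design: experimental $n = 30$
and control $n = 34$ (the sizes after exclusions in the kind of study
this targets), pre/post sessions with 120 test trials per task at set
size 4 (16 for search) plus 20 flagged practice trials, and four training
sessions of 360 trials, 120 per set size (2/4/6 reproduction for the
experimental group, 8/16/24 search for the control group).

Default generating parameters were chosen once to be realistic for
healthy young adults and are not tuned: reproduction at set size 4 uses
$g = 0.39$, $SD = 16.7^\circ$ (capacity $\approx 2.4$, precision
$\approx 0.06$); shape reproduction is slightly harder ($g = 0.44$,
$SD = 21^\circ$); training cells follow the set-size effect
($g = .06/.30/.48$, $SD = 11.8/15.4/16.7^\circ$ at set sizes 2/4/6);
change detection uses true $k = 2$ of 4 with guess rate 0.5; search
accuracy/RT decline with set size (0.92/0.85/0.75; 2000/2800/3150 ms)
with 2% omissions and a 5 s response deadline. The `"quality_gain"`
scenario multiplies only the experimental group's post-test reproduction
SD by 0.8, leaving every guess rate untouched: a pure quality
improvement with no quantity change, the pattern the pipeline should
(and, per the acceptance tests, does in >80% of 200 replicates) detect as
a Time × Group interaction for precision but not for capacity.

What the simulator does *not* emulate — and hence what a green test does
not establish: swap/misbinding errors and variable precision (errors are
exactly SMM-distributed, so the model is correctly specified by
construction); response-time structure in reproduction tasks; within-
session learning or fatigue; item-level stimulus effects (canonical-
orientation attraction); drop-out and attrition. Conclusions about model
misspecification on real data need real data.

## Pipeline and numerical choices

- **Exclusions** (per participant): more than 10% extra logged trials in
  any task ("exceeded" read strictly: 13 extra on a 120-trial task
  excludes, exactly 12 retains); more than 20% of responses faster than
  200 ms; more than 20% omissions. The RT/omission thresholds are stated
  defaults of this package, exposed in `analysis_config()`, not asserted
  facts about any particular study's pre-registration.
- **Density comparison**: responses are binned into 8 bins of 45°
  anchored at 0° and compared across groups by a Pearson chi-square of
  homogeneity ($df = 7$). The anchor is configurable for a substantive
  reason: peaks at the oblique orientations 45°/135°/225°/315° fall
  exactly on 0°-anchored bin edges and split evenly between neighbouring
  bins, making the 8-bin test blind to them; an anchor of 22.5° centres
  the bins on those peaks. The pipeline default runs the
  groups-at-each-timepoint comparison; the operation itself is
  direction-agnostic (any two response pools).
- **Bessel evaluation**: exponentially-scaled `besselI` throughout, with
  the large-$\kappa$ asymptotic series for the mean resultant length
  above $\kappa = 10^5$ where the scaled Bessel underflows.
  `sd_to_kappa()` inverts the SD conversion by monotone root bracketing
  in $\log\kappa$ (round-trip error $< 10^{-6}$ degrees over
  1°–120°).
- **Ties and degenerate input**: identical paired samples return
  $t = 0, p = 1$; zero winsorized variance raises a diagnostic error;
  all-identical reproduction errors produce a boundary-flagged fit.
- **Determinism**: identical trials + config give byte-identical reports
  (no timestamps in the JSON); the only RNG in the package is in the
  simulator, controlled by the config seed.

## Known limitations

- The SMM ignores swap errors; on real data with misbinding, $g$ absorbs
  swaps and capacity is underestimated.
- BIC-approximate ANOVA BFs are not default Bayes factors (see above).
- The mixed ANOVA handles one between and one within factor, the
  repeated-measures ANOVA exactly two within factors — the shapes this
  design needs, not a general ANOVA engine.
- Yuen's test relies on a t approximation; its null p-values are
  uniform to KS precision at the design's sample sizes (verified in the
  suite) but small-sample behaviour below $n \approx 15$ is untested.
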