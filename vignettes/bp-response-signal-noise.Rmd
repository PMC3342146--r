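---
title: "Signal, noise, and power for blood-pressure response phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal, noise, and power for blood-pressure response phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpsignal)
```

## The measurement model

A hypertensive subject treated with a single antihypertensive drug has one
true blood-pressure response — the decline in BP attributable to therapy.
That response can be measured four ways: office readings, home
self-monitoring averages, and ambulatory daytime and nighttime averages.
`bpsignal` works under the *same-signal* model: writing $y_{im}$ for subject
$i$'s measured response (post-treatment minus pretreatment average, mmHg,
negative for declines) by method $m$,

$$ y_{im} = s_i + \delta_m + \gamma_m (x_{im} - \bar x) + e_{im}, $$

where $s_i$ is the latent response signal shared by all methods, $\delta_m$
is a constant method offset (white-coat and related level effects),
$x_{im}$ is the own-method pretreatment BP level with regression-to-the-mean
slope $\gamma_m$, and $e_{im} \sim N(0, \sigma^2_{e,m})$ is independent
method-specific measurement noise.  The signal itself carries the covariate
structure

$$ s_i = \beta_0 + z_i^\top \beta + \beta_g g_i + u_i,\qquad
   u_i \sim N(0, \sigma^2_u), $$

with $z_i$ the subject's covariates (race, log plasma renin activity, sex,
log hypertension duration, serum ALT, age), $g_i \in \{0,1,2\}$ an optional
additively coded biallelic genotype in Hardy–Weinberg equilibrium, and
$\beta_g$ its per-allele effect in mmHg.

Everything downstream follows from this model:

* after regressing out the own-method pretreatment level, the covariance of
  the four adjusted responses is $\sigma^2_s J + \mathrm{diag}(\sigma^2_{e,m})$,
  so **every pairwise covariance estimates the signal variance**
  $\sigma^2_s$; the package averages the six of them
  (`estimate_signal_noise()`);
* each method's noise is its total variance minus the signal, and its
  signal-to-noise ratio is $\mathrm{SNR}_m = \sigma^2_s / \sigma^2_{e,m}$;
* unit-sum weights proportional to the row sums of $\Sigma^{-1}$ minimize
  the variance of a weighted-average response (`min_variance_weights()`);
* measurement noise attenuates the fraction of variance a genetic predictor
  can explain by $\lambda_m = 1 + 1/\mathrm{SNR}_m$, which maps directly to
  association power (`scheme_power_table()`).

## What the synthetic generator emulates — and what it does not

No subject-level data from the emulated trial are distributed, so the
package ships a generator (`generate_cohort()`) whose defaults reproduce the
trial's published operating conditions:

* covariate marginals from the baseline table: race prevalence 0.41, male
  0.47; log-PRA normal with parameters chosen so the exponentiated
  distribution has mean 1.0 and SD 1.2 ng·mL⁻¹·hr⁻¹; hypertension duration
  entered as $\log(\text{years}+1)$ (the +1 tolerates newly diagnosed
  subjects with zero years) matched to mean 7.1/SD 7.2 years; ALT
  N(29.1, 15.9) U·L⁻¹; age N(49.3, 9.1) years;
* predictor effects from the published multivariable models, e.g. for the
  atenolol systolic response: intercept −14.1, race +6.3, log-PRA −4.4,
  male +2.3, log-hypertension-years +1.3, ALT +0.08 mmHg per unit.  Binary
  covariates enter as-is and continuous ones centered, so the intercept is
  the reference subject's signal mean and published coefficients are usable
  verbatim;
* per-method raw response means and SDs from the published response summary
  (e.g. atenolol systolic: −13.5 ± 15.6 office, −8.3 ± 10.4 home,
  −12.2 ± 11.1 daytime, −8.9 ± 12.9 nighttime).  Method mean differences are
  represented by the offsets $\delta_m$; they shift columns without touching
  any covariance, so the signal/noise machinery is invariant to them;
* the per-(drug, endpoint) signal variance is back-solved from the published
  genome-wide-detectable per-allele effects (5.22/3.36 mmHg for atenolol
  systolic/diastolic, 4.04/2.63 for hydrochlorothiazide) through
  $\sigma^2_s = 2p(1-p)\beta_g^2 / r^2$ at MAF $p = 0.2$ and
  $r^2 = 0.1166$; the method noise variances are then the remainder of the
  published total variances after the signal and the pretreatment term.

Two calibration constants were genuinely open and fixed once:

* **pretreatment slope** $\gamma_m = -0.2$ for every method (higher
  pretreatment level, larger decline).  The trial reports the direction of
  this dependence but no magnitude; −0.2 is a modest regression-to-the-mean
  slope and, combined with the calibrated signal variances, keeps the
  office and nighttime SNRs below 1 and the home and daytime SNRs above 1 —
  the qualitative SNR pattern the trial reported.  A steeper slope would
  leave too little nighttime noise to keep that ordering;
* **pretreatment correlation between methods** 0.8: one shared latent
  pretreatment level per subject plus method deviations, so the home and
  office screening thresholds in `apply_eligibility_filter()` act on a
  bivariate-normal pair rather than one duplicated number.

Features of real data the generator does **not** emulate: visit-level
averaging of individual readings (only the pre/post averages the analysis
consumes are drawn), dose titration, drop-out, non-normal noise, and any
dependence of noise on the number of readings per subject.  Passing tests
therefore demonstrate that the estimators recover the truth *under the
same-signal model*, not that real BP data satisfy the model.  The
eligibility filter is off by default because screening on pretreatment BP
induces selection the variance decomposition does not model; it exists so
users can probe that sensitivity.

The generator also retains each subject's latent signal in a
`signal_<endpoint>` column.  It is an oracle for truth-recovery tests; no
estimation routine reads it.

## Preparation choices

Responses are post- minus pretreatment averages; subjects missing any method
are dropped (the covariance step needs a complete N×4 matrix) and counted.
Pretreatment adjustment is method-specific and univariate — own-method
pretreatment only, as cross-method terms are not part of the model — and the
column mean is restored after residualization so adjusted responses keep
their mmHg location.  Covariance, SNR, and power results are invariant to
the mean restoration; it only keeps intercepts interpretable.  Adjustment
and all downstream estimation are per (drug, endpoint); nothing is pooled
across arms.

## The same-signal test

If different methods measured different signals, predictor effects would
differ by method.  `same_signal_test()` stacks the four adjusted responses
(long format, subject as cluster), fits
`response ~ covariates + method + covariates:method` with an exchangeable
working correlation over the four within-subject rows, and jointly tests the
15 interaction coefficients (5 covariates × 3 method contrasts).

The joint statistic is, by default, the **cluster-robust generalized score
test**: the interaction columns are residualized against the null design
under the working weight, per-subject efficient scores are evaluated at the
null fit, and — since those scores are iid mean-zero vectors under the null
— their sum is tested with the one-sample Hotelling $T^2$ statistic
($T^2 = U^\top V^{-1} U$ with $V$ the centered empirical score covariance,
referred to $F_{q,\,G-q}$ for $G$ subjects and $q$ tested coefficients).
The familiar sandwich chi-square Wald test on the fitted interaction
coefficients is available via `statistic = "wald"`, and per-interaction
estimates with robust standard errors are always reported from the full
fit.  The score default is a deliberate design choice: in simulations at
the package's own operating point (500 subjects, $q = 15$) the CR0 sandwich
Wald rejects a true null about 8% of the time at nominal 5% — a known
finite-sample liberality when the tested dimension is non-negligible
relative to the cluster count, which F references or bias-corrected-meat
variants only partially repair — while the Hotelling-form score test holds
5% and still rejects at least 90% of the time when a 6 mmHg office-only
race effect is injected.  Centering $V$ matters for power: the uncentered
score covariance absorbs the noncentrality and saturates the statistic
under strong alternatives.

The working correlation is estimated by moments from pooled residuals; if
the estimate leaves $(-1/3, 1)$ the fit falls back to independence with a
warning.  The cluster-robust covariance keeps both flavors valid under
either working structure.

## Predictor models and backward elimination

`fit_predictor_model()` is ordinary least squares of an adjusted response on
covariates.  By default the response is the equal-weight mean of the four
adjusted methods — under the same-signal model all methods share the
covariate structure, and averaging only reduces noise.  Backward elimination
(`backward_eliminate()`) removes one candidate at a time — the one whose
best case across arms (the larger of its two endpoint p-values, minimized
over arms) is worst — until every survivor is significant at 0.05 for
*both* endpoints in at least one arm.  Run on a single drug's panel pair,
the rule reduces to "both endpoints within this drug", which is how effects
present only in one arm (ALT, hypertension duration for the beta-blocker)
end up retained there and absent from the other arm's model.  Age is a
standing candidate expected to fall out: its generating effect is zero.

## Power machinery

The noncentrality needed for a two-sided level-$\alpha$ test to reject with
probability $1-\beta$ is $z_{1-\alpha/2} + z_{1-\beta}$; at the genome-wide
level $5\times10^{-8}$ with 80% power this is 6.29.  A polymorphism just
detectable at reference size $n$ explains
$r^2 = \mathrm{ncp}^2 / (\mathrm{ncp}^2 + n)$ of the trait it is tested on —
11.66% of the signal at $n = 300$ — and converts to a per-allele effect via
the HWE genotype variance $2p(1-p)$.  A measurement scheme with inflation
$\lambda$ shrinks the explainable fraction to $r^2/\lambda$; power at $n$ is
$\Phi(\sqrt{n r^2 / (1 - r^2)} - z_{1-\alpha/2})$ (the opposite tail is
negligible at any usable $\alpha$) and required sample sizes are rounded up
with the unrounded value attached.  These are large-sample normal formulas:
a noncentral-t option (`df_method = "t"`) shows the far-tail difference,
about 0.05 of power at the genome-wide design point.

`simulate_snp_power()` validates the engine by simulating the single-SNP
Wald regression (maximum-likelihood residual variance, standard-normal
critical value).  Its default *realized-R²* convention scales the effect
within each replicate so the drawn genotypes explain exactly $r^2$ of the
trait variance — the conditional-on-design situation the analytic formula
describes — and reproduces the analytic 80% within Monte-Carlo error at the
design point.  The alternative *population* convention fixes the effect from
population variances and lets the realized genotype variance fluctuate; at
$\alpha = 5\times10^{-8}$ it sits about one percentage point below the
analytic value (far-tail t behavior plus genotype-variance sampling), which
is the honest size of the normal approximation's error at that extreme.

## Numerical and degenerate-input choices

* Negative noise estimates (a method's variance below the mean covariance)
  are reported with an `NA` SNR and flagged, never clipped: truncation would
  bias every downstream power number.
* Minimum-variance weights are normalized to unit sum (row sums of the
  inverse covariance are only proportional); unit sum keeps the combination
  unbiased for the signal.  Singular submatrices and unknown methods raise
  errors naming the subset; a singleton subset returns weight 1.
* Collinear predictor designs (rank-deficient or condition number beyond
  1e10) raise a diagnostic error rather than silently dropping columns.
* Noise-free stacked data with exactly-zero interaction estimates return
  statistic 0 and p = 1 instead of a 0/0 failure.
* Constant pretreatment columns are a degenerate design error; fewer than 5
  subjects is an insufficient-data error for the covariance stage.
* Fixing the generator seed reproduces cohorts byte-identically;
  `run_pipeline(seed =)` propagates one seed to every stochastic stage and
  records it in the manifest.

## Problem sizes used in the shipped checks

The package's own test suite exercises the estimators at sizes chosen to
make Monte-Carlo error small relative to the assertions: cohorts of 300–500
subjects for operating-characteristic replications (1000 null replicates for
the same-signal size check, 400 for its power check), 5000 subjects for
coefficient and moment recovery, 200 replicates of 5000 for signal/noise
bias, 20,000–30,000 subjects for attenuation and eligibility-tail checks,
and $10^5$ replicates for the Wald-regression power validation.  These sizes
are statements about Monte-Carlo precision, not about the method's limits.

## Known limitations

* The same-signal model assumes noise independent across methods; shared
  device or visit effects would masquerade as signal.
* SNR estimates at a few hundred subjects are noisy, and their reciprocals
  (the $\lambda$ inflations) noisier; power tables inherit that noise.
  No confidence intervals are attached.
* The power formulas are two-sided normal approximations for a quantitative
  trait under additive coding; binary traits, dominance, imputation quality,
  and winner's curse are out of scope.
* The eligibility filter's selection effects on the variance decomposition
  are deliberately unmodeled — switching it on at the default thresholds and
  comparing decompositions is the intended way to gauge that sensitivity.
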