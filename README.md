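# bpsignal

Do office, home, and ambulatory daytime and nighttime blood-pressure (BP)
responses to an antihypertensive drug measure the same thing?  And if they
do, which way of measuring the response gives a pharmacogenomic study the
best chance of finding a genetic predictor?  `bpsignal` implements the full
analysis pipeline behind those questions, for biostatisticians designing
drug-response association studies:

* a **synthetic cohort generator** calibrated to a published two-arm
  monotherapy trial (atenolol vs hydrochlorothiazide), so every stage can be
  exercised without subject-level data;
* **response preparation**: responses as post- minus pretreatment averages,
  with the own-method pretreatment level regressed out;
* a **same-signal test**: a stacked within-subject regression with a
  cluster-robust joint test of covariate-by-method interactions;
* **predictor models** with backward elimination under a two-endpoint
  retention rule;
* **signal/noise decomposition** and **minimum-variance weighted averages**;
* an analytic **power/sample-size engine** for detecting an additive SNP,
  validated by Monte Carlo.

## The model in brief

Each subject has one latent response signal $s_i$; method $m$ observes

$$y_{im} = s_i + \delta_m + \gamma_m (x_{im} - \bar x) + e_{im},
\qquad e_{im} \sim N(0, \sigma^2_{e,m}).$$

After pretreatment adjustment, every pairwise covariance of the four
responses estimates the signal variance $\sigma^2_s$; the package averages
the six pairwise covariances, sets noise $\sigma^2_{e,m}$ as the per-method
remainder, and forms $\mathrm{SNR}_m = \sigma^2_s/\sigma^2_{e,m}$.
Unit-sum weights proportional to the row sums of the inverse covariance
matrix minimize the variance of a combined response.  Measurement noise
inflates variance by $\lambda = 1 + 1/\mathrm{SNR}$ and attenuates the
variance fraction a SNP explains from $r^2$ to $r^2/\lambda$; with
$\mathrm{ncp} = z_{1-\alpha/2} + z_{\text{power}}$, power at sample size $n$
is $\Phi(\sqrt{n r^2/(1-r^2)} - z_{1-\alpha/2})$ and the required $n$ is
$\mathrm{ncp}^2 (1-r^2)/r^2$.

## Worked example

```r
library(bpsignal)

cfg <- default_generator_config("atenolol", "systolic", n_subjects = 3000, seed = 11)
cohort <- generate_cohort(cfg)
panel <- adjust_pretreatment(compute_responses(cohort, "atenolol", "systolic"))

dec <- estimate_signal_noise(panel)
dec
#> Signal/noise decomposition (atenolol, systolic), n = 3000
#>   signal variance: 77.206 mmHg^2
#>     method total noise   snr
#>     office   240 163.1 0.473
#>       home   102  24.7 3.125
#>    amb_day   117  40.0 1.928
#>  amb_night   160  83.2 0.928
```

The home and daytime responses carry more signal than noise; office and
nighttime carry more noise than signal.  Combining all four methods with
minimum-variance weights:

```r
w_all <- min_variance_weights(dec)
scheme_power_table(dec, list(w_all))
#> Power table: maf=0.2, alpha=5e-08, reference N=300 at 80% power
#> Detectable signal fraction r2 = 0.1166; per-allele effect on signal = 5.30 mmHg
#>                                  scheme   snr lambda r2_pct power_at_n_ref n_for_target_power
#>                                  signal   Inf   1.00  11.66          0.800                300
#>                                  office 0.473   3.11   3.75          0.021               1018
#>                                    home 3.125   1.32   8.83          0.476                409
#>                                 amb_day 1.928   1.52   7.68          0.324                477
#>                               amb_night 0.928   2.08   5.61          0.110                667
#>  weighted_office+home+amb_day+amb_night 6.584   1.15  10.12          0.641                352
```

Reading the table: a SNP detectable with 80% power at N = 300 on the
noise-free signal would be detected with only ~2% power from office
responses (N ≈ 1000 needed for 80%), while the weighted average of all four
methods keeps the required N within ~17% of the ideal 300.  The same-signal
premise behind the pooling is testable:

```r
same_signal_test(panel, c("race_black", "log_pra", "male", "log_htn_years", "alt"))
#> Same-signal test (atenolol, systolic): robust score chi^2 = 12.74 on 15 df, p = 0.654
#>   working correlation: exchangeable (rho = 0.366), 3000 subjects
```

No evidence that predictor effects depend on the measurement method — the
four methods can be treated as noisy readings of one signal.
`run_pipeline()` chains all stages and writes every intermediate table
(cohort, panels, predictor models, decompositions, weights, power tables,
manifest) to an output directory.

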