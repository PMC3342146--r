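test_that("required noncentrality matches quantile sums", {
  expect_equal(round(required_ncp(5e-8, 0.80), 2), 6.29)
  expect_equal(required_ncp(0.05, 0.50), qnorm(0.975))
  # independent quantile computation
  expect_equal(required_ncp(0.05, 0.80),
               qnorm(0.975) + qnorm(0.8), tolerance = 1e-12)
  expect_equal(round(required_ncp(0.05, 0.80), 4), 2.8016)
  expect_error(required_ncp(0, 0.8), "alpha")
  expect_error(required_ncp(0.05, 1), "power")
})

test_that("detectable r2 inverts the noncentrality relation", {
  expect_equal(detectable_r2(6.29, 300), 6.29^2 / (6.29^2 + 300))
  expect_equal(round(detectable_r2(6.29, 300), 4), 0.1165)
  expect_equal(detectable_r2(0, 500), 0)
  expect_equal(round(detectable_r2(2.8016, 100), 4), 0.0728)
  # numeric inversion oracle: the r2 whose ncp is the input
  r2 <- detectable_r2(3.5, 250)
  expect_equal(sqrt(250 * r2 / (1 - r2)), 3.5, tolerance = 1e-12)
  expect_error(detectable_r2(6.29, 1), "n")
})

test_that("allele effect size follows the HWE variance conversion", {
  expect_equal(allele_effect_size(0, 100, 0.2), 0)
  expect_equal(allele_effect_size(0.116, 100, 0.2), sqrt(11.6 / 0.32))
  expect_equal(round(allele_effect_size(0.116, 100, 0.2), 2), 6.02)
  expect_equal(allele_effect_size(0.1, 80, 0.3),
               allele_effect_size(0.1, 80, 0.7))  # maf symmetry
  expect_error(allele_effect_size(0.1, 80, 0), "maf")
})

test_that("simulated per-allele effect reproduces its target R2", {
  # attenuation check: regressing a noisy scheme on genotype recovers r2/lambda
  n <- 30000
  cfg <- default_generator_config("atenolol", "systolic", n_subjects = n,
                                  seed = 91, beta_snp = 5.22)
  co <- generate_cohort(cfg)
  panel <- adjust_pretreatment(compute_responses(co, "atenolol", "systolic"))
  s_base <- cfg$calib$systolic$signal_resid_var +
    bpsignal:::.covariate_signal_var(cfg$calib$systolic$beta,
                                     cfg$covariate_params)
  s_tot <- s_base + 2 * 0.2 * 0.8 * 5.22^2
  for (m in c("home", "office")) {
    noise <- cfg$calib$systolic$noise_vars[match(m, bp_methods)]
    r2_exp <- 2 * 0.2 * 0.8 * 5.22^2 / (s_tot + noise)
    r2_obs <- summary(lm(panel$adjusted[, m] ~ panel$covariates$genotype))$r.squared
    expect_lt(abs(r2_obs - r2_exp), 3 * sqrt(4 * r2_exp / n) + 0.003)
  }
})

test_that("power at n matches the normal approximation and its null limit", {
  expect_equal(round(power_at_n(300, 0.1165, 5e-8), 2), 0.80)
  expect_equal(power_at_n(300, 0, 5e-8), 5e-8 / 2)
  expect_equal(round(power_at_n(300, 0.05, 5e-8), 3), 0.070)
  # noncentral-t option is close to but below the normal value far in the tail
  expect_lt(power_at_n(300, 0.1165, 5e-8, df_method = "t"),
            power_at_n(300, 0.1165, 5e-8))
  expect_lt(abs(power_at_n(300, 0.1165, 5e-8, df_method = "t") -
                  power_at_n(300, 0.1165, 5e-8)), 0.06)
})

test_that("sample size inverts power and round-trips", {
  n <- sample_size_for_power(detectable_r2(required_ncp(5e-8, 0.8), 300),
                             5e-8, 0.8)
  expect_equal(as.numeric(n), 300)
  expect_equal(as.numeric(sample_size_for_power(0.1165, 5e-8, 0.8)), 301)
  expect_equal(as.numeric(sample_size_for_power(0.05, 5e-8, 0.8)), 753)
  for (r2 in c(0.02, 0.08, 0.15, 0.25)) {
    n <- sample_size_for_power(r2, 5e-8, 0.8)
    expect_gte(power_at_n(as.numeric(n), r2, 5e-8), 0.8)
  }
  expect_warning(n0 <- sample_size_for_power(0, 5e-8, 0.8), "unbounded")
  expect_equal(as.numeric(n0), Inf)
})

test_that("power is monotone in n and in SNR", {
  ns <- c(100, 200, 400, 800)
  pw <- power_at_n(ns, 0.05, 5e-8)
  expect_true(all(diff(pw) > 0))
  dec <- signal_noise_from_cov(matrix(50, 4, 4) + diag(c(150, 30, 40, 100)),
                               n_subjects = 500)
  tab <- scheme_power_table(dec)
  expect_equal(tab$power_at_n_ref[tab$scheme == "signal"], 0.8,
               tolerance = 1e-6)
  expect_equal(tab$n_for_target_power[tab$scheme == "signal"], 300)
  ord <- order(tab$snr, decreasing = TRUE)
  expect_equal(order(tab$power_at_n_ref, decreasing = TRUE), ord)
  expect_equal(order(tab$n_for_target_power), ord)
})

test_that("schemes with undefined SNR appear as flagged NA rows", {
  C <- matrix(5, 4, 4); diag(C) <- c(4, 8, 9, 10)
  dec <- signal_noise_from_cov(C, n_subjects = 100)
  expect_warning(tab <- scheme_power_table(dec), "negative noise")
  expect_true(is.na(tab$power_at_n_ref[tab$scheme == "office"]))
  expect_false(anyNA(tab$power_at_n_ref[tab$scheme %in% c("home", "amb_day")]))
})

test_that("Monte-Carlo rejection tracks the analytic power at ordinary alpha", {
  set.seed(92)
  target <- power_at_n(100, 0.0728, 0.05)
  mc <- simulate_snp_power(100, 0.0728, 0.05, reps = 4000)
  expect_lt(abs(mc - target), 3 * attr(mc, "se") + 0.01)
})
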