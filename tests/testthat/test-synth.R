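test_that("noise-free degenerate configuration yields four identical responses", {
  cfg <- generator_config(
    n_subjects = 20, drug = "atenolol", endpoint = "systolic",
    intercept = -10, beta = c(race_black = 0, log_pra = 0, male = 0),
    signal_resid_var = 0, noise_vars = rep(0, 4),
    method_offsets = rep(0, 4), gamma = rep(0, 4), beta_snp = 0, seed = 5
  )
  co <- generate_cohort(cfg)
  resp <- sapply(bp_methods, function(m)
    co[[paste0("post_systolic_", m)]] - co[[paste0("pre_systolic_", m)]])
  expect_true(all(abs(resp - (-10)) < 1e-12))
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  n <- 1e5
  cfg <- null_signal_config(n, seed = 21, maf = 0.2)
  g <- generate_cohort(cfg)$genotype
  p_hat <- tabulate(g + 1L, 3L) / n
  p_exp <- c(0.64, 0.32, 0.04)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_true(all(abs(p_hat - p_exp) <= 3 * se))
})

test_that("fixed seed reproduces the cohort exactly", {
  cfg <- default_generator_config("hctz", c("systolic", "diastolic"),
                                  n_subjects = 100, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("default atenolol systolic calibration matches configured response moments", {
  n <- 5000
  cfg <- default_generator_config("atenolol", "systolic", n_subjects = n,
                                  seed = 33)
  co <- generate_cohort(cfg)
  target_mean <- c(-13.5, -8.3, -12.2, -8.9)
  target_sd <- c(15.6, 10.4, 11.1, 12.9)
  for (m in seq_along(bp_methods)) {
    resp <- co[[paste0("post_systolic_", bp_methods[m])]] -
      co[[paste0("pre_systolic_", bp_methods[m])]]
    expect_lt(abs(mean(resp) - target_mean[m]), 3 * target_sd[m] / sqrt(n))
    expect_lt(abs(sd(resp) - target_sd[m]),
              3 * target_sd[m] / sqrt(2 * (n - 1)))
  }
})

test_that("null per-allele effect leaves genotype independent of responses", {
  n <- 20000
  cfg <- default_generator_config("atenolol", "systolic", n_subjects = n,
                                  seed = 44, beta_snp = 0)
  co <- generate_cohort(cfg)
  for (m in bp_methods) {
    resp <- co[[paste0("post_systolic_", m)]] - co[[paste0("pre_systolic_", m)]]
    expect_lt(abs(cor(resp, co$genotype)), 3 / sqrt(n))
  }
})

test_that("generated covariance has the latent-signal structure after adjustment", {
  n <- 20000
  cfg <- null_signal_config(n, signal_var = 50,
                            noise_vars = c(150, 30, 40, 100), seed = 99)
  panel <- adjust_pretreatment(compute_responses(generate_cohort(cfg),
                                                 "atenolol", "systolic"))
  C <- cov(panel$adjusted)
  off <- C[upper.tri(C)]
  # off-diagonals all estimate the signal variance
  expect_true(all(abs(off - 50) < 3 * sqrt((50^2 + 150 * 150) / n) + 3))
  expect_true(all(abs(diag(C) - (50 + c(150, 30, 40, 100))) <
                    3 * sqrt(2 / n) * (50 + c(150, 30, 40, 100))))
})

test_that("config validation names the offending field", {
  expect_error(generator_config(1, "atenolol", "systolic"), "n_subjects")
  expect_error(generator_config(10, "atenolol", "systolic", maf = 0.7), "maf")
  expect_error(generator_config(10, "atenolol", "systolic",
                                noise_vars = c(-1, 1, 1, 1)), "noise_vars")
  expect_error(generator_config(10, "atenolol", "systolic",
                                signal_resid_var = -2), "signal_resid_var")
  expect_error(generator_config(10, "atenolol", "systolic",
                                beta = c(bogus = 1)), "beta")
})

test_that("eligibility filter applies both diastolic thresholds", {
  co <- data.frame(subject_id = 1:3, arm = "atenolol",
                   pre_diastolic_home = c(84, 85, 90),
                   pre_diastolic_office = c(95, 89, 92))
  class(co) <- c("bp_cohort", "data.frame")
  kept <- apply_eligibility_filter(co, 85, 90)
  expect_equal(kept$subject_id, 3L)
  expect_equal(attr(kept, "n_removed"), 2L)

  unchanged <- apply_eligibility_filter(co, -Inf, -Inf)
  expect_equal(nrow(unchanged), 3L)
  expect_error(apply_eligibility_filter(co, "85", 90), "thresholds")
})

test_that("eligibility retention rate matches the bivariate-normal tail", {
  n <- 20000
  cfg <- default_generator_config("atenolol", "diastolic", n_subjects = n,
                                  seed = 55)
  co <- generate_cohort(cfg)
  kept <- apply_eligibility_filter(co, 85, 90)
  # oracle: integrate over the shared latent pretreatment level
  rho <- 0.8; mu <- 98.2; sdt <- 6.3
  s_l <- sdt * sqrt(rho); s_u <- sdt * sqrt(1 - rho)
  p_true <- integrate(function(l)
    dnorm(l, mu, s_l) * pnorm((85 - l) / s_u, lower.tail = FALSE) *
      pnorm((90 - l) / s_u, lower.tail = FALSE),
    mu - 8 * s_l, mu + 8 * s_l)$value
  expect_lt(abs(nrow(kept) / n - p_true),
            3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("generator config round-trips through YAML", {
  cfg <- default_generator_config("atenolol", "systolic", n_subjects = 50,
                                  seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg2))
})
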