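test_that("compound-symmetry covariance decomposes exactly", {
  C <- matrix(2, 4, 4); diag(C) <- c(5, 3, 4, 6)
  dec <- signal_noise_from_cov(C, n_subjects = 100)
  expect_equal(dec$signal_var, 2)
  expect_equal(unname(dec$noise_vars), c(3, 1, 2, 4))
  expect_equal(unname(dec$snr), c(2/3, 2, 1, 0.5))
})

test_that("duplicated methods share variance and have equal noise", {
  set.seed(10)
  y <- rnorm(50, -10, 4)
  adj <- cbind(y + rnorm(50), y, y, y + rnorm(50))
  dec <- estimate_signal_noise(make_panel(adj))
  C <- dec$cov_matrix
  expect_equal(C["home", "amb_day"], C["home", "home"])
  expect_equal(dec$noise_vars[["home"]], dec$noise_vars[["amb_day"]])
})

test_that("negative noise is reported, flagged, and not clipped", {
  C <- matrix(5, 4, 4); diag(C) <- c(4, 8, 9, 10)  # method 1 below the signal
  dec <- signal_noise_from_cov(C)
  expect_equal(dec$noise_vars[["office"]], -1)
  expect_true(is.na(dec$snr[["office"]]))
  expect_equal(dec$negative_noise, "office")
})

test_that("estimate_signal_noise validates its input", {
  panel <- make_panel(matrix(rnorm(16), 4))
  expect_error(estimate_signal_noise(panel), "at least 5")
  panel <- make_panel(matrix(c(rnorm(23), NA), 6))
  expect_error(estimate_signal_noise(panel), "non-finite")
  panel <- make_panel(matrix(rnorm(24), 6), adjusted = NULL)
  expect_error(estimate_signal_noise(panel), "adjust_pretreatment")
})

test_that("two-method minimum-variance weights match the calculus oracle", {
  S <- matrix(c(2, 1, 1, 4), 2,
              dimnames = list(c("office", "home"), c("office", "home")))
  w <- min_variance_weights(S, signal_var = 1)
  expect_equal(unname(w$weights), c(0.75, 0.25))
  expect_equal(w$combined_var, 1.75)
  expect_equal(w$combined_noise, 0.75)
  # independent 1-d minimization of w^2*2 + (1-w)^2*4 + 2w(1-w)*1
  oracle <- optimize(function(a) a^2 * 2 + (1 - a)^2 * 4 + 2 * a * (1 - a),
                     c(0, 1), tol = 1e-9)
  expect_equal(unname(w$weights[1]), oracle$minimum, tolerance = 1e-6)
  expect_equal(w$combined_var, oracle$objective, tolerance = 1e-6)
})

test_that("compound-symmetric matrices give exactly equal weights", {
  C <- matrix(3, 4, 4); diag(C) <- 7
  w <- min_variance_weights(C, signal_var = 3)
  expect_equal(unname(w$weights), rep(0.25, 4))
})

test_that("uncorrelated-noise weights reduce to precision weights", {
  d <- c(150, 30, 40, 100)
  C <- matrix(50, 4, 4) + diag(d)
  w <- min_variance_weights(C, signal_var = 50)
  expect_equal(unname(w$weights), unname((1 / d) / sum(1 / d)),
               tolerance = 1e-10)
  # combined variance never exceeds the best single method
  expect_lt(w$combined_var, min(diag(C)))
  # and beats 200 random unit-sum weight vectors
  set.seed(11)
  for (r in 1:200) {
    a <- rexp(4); a <- a / sum(a)
    expect_lte(w$combined_var, drop(t(a) %*% C %*% a) + 1e-12)
  }
})

test_that("weight edge cases behave", {
  C <- matrix(50, 4, 4) + diag(c(150, 30, 40, 100))
  dimnames(C) <- list(bp_methods, bp_methods)
  w1 <- min_variance_weights(C, methods = "home", signal_var = 50)
  expect_equal(unname(w1$weights), 1)
  expect_equal(w1$combined_var, 80)
  Csing <- C; Csing[2, ] <- Csing[3, ]; Csing[, 2] <- Csing[, 3]
  expect_error(min_variance_weights(Csing, methods = c("home", "amb_day")),
               "singular")
  expect_error(min_variance_weights(C, methods = "finger"), "not in covariance")
})

test_that("signal estimate is shift-invariant and scale-equivariant", {
  cfg <- null_signal_config(800, seed = 12)
  panel <- adjust_pretreatment(compute_responses(generate_cohort(cfg),
                                                 "atenolol", "systolic"))
  dec <- estimate_signal_noise(panel)

  shifted <- panel
  shifted$adjusted[, "home"] <- shifted$adjusted[, "home"] + 25
  dec_s <- estimate_signal_noise(shifted)
  expect_equal(dec_s$signal_var, dec$signal_var)
  expect_equal(dec_s$noise_vars, dec$noise_vars)

  scaled <- panel
  scaled$adjusted <- 3 * scaled$adjusted
  dec_c <- estimate_signal_noise(scaled)
  expect_equal(dec_c$signal_var, 9 * dec$signal_var)
  expect_equal(dec_c$noise_vars, 9 * dec$noise_vars)
})

test_that("weighted averages combine columns as specified", {
  cfg <- null_signal_config(600, seed = 13)
  panel <- adjust_pretreatment(compute_responses(generate_cohort(cfg),
                                                 "atenolol", "systolic"))
  dec <- estimate_signal_noise(panel)

  w_office <- min_variance_weights(dec, methods = "office")
  expect_equal(apply_weighted_average(panel, w_office),
               unname(panel$adjusted[, "office"]))

  w_all <- min_variance_weights(dec)
  comb <- apply_weighted_average(panel, w_all)
  # sample variance of the combination equals w' Sigma_hat w exactly
  expect_equal(var(comb), w_all$combined_var, tolerance = 1e-12)

  bad <- w_all; bad$methods <- c(bad$methods, "finger")
  expect_error(apply_weighted_average(panel, bad), "lacks methods")
})

test_that("combined SNR beats every single method on generator output", {
  set.seed(14)
  wins <- 0
  for (r in 1:20) {
    cfg <- default_generator_config("atenolol", "systolic", n_subjects = 500)
    panel <- adjust_pretreatment(compute_responses(generate_cohort(cfg),
                                                   "atenolol", "systolic"))
    dec <- estimate_signal_noise(panel)
    w <- min_variance_weights(dec)
    wins <- wins + (w$combined_snr >= max(dec$snr, na.rm = TRUE))
  }
  expect_gte(wins / 20, 0.95)
})
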