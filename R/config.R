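# Calibration constants for the synthetic cohort generator.
#
# Marginals and effect sizes are taken from the published description of the
# PEAR monotherapy arms: covariate distributions from the baseline table,
# per-method response means/SDs from the response table, predictor
# coefficients from the multivariable model table, and per-(drug, endpoint)
# signal variances back-solved from the reported genome-wide-detectable
# per-allele effect sizes (mmHg/allele at MAF 0.2).  See the methods vignette
# for the derivations.

.bp_methods <- c("office", "home", "amb_day", "amb_night")
.bp_covariates <- c("race_black", "log_pra", "male", "log_htn_years", "alt", "age")

.pear_calibration <- local({
  # log-PRA: normal on log scale so exp() has mean 1.0 and SD 1.2 ng/mL/hr
  s2_pra <- log(1 + (1.2 / 1.0)^2)
  # hypertension duration modeled as log(years + 1); years have mean 7.1, SD 7.2
  s2_htn <- log(1 + (7.2 / 8.1)^2)
  list(
    covariate_params = list(
      race_black    = list(prevalence = 0.41),
      male          = list(prevalence = 0.47),
      log_pra       = list(mean = -s2_pra / 2, sd = sqrt(s2_pra)),
      log_htn_years = list(mean = log(8.1) - s2_htn / 2, sd = sqrt(s2_htn)),
      alt           = list(mean = 29.1, sd = 15.9),
      age           = list(mean = 49.3, sd = 9.1)
    ),
    pretreat = list(systolic = c(mean = 151.5, sd = 13.8),
                    diastolic = c(mean = 98.2, sd = 6.3)),
    pretreat_rho = 0.8,
    gamma = rep(-0.2, 4L),
    # per-method raw response mean and SD, order office/home/amb_day/amb_night
    response_moments = list(
      atenolol = list(
        systolic  = list(mean = c(-13.5, -8.3, -12.2, -8.9),
                         sd   = c(15.6, 10.4, 11.1, 12.9)),
        diastolic = list(mean = c(-10.5, -7.8, -9.2, -7.0),
                         sd   = c(9.4, 6.8, 7.9, 10.0))),
      hctz = list(
        systolic  = list(mean = c(-13.2, -9.4, -10.8, -10.6),
                         sd   = c(13.7, 9.1, 9.8, 12.1)),
        diastolic = list(mean = c(-6.8, -5.3, -6.1, -6.5),
                         sd   = c(7.9, 6.0, 7.0, 9.0)))
    ),
    # predictor model: intercept for the reference subject (non-black female
    # at covariate means) and effects per unit covariate
    predictor_model = list(
      atenolol = list(
        systolic  = list(intercept = -14.1,
                         beta = c(race_black = 6.3, log_pra = -4.4, male = 2.3,
                                  log_htn_years = 1.3, alt = 0.08, age = 0)),
        diastolic = list(intercept = -11.8,
                         beta = c(race_black = 4.8, log_pra = -2.5, male = 2.9,
                                  log_htn_years = 1.0, alt = 0.04, age = 0))),
      hctz = list(
        systolic  = list(intercept = -11.8,
                         beta = c(race_black = -2.9, log_pra = 0.7, male = 4.2,
                                  log_htn_years = 0, alt = 0, age = 0)),
        diastolic = list(intercept = -6.7,
                         beta = c(race_black = -2.0, log_pra = 0.7, male = 2.7,
                                  log_htn_years = 0, alt = 0, age = 0)))
    ),
    # reported per-allele effects (mmHg/allele) for the signal at MAF 0.2
    beta_per_allele = list(atenolol = c(systolic = 5.22, diastolic = 3.36),
                           hctz     = c(systolic = 4.04, diastolic = 2.63))
  )
})

# variance of the covariate contribution to the signal for an effect vector
.covariate_signal_var <- function(beta, params) {
  v <- 0
  for (nm in names(beta)) {
    p <- params[[nm]]
    v <- v + if (!is.null(p$prevalence))
      beta[[nm]]^2 * p$prevalence * (1 - p$prevalence)
    else beta[[nm]]^2 * p$sd^2
  }
  v
}

# signal mean given intercept convention: binary covariates at prevalence,
# continuous covariates centered
.signal_mean <- function(intercept, beta, params) {
  m <- intercept
  for (nm in names(beta)) {
    p <- params[[nm]]
    if (!is.null(p$prevalence)) m <- m + beta[[nm]] * p$prevalence
  }
  m
}

#' Configure the synthetic cohort generator
#'
#' Builds a single-endpoint generator configuration for the latent-signal
#' measurement model: each subject carries one true (latent) BP response
#' common to all four measurement methods, and each method observes it with
#' independent mean-zero noise plus a method-specific dependence on the
#' subject's pretreatment BP level and an optional constant method offset.
#'
#' @param n_subjects Number of subjects, >= 2.
#' @param drug Arm label, `"atenolol"` or `"hctz"`.
#' @param endpoint `"systolic"` or `"diastolic"`.
#' @param intercept Signal mean for the reference subject (non-black female at
#'   covariate means), mmHg.
#' @param beta Named covariate effect vector on the signal (mmHg per unit) over
#'   any subset of `race_black, log_pra, male, log_htn_years, alt, age`.
#'   Continuous covariates are centered before the effect is applied.
#' @param signal_resid_var Residual signal variance beyond covariates, mmHg^2.
#' @param noise_vars Length-4 vector of method noise variances (mmHg^2), order
#'   office, home, ambulatory daytime, ambulatory nighttime.
#' @param method_offsets Length-4 vector of constant per-method response
#'   offsets, mmHg (0 = all methods share the signal mean).
#' @param pretreat_mean,pretreat_sd Pretreatment BP mean and SD, mmHg.
#' @param pretreat_rho Correlation between any two methods' pretreatment
#'   levels (one shared latent level plus method-specific deviation).
#' @param gamma Length-4 vector of slopes of response on own-method centered
#'   pretreatment BP (negative: higher pretreatment level, larger decline).
#' @param covariate_params Per-covariate distribution parameters; defaults to
#'   the trial-calibrated marginals.
#' @param maf Minor allele frequency of the optional biallelic variant, in
#'   \[0, 0.5\].
#' @param beta_snp Per-allele effect on the signal, mmHg (0 disables any
#'   genotype-response association; the genotype column is always generated).
#' @param seed Optional integer seed; fixing it reproduces the cohort exactly.
#' @param apply_eligibility If `TRUE` (and the endpoint is diastolic or the
#'   configuration includes a diastolic endpoint), the home/office diastolic
#'   pretreatment eligibility filter is applied after generation.
#' @param interaction_effect Optional list `(method=, covariate=, delta=)`
#'   adding `delta * covariate` to one method's response only -- a deliberate
#'   violation of the same-signal model for power studies of the
#'   interaction test.
#' @return An object of class `generator_config`.
#' @seealso [default_generator_config()] for the trial-calibrated defaults,
#'   [generate_cohort()].
#' @export
generator_config <- function(n_subjects,
                             drug = c("atenolol", "hctz"),
                             endpoint = c("systolic", "diastolic"),
                             intercept = 0,
                             beta = NULL,
                             signal_resid_var = 25,
                             noise_vars = rep(25, 4L),
                             method_offsets = rep(0, 4L),
                             pretreat_mean = NULL,
                             pretreat_sd = NULL,
                             pretreat_rho = 0.8,
                             gamma = rep(-0.2, 4L),
                             covariate_params = .pear_calibration$covariate_params,
                             maf = 0.2,
                             beta_snp = 0,
                             seed = NULL,
                             apply_eligibility = FALSE,
                             interaction_effect = NULL) {
  drug <- match.arg(drug)
  endpoint <- match.arg(endpoint)
  if (is.null(pretreat_mean))
    pretreat_mean <- .pear_calibration$pretreat[[endpoint]][["mean"]]
  if (is.null(pretreat_sd))
    pretreat_sd <- .pear_calibration$pretreat[[endpoint]][["sd"]]
  if (is.null(beta)) beta <- c(race_black = 0)
  calib <- list(list(
    intercept = intercept, beta = beta,
    signal_resid_var = signal_resid_var, noise_vars = noise_vars,
    method_offsets = method_offsets,
    pretreat_mean = pretreat_mean, pretreat_sd = pretreat_sd,
    gamma = gamma, interaction_effect = interaction_effect
  ))
  names(calib) <- endpoint
  cfg <- structure(list(
    n_subjects = n_subjects, drug = drug, endpoints = endpoint,
    covariate_params = covariate_params, pretreat_rho = pretreat_rho,
    maf = maf, beta_snp = beta_snp, seed = seed,
    apply_eligibility = apply_eligibility, calib = calib
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Trial-calibrated default generator configuration
#'
#' Returns a configuration whose defaults reproduce the published study
#' conditions: covariate marginals from the baseline characteristics, raw
#' response means and SDs per method from the response summary, covariate
#' effects from the multivariable predictor models, and per-(drug, endpoint)
#' signal variances chosen so that the polymorphism detectable with 80% power
#' at N = 300 and genome-wide alpha explains 11.7% of the signal with the
#' reported per-allele effects (5.22/3.36 mmHg for atenolol systolic/
#' diastolic, 4.04/2.63 for hydrochlorothiazide).  Method noise variances are
#' the remainder of the total variance after the signal and the pretreatment
#' dependence.  Requesting both endpoints generates them for the same
#' subjects (covariates and genotype shared; signal residuals independent).
#'
#' @param drug `"atenolol"` or `"hctz"`.
#' @param endpoints One or both of `"systolic"`, `"diastolic"`.
#' @param n_subjects Subjects per cohort (the trial randomized about 300 per
#'   arm).
#' @param maf,beta_snp,seed,apply_eligibility Passed through; see
#'   [generator_config()].
#' @return A `generator_config`.
#' @export
default_generator_config <- function(drug = c("atenolol", "hctz"),
                                     endpoints = c("systolic", "diastolic"),
                                     n_subjects = 300,
                                     maf = 0.2, beta_snp = 0, seed = NULL,
                                     apply_eligibility = FALSE) {
  drug <- match.arg(drug)
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  cal <- .pear_calibration
  r2_gw <- detectable_r2(required_ncp(5e-8, 0.8), 300)
  calib <- list()
  for (ep in endpoints) {
    pm <- cal$predictor_model[[drug]][[ep]]
    mom <- cal$response_moments[[drug]][[ep]]
    pre <- cal$pretreat[[ep]]
    # signal variance back-solved from the reported per-allele effect at MAF 0.2
    b_allele <- cal$beta_per_allele[[drug]][[ep]]
    signal_var <- 2 * 0.2 * 0.8 * b_allele^2 / r2_gw
    cov_var <- .covariate_signal_var(pm$beta, cal$covariate_params)
    resid <- signal_var - cov_var
    stopifnot(resid > 0)
    noise <- mom$sd^2 - cal$gamma^2 * pre[["sd"]]^2 - signal_var
    stopifnot(all(noise > 0))
    offsets <- mom$mean - .signal_mean(pm$intercept, pm$beta, cal$covariate_params)
    calib[[ep]] <- list(
      intercept = pm$intercept, beta = pm$beta,
      signal_resid_var = resid, noise_vars = noise,
      method_offsets = offsets,
      pretreat_mean = pre[["mean"]], pretreat_sd = pre[["sd"]],
      gamma = cal$gamma, interaction_effect = NULL
    )
  }
  cfg <- structure(list(
    n_subjects = n_subjects, drug = drug, endpoints = endpoints,
    covariate_params = cal$covariate_params, pretreat_rho = cal$pretreat_rho,
    maf = maf, beta_snp = beta_snp, seed = seed,
    apply_eligibility = apply_eligibility, calib = calib
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks every field invariant and stops with a message naming the first
#' offending field.
#'
#' @param config A `generator_config`.
#' @return The configuration, invisibly, if valid.
#' @export
validate_generator_config <- function(config) {
  fail <- function(field, why)
    stop(sprintf("invalid generator config: field '%s' %s", field, why),
         call. = FALSE)
  if (!is.numeric(config$n_subjects) || length(config$n_subjects) != 1L ||
      is.na(config$n_subjects) || config$n_subjects < 2)
    fail("n_subjects", "must be a count >= 2")
  if (!config$drug %in% c("atenolol", "hctz")) fail("drug", "unknown label")
  if (!all(config$endpoints %in% c("systolic", "diastolic")))
    fail("endpoint", "unknown label")
  if (!is.numeric(config$maf) || config$maf < 0 || config$maf > 0.5)
    fail("maf", "must lie in [0, 0.5]")
  if (!is.numeric(config$beta_snp) || length(config$beta_snp) != 1L)
    fail("beta_snp", "must be a single number")
  if (!is.numeric(config$pretreat_rho) || config$pretreat_rho < 0 ||
      config$pretreat_rho > 1)
    fail("pretreat_rho", "must lie in [0, 1]")
  for (nm in .bp_covariates) {
    p <- config$covariate_params[[nm]]
    if (is.null(p)) fail(paste0("covariate_params$", nm), "is missing")
    if (!is.null(p$prevalence) && (p$prevalence < 0 || p$prevalence > 1))
      fail(paste0("covariate_params$", nm), "prevalence outside [0, 1]")
    if (is.null(p$prevalence) && (is.null(p$sd) || p$sd < 0))
      fail(paste0("covariate_params$", nm), "needs a nonnegative sd")
  }
  for (ep in config$endpoints) {
    cc <- config$calib[[ep]]
    if (is.null(cc)) fail("calib", paste("missing endpoint", ep))
    if (!is.numeric(cc$signal_resid_var) || cc$signal_resid_var < 0)
      fail("signal_resid_var", "must be >= 0")
    if (length(cc$noise_vars) != 4L || any(cc$noise_vars < 0))
      fail("noise_vars", "must be a nonnegative 4-vector")
    if (length(cc$gamma) != 4L) fail("gamma", "must be a 4-vector")
    if (length(cc$method_offsets) != 4L)
      fail("method_offsets", "must be a 4-vector")
    if (!is.numeric(cc$pretreat_sd) || cc$pretreat_sd < 0)
      fail("pretreat_sd", "must be >= 0")
    if (length(cc$beta) &&
        (is.null(names(cc$beta)) || !all(names(cc$beta) %in% .bp_covariates)))
      fail("beta", "must be named with known covariates")
    ie <- cc$interaction_effect
    if (!is.null(ie) &&
        (!ie$method %in% .bp_methods || !ie$covariate %in% .bp_covariates))
      fail("interaction_effect", "names an unknown method or covariate")
  }
  invisible(config)
}

#' Read or write a generator configuration as YAML
#'
#' @param config A `generator_config`.
#' @param path File path.
#' @return `write_generator_config()` returns the path invisibly;
#'   `read_generator_config()` returns a validated `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  validate_generator_config(config)
  x <- unclass(config)
  # named atomic vectors lose their names through YAML; store beta as a map
  x$calib <- lapply(x$calib, function(cc) {
    cc$beta <- as.list(cc$beta)
    cc
  })
  yaml::write_yaml(x, path, precision = 17)  # lossless double round-trip
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$calib <- lapply(x$calib, function(cc) {
    cc$beta <- unlist(cc$beta)
    cc
  })
  cfg <- structure(x, class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d subjects, %s, endpoint(s): %s\n",
              as.integer(x$n_subjects), x$drug,
              paste(x$endpoints, collapse = ", ")))
  for (ep in x$endpoints) {
    cc <- x$calib[[ep]]
    cat(sprintf("  %s: signal resid var %.1f, noise vars (%s) mmHg^2\n", ep,
                cc$signal_resid_var,
                paste(sprintf("%.1f", cc$noise_vars), collapse = ", ")))
  }
  cat(sprintf("  maf %.2f, per-allele effect %.2f mmHg, seed %s\n",
              x$maf, x$beta_snp,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}
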