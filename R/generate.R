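#' Generate a synthetic cohort
#'
#' Draws a cohort under the latent-signal measurement model.  For each
#' subject: genotype ~ Binomial(2, maf); covariates from their configured
#' marginals; the latent BP response (signal) is intercept + covariate
#' effects + per-allele genotype effect + normal residual; each method's
#' observed response is the signal plus its constant offset, its slope times
#' the centered own-method pretreatment level, and independent method noise.
#' Post-treatment BP is the pretreatment level plus the response.
#' Pretreatment levels share one latent per-subject level across methods
#' (between-method correlation `pretreat_rho`).
#'
#' @param config A `generator_config` (see [generator_config()] and
#'   [default_generator_config()]).
#' @return A data frame of class `bp_cohort`, one row per subject, with
#'   covariates, genotype, and per method x endpoint columns
#'   `pre_<endpoint>_<method>` and `post_<endpoint>_<method>`.  The latent
#'   signal is retained as `signal_<endpoint>` for truth-recovery testing
#'   only -- no estimation stage may read it.
#' @examples
#' cfg <- default_generator_config("atenolol", "systolic", n_subjects = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
#' head(cohort[, 1:8])
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- as.integer(config$n_subjects)
  cp <- config$covariate_params

  cov_df <- data.frame(
    race_black    = stats::rbinom(n, 1L, cp$race_black$prevalence),
    male          = stats::rbinom(n, 1L, cp$male$prevalence),
    log_pra       = stats::rnorm(n, cp$log_pra$mean, cp$log_pra$sd),
    log_htn_years = stats::rnorm(n, cp$log_htn_years$mean, cp$log_htn_years$sd),
    alt           = stats::rnorm(n, cp$alt$mean, cp$alt$sd),
    age           = stats::rnorm(n, cp$age$mean, cp$age$sd)
  )
  genotype <- stats::rbinom(n, 2L, config$maf)

  out <- data.frame(subject_id = seq_len(n), arm = config$drug, cov_df,
                    genotype = genotype, stringsAsFactors = FALSE)

  for (ep in config$endpoints) {
    cc <- config$calib[[ep]]
    # covariate contribution: binary covariates enter as-is, continuous ones
    # centered at their configured means, so the intercept is the signal mean
    # of the reference (non-black, female) subject
    eta <- rep(cc$intercept, n)
    for (nm in names(cc$beta)) {
      p <- cp[[nm]]
      x <- if (!is.null(p$prevalence)) cov_df[[nm]] else cov_df[[nm]] - p$mean
      eta <- eta + cc$beta[[nm]] * x
    }
    signal <- eta + config$beta_snp * genotype +
      stats::rnorm(n, 0, sqrt(cc$signal_resid_var))

    rho <- config$pretreat_rho
    latent_pre <- stats::rnorm(n, cc$pretreat_mean, cc$pretreat_sd * sqrt(rho))
    for (m in seq_along(.bp_methods)) {
      meth <- .bp_methods[m]
      pre <- latent_pre +
        stats::rnorm(n, 0, cc$pretreat_sd * sqrt(1 - rho))
      resp <- signal + cc$method_offsets[m] +
        cc$gamma[m] * (pre - cc$pretreat_mean) +
        stats::rnorm(n, 0, sqrt(cc$noise_vars[m]))
      ie <- cc$interaction_effect
      if (!is.null(ie) && ie$method == meth)
        resp <- resp + ie$delta * cov_df[[ie$covariate]]
      out[[paste0("pre_", ep, "_", meth)]] <- pre
      out[[paste0("post_", ep, "_", meth)]] <- pre + resp
    }
    out[[paste0("signal_", ep)]] <- signal
  }

  class(out) <- c("bp_cohort", "data.frame")
  attr(out, "endpoints") <- config$endpoints
  attr(out, "drug") <- config$drug
  if (isTRUE(config$apply_eligibility)) {
    if (!"diastolic" %in% config$endpoints)
      stop("eligibility filter needs diastolic pretreatment columns; ",
           "include the diastolic endpoint", call. = FALSE)
    out <- apply_eligibility_filter(out)
  }
  out
}

#' Apply the trial eligibility filter
#'
#' Retains subjects whose average home diastolic pretreatment BP is at least
#' `home_dbp_min` and whose office diastolic pretreatment BP is at least
#' `office_dbp_min` (the screening rule of the emulated trial: home >= 85 and
#' office >= 90 mmHg).  The filter induces selection on pretreatment level
#' that the downstream variance machinery does not model, so it is off by
#' default in the generator.
#'
#' @param cohort A `bp_cohort` containing diastolic pretreatment columns.
#' @param home_dbp_min,office_dbp_min Thresholds in mmHg.
#' @return The filtered cohort; the number of removed subjects is attached as
#'   attribute `n_removed`.
#' @export
apply_eligibility_filter <- function(cohort, home_dbp_min = 85,
                                     office_dbp_min = 90) {
  if (!is.numeric(home_dbp_min) || !is.numeric(office_dbp_min) ||
      length(home_dbp_min) != 1L || length(office_dbp_min) != 1L ||
      is.na(home_dbp_min) || is.na(office_dbp_min))
    stop("eligibility thresholds must be single numbers", call. = FALSE)
  need <- c("pre_diastolic_home", "pre_diastolic_office")
  if (!all(need %in% names(cohort)))
    stop("cohort lacks diastolic pretreatment columns (",
         paste(setdiff(need, names(cohort)), collapse = ", "), ")",
         call. = FALSE)
  keep <- cohort$pre_diastolic_home >= home_dbp_min &
    cohort$pre_diastolic_office >= office_dbp_min
  out <- cohort[keep, , drop = FALSE]
  attr(out, "endpoints") <- attr(cohort, "endpoints")
  attr(out, "drug") <- attr(cohort, "drug")
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(cohort)
  out
}

#' Read or write a cohort as CSV
#'
#' One header row, comma-delimited, columns as generated by
#' [generate_cohort()]; missing genotypes are written as empty fields.
#'
#' @param cohort A `bp_cohort`.
#' @param path File path.
#' @return `write_cohort()` the path, invisibly; `read_cohort()` a
#'   `bp_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  eps <- unique(sub("^pre_(systolic|diastolic)_.*$", "\\1",
                    grep("^pre_", names(out), value = TRUE)))
  class(out) <- c("bp_cohort", "data.frame")
  attr(out, "endpoints") <- eps
  attr(out, "drug") <- if (nrow(out)) out$arm[1] else NA_character_
  out
}
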