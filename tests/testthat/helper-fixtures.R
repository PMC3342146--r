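bp_methods <- c("office", "home", "amb_day", "amb_night")

# hand-built response panel for unit tests that need exact control
make_panel <- function(raw, adjusted = raw, pretreat = NULL,
                       covariates = NULL, drug = "atenolol",
                       endpoint = "systolic") {
  n <- nrow(raw)
  dimnames(raw) <- list(NULL, bp_methods)
  if (!is.null(adjusted)) dimnames(adjusted) <- list(NULL, bp_methods)
  if (is.null(pretreat))
    pretreat <- matrix(stats::rnorm(n * 4, 150, 10), n, 4,
                       dimnames = list(NULL, bp_methods))
  if (is.null(covariates))
    covariates <- data.frame(row.names = seq_len(n))
  structure(list(
    drug = drug, endpoint = endpoint, subject_id = seq_len(n),
    methods = bp_methods, raw = raw, pretreat = pretreat,
    adjusted = adjusted, adjustment_slopes = stats::setNames(rep(0, 4), bp_methods),
    covariates = covariates, n_dropped = 0L
  ), class = "response_panel")
}

# generator config with no covariate effects: pure signal + method noise
null_signal_config <- function(n, signal_var = 50,
                               noise_vars = c(150, 30, 40, 100),
                               gamma = rep(-0.2, 4), seed = NULL, ...) {
  generator_config(
    n_subjects = n, drug = "atenolol", endpoint = "systolic",
    intercept = -10, beta = c(race_black = 0),
    signal_resid_var = signal_var, noise_vars = noise_vars,
    method_offsets = rep(0, 4), gamma = gamma, seed = seed, ...
  )
}

# minimal two-subject-or-more cohort with constant responses, all methods
constant_cohort <- function(n = 4, pre = 150, resp = -13,
                            endpoint = "systolic", drug = "atenolol") {
  out <- data.frame(subject_id = seq_len(n), arm = drug)
  for (m in bp_methods) {
    out[[paste0("pre_", endpoint, "_", m)]] <- pre
    out[[paste0("post_", endpoint, "_", m)]] <- pre + resp
  }
  out
}
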