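#' Summarize raw BP responses by method
#'
#' Mean and SD of the raw response per measurement method, plus a
#' cluster-robust contrast p-value testing that the four method means are
#' equal (stacked within-subject model with subject clusters).
#'
#' @param panel A `response_panel` (raw responses suffice).
#' @return A data frame of class `response_summary` (`method`, `mean`, `sd`)
#'   with the contrast p-value as attribute `contrast_p`.
#' @export
summarize_responses <- function(panel) {
  stopifnot(inherits(panel, "response_panel"))
  n <- nrow(panel$raw)
  if (n < 1) stop("empty panel", call. = FALSE)
  out <- data.frame(method = panel$methods,
                    mean = colMeans(panel$raw),
                    sd = apply(panel$raw, 2, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  k <- length(panel$methods)
  long <- data.frame(method = factor(rep(panel$methods, each = n),
                                     levels = panel$methods))
  X <- stats::model.matrix(~method, long)
  fit <- .stacked_fit(as.vector(panel$raw), X, rep(seq_len(n), k),
                      working = "exchangeable")
  wt <- .wald_subset(fit, seq(2L, k))
  attr(out, "contrast_p") <- wt$p
  attr(out, "drug") <- panel$drug
  attr(out, "endpoint") <- panel$endpoint
  class(out) <- c("response_summary", "data.frame")
  out
}

#' @export
print.response_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Raw BP responses (%s, %s); contrast p = %.3g\n",
              attr(x, "drug"), attr(x, "endpoint"), attr(x, "contrast_p")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> response prep -> predictor models and
#' same-signal test -> signal/noise decomposition and minimum-variance
#' weighted averages -> power tables, writing every intermediate artifact as
#' CSV/JSON into `out_dir` so each stage can be inspected or re-run.  A
#' manifest records the seed, package version, subject counts per stage, and
#' an MD5 hash of every emitted file.
#'
#' @param configs A `generator_config` or list of them (one per drug arm), or
#'   a character path to a cohort CSV written by [write_cohort()].
#' @param out_dir Output directory, created if needed.
#' @param stages Subset of `c("predictors", "signalnoise", "power")`; the
#'   simulate/prep stages always run.  Dropping `"power"` omits the power
#'   tables without changing the other outputs.
#' @param covariates Candidate predictors for the predictor stage.
#' @param weight_subsets List of method subsets for weighted averages.
#' @param pspec A `power_spec` for the power stage.
#' @param seed Optional integer; overrides the configs' seeds (config `i`
#'   receives `seed + i - 1`) so one argument makes the whole run
#'   reproducible.
#' @return Invisibly, a list with the per-(drug, endpoint) results and the
#'   manifest.
#' @export
run_pipeline <- function(configs, out_dir,
                         stages = c("predictors", "signalnoise", "power"),
                         covariates = c("race_black", "log_pra", "male",
                                        "log_htn_years", "alt", "age"),
                         weight_subsets = list(.bp_methods,
                                               c("office", "home")),
                         pspec = power_spec(),
                         seed = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.character(configs)) {
    cohorts <- list(read_cohort(configs))
  } else {
    if (inherits(configs, "generator_config")) configs <- list(configs)
    if (!is.null(seed))
      for (i in seq_along(configs)) configs[[i]]$seed <- seed + i - 1L
    cohorts <- lapply(configs, generate_cohort)
  }

  results <- list()
  counts <- list()
  for (cohort in cohorts) {
    drug <- attr(cohort, "drug")
    write_cohort(cohort, file.path(out_dir, paste0("cohort_", drug, ".csv")))
    panels <- list()
    for (ep in attr(cohort, "endpoints")) {
      tag <- paste0(drug, "_", ep)
      panel <- adjust_pretreatment(compute_responses(cohort, drug, ep))
      panels[[ep]] <- panel
      counts[[tag]] <- list(n_subjects = nrow(panel$raw),
                            n_dropped = panel$n_dropped)
      write_panel(panel, file.path(out_dir, paste0("panel_", tag, ".csv")))

      res <- list(panel = panel)
      summ <- summarize_responses(panel)
      utils::write.csv(summ, file.path(out_dir, paste0("responses_", tag, ".csv")),
                       row.names = FALSE)
      res$summary <- summ

      if ("predictors" %in% stages) {
        model <- fit_predictor_model(panel, covariates)
        utils::write.csv(model$coefficients,
                         file.path(out_dir, paste0("predictors_", tag, ".csv")),
                         row.names = FALSE)
        sst <- same_signal_test(panel, covariates)
        jsonlite::write_json(
          list(wald_statistic = sst$wald_statistic, df = sst$df,
               p_value = sst$p_value,
               working_correlation = sst$working_correlation, rho = sst$rho),
          file.path(out_dir, paste0("same_signal_", tag, ".json")),
          auto_unbox = TRUE, digits = NA)
        res$predictors <- model
        res$same_signal <- sst
      }
      if ("signalnoise" %in% stages) {
        dec <- estimate_signal_noise(panel)
        jsonlite::write_json(
          list(drug = drug, endpoint = ep, signal_var = dec$signal_var,
               noise_vars = as.list(dec$noise_vars), snr = as.list(dec$snr),
               n_subjects = dec$n_subjects),
          file.path(out_dir, paste0("signal_noise_", tag, ".json")),
          auto_unbox = TRUE, digits = NA)
        specs <- lapply(weight_subsets, function(ms)
          min_variance_weights(dec, methods = ms))
        wtab <- do.call(rbind, lapply(specs, function(s)
          data.frame(subset = paste(s$methods, collapse = "+"),
                     method = s$methods, weight = s$weights,
                     row.names = NULL)))
        utils::write.csv(wtab, file.path(out_dir, paste0("weights_", tag, ".csv")),
                         row.names = FALSE)
        res$decomposition <- dec
        res$weighted <- specs
        if ("power" %in% stages) {
          ptab <- scheme_power_table(dec, specs, pspec)
          utils::write.csv(as.data.frame(ptab),
                           file.path(out_dir, paste0("power_", tag, ".csv")),
                           row.names = FALSE)
          res$power <- ptab
        }
      }
      results[[tag]] <- res
    }
    if ("predictors" %in% stages && length(panels) == 2L) {
      elim <- backward_eliminate(panels$systolic, panels$diastolic, covariates)
      jsonlite::write_json(
        list(drug = drug, retained = elim$retained, dropped = elim$path),
        file.path(out_dir, paste0("elimination_", drug, ".json")),
        auto_unbox = TRUE, digits = NA)
      results[[paste0(drug, "_elimination")]] <- elim
    }
  }

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("bpsignal")),
    seed = seed, stages = stages, subject_counts = counts,
    file_md5 = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}
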