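#' Fit the multivariable predictor model of the adjusted BP response
#'
#' Ordinary least squares of the pretreatment-adjusted response on subject
#' covariates.  The response may be a single method's column or (default)
#' the equal-weight mean of the four adjusted responses, a low-noise proxy
#' for the common signal that the predictor coefficients describe.
#'
#' @param panel An adjusted `response_panel` (see [adjust_pretreatment()]).
#' @param covariates Character vector of covariate names present in
#'   `panel$covariates`.
#' @param method One of the four method labels, or `"mean"` for the
#'   equal-weight average of the adjusted responses.
#' @return An object of class `predictor_model` with a coefficient table
#'   (`term`, `estimate`, `se`, `t`, `p`), `r_squared`, and metadata.
#' @export
fit_predictor_model <- function(panel, covariates, method = "mean") {
  stopifnot(inherits(panel, "response_panel"))
  if (is.null(panel$adjusted))
    stop("panel is not pretreatment-adjusted; run adjust_pretreatment() first",
         call. = FALSE)
  if (!method %in% c("mean", panel$methods))
    stop("unknown method '", method, "'", call. = FALSE)
  missing_cov <- setdiff(covariates, names(panel$covariates))
  if (length(missing_cov))
    stop("covariates not in panel: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  y <- if (method == "mean") rowMeans(panel$adjusted)
       else panel$adjusted[, method]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(panel$covariates[, covariates, drop = FALSE]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("collinear design: rank ", qr_x$rank, " < ", ncol(X),
         " columns (", paste(covariates, collapse = ", "), ")", call. = FALSE)
  if (kappa(X, exact = FALSE) > 1e10)
    stop("ill-conditioned design (condition number > 1e10)", call. = FALSE)
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  p <- ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(abs(tval), n - p, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  structure(list(
    drug = panel$drug, endpoint = panel$endpoint, method = method,
    coefficients = data.frame(term = colnames(X), estimate = fit$coefficients,
                              se = se, t = tval, p = pval,
                              row.names = NULL, stringsAsFactors = FALSE),
    r_squared = 1 - rss / tss,
    n = n, covariates = covariates
  ), class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, digits = 3, ...) {
  cat(sprintf("Predictor model of %s %s BP response (%s), n = %d, R^2 = %.1f%%\n",
              x$drug, x$endpoint, x$method, x$n, 100 * x$r_squared))
  print(x$coefficients, digits = digits, row.names = FALSE)
  invisible(x)
}

# p-values of the candidate terms for every (drug, endpoint) fit
.candidate_pvals <- function(panels_s, panels_d, active, method) {
  lapply(seq_along(panels_s), function(i) {
    fs <- fit_predictor_model(panels_s[[i]], active, method)
    fd <- fit_predictor_model(panels_d[[i]], active, method)
    ps <- fs$coefficients$p[match(active, fs$coefficients$term)]
    pd <- fd$coefficients$p[match(active, fd$coefficients$term)]
    list(systolic = ps, diastolic = pd, fit_s = fs, fit_d = fd)
  })
}

#' Backward elimination of BP-response predictors
#'
#' Iteratively removes the weakest candidate until every remaining predictor
#' satisfies the retention rule: significant (p < `alpha`) for both the
#' systolic and the diastolic response in at least one supplied drug arm.
#' At each step the dropped candidate is the one with the largest retention
#' score, where a candidate's score is its best case across drugs -- the
#' minimum over arms of the larger of its two endpoint p-values -- and the
#' models are refit after each drop.
#'
#' @param panel_s,panel_d Adjusted systolic and diastolic `response_panel`s
#'   sharing subjects, or parallel lists of such panels (one pair per drug
#'   arm) to apply the cross-drug retention rule.
#' @param candidates Character vector of candidate covariates.
#' @param alpha Significance threshold (0.05, fixed a priori in the emulated
#'   analysis).
#' @param method Response column passed to [fit_predictor_model()].
#' @return A list of class `elimination_result`: `retained` (character),
#'   `models` (per drug, a list with `systolic` and `diastolic`
#'   `predictor_model`s refit on the retained set), and `path` (candidates in
#'   drop order).  If nothing survives, intercept-only models are returned
#'   with a warning.
#' @export
backward_eliminate <- function(panel_s, panel_d, candidates, alpha = 0.05,
                               method = "mean") {
  if (inherits(panel_s, "response_panel")) panel_s <- list(panel_s)
  if (inherits(panel_d, "response_panel")) panel_d <- list(panel_d)
  stopifnot(length(panel_s) == length(panel_d), length(panel_s) >= 1)
  for (i in seq_along(panel_s)) {
    stopifnot(inherits(panel_s[[i]], "response_panel"),
              inherits(panel_d[[i]], "response_panel"))
    if (!identical(panel_s[[i]]$subject_id, panel_d[[i]]$subject_id))
      stop("systolic and diastolic panels must share subjects", call. = FALSE)
  }
  active <- candidates
  dropped <- character(0)
  while (length(active)) {
    fits <- .candidate_pvals(panel_s, panel_d, active, method)
    # score_j: best case over drugs of the worse endpoint p-value
    score <- sapply(seq_along(active), function(j)
      min(sapply(fits, function(f) max(f$systolic[j], f$diastolic[j]))))
    if (all(score < alpha)) break
    worst <- which.max(score)
    dropped <- c(dropped, active[worst])
    active <- active[-worst]
  }
  if (!length(active)) {
    warning("no candidates survive backward elimination; ",
            "returning intercept-only models", call. = FALSE)
    fits <- NULL
  }
  models <- lapply(seq_along(panel_s), function(i) list(
    systolic = fit_predictor_model(panel_s[[i]], active, method),
    diastolic = fit_predictor_model(panel_d[[i]], active, method)
  ))
  names(models) <- sapply(panel_s, `[[`, "drug")
  structure(list(retained = active, models = models, path = dropped,
                 alpha = alpha),
            class = "elimination_result")
}

#' @export
print.elimination_result <- function(x, ...) {
  cat("Backward elimination (retention: p <", x$alpha,
      "for both endpoints in >= 1 arm)\n")
  cat("  retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  if (length(x$path)) cat("  dropped (in order):",
                          paste(x$path, collapse = ", "), "\n")
  invisible(x)
}
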