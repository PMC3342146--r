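#' Compute BP responses for one drug arm and endpoint
#'
#' The response for each measurement method is the post-treatment average
#' minus the pretreatment average (negative values are declines).  Subjects
#' with any missing method are dropped -- the covariance stage needs a
#' complete N x 4 matrix -- and the count of dropped subjects is recorded.
#'
#' @param cohort A `bp_cohort` or any data frame with
#'   `pre_<endpoint>_<method>` / `post_<endpoint>_<method>` columns and an
#'   `arm` column.
#' @param drug Arm to extract, `"atenolol"` or `"hctz"`.
#' @param endpoint `"systolic"` or `"diastolic"`.
#' @return An object of class `response_panel`: a list with `raw`,
#'   `pretreat` (N x 4 matrices, columns office/home/amb_day/amb_night),
#'   `adjusted` (`NULL` until [adjust_pretreatment()]), `covariates`,
#'   `subject_id`, `n_dropped`, `drug`, `endpoint`.
#' @export
compute_responses <- function(cohort, drug = c("atenolol", "hctz"),
                              endpoint = c("systolic", "diastolic")) {
  drug <- match.arg(drug)
  endpoint <- match.arg(endpoint)
  rows <- cohort[cohort$arm == drug, , drop = FALSE]
  pre_cols <- paste0("pre_", endpoint, "_", .bp_methods)
  post_cols <- paste0("post_", endpoint, "_", .bp_methods)
  missing_cols <- setdiff(c(pre_cols, post_cols), names(rows))
  if (length(missing_cols))
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  pre <- as.matrix(rows[, pre_cols])
  post <- as.matrix(rows[, post_cols])
  complete <- stats::complete.cases(pre) & stats::complete.cases(post)
  n_dropped <- sum(!complete)
  if (!any(complete))
    stop("empty panel: no subjects with complete ", endpoint,
         " measurements in the ", drug, " arm", call. = FALSE)
  pre <- pre[complete, , drop = FALSE]
  post <- post[complete, , drop = FALSE]
  dimnames(pre) <- dimnames(post) <- list(NULL, .bp_methods)
  cov_keep <- intersect(c(.bp_covariates, "genotype"), names(rows))
  structure(list(
    drug = drug, endpoint = endpoint,
    subject_id = rows$subject_id[complete],
    methods = .bp_methods,
    raw = post - pre,
    pretreat = pre,
    adjusted = NULL,
    adjustment_slopes = NULL,
    covariates = rows[complete, cov_keep, drop = FALSE],
    n_dropped = n_dropped
  ), class = "response_panel")
}

#' Regress out the pretreatment BP level
#'
#' For each method, fits ordinary least squares of the raw response on the
#' own-method pretreatment level (with intercept) and replaces the response
#' with residual + column mean, so the adjusted response is uncorrelated with
#' its method's pretreatment level but keeps its mmHg location.  Adjustment
#' is method-specific and univariate; the fitted slopes are recorded.
#'
#' @param panel A `response_panel` from [compute_responses()].
#' @return The panel with `adjusted` and `adjustment_slopes` filled.
#' @export
adjust_pretreatment <- function(panel) {
  stopifnot(inherits(panel, "response_panel"))
  raw <- panel$raw
  pre <- panel$pretreat
  adjusted <- raw
  slopes <- numeric(ncol(raw))
  for (m in seq_len(ncol(raw))) {
    x <- pre[, m]
    if (stats::sd(x) == 0)
      stop("degenerate design: pretreatment column '", panel$methods[m],
           "' is constant", call. = FALSE)
    b <- stats::cov(x, raw[, m]) / stats::var(x)
    adjusted[, m] <- raw[, m] - b * (x - mean(x))
    slopes[m] <- b
  }
  names(slopes) <- panel$methods
  panel$adjusted <- adjusted
  panel$adjustment_slopes <- slopes
  panel
}

#' Write or read a response panel
#'
#' Long-format CSV (`subject_id, method, raw, adjusted, pretreat`) with a
#' JSON sidecar (`<path>.json`) carrying drug, endpoint, adjustment slopes,
#' and the dropped-subject count.  Covariates are stored as extra columns so
#' the panel round-trips.
#'
#' @param panel A `response_panel`.
#' @param path CSV file path.
#' @return `write_panel()` the path, invisibly; `read_panel()` a
#'   `response_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "response_panel"))
  n <- nrow(panel$raw)
  long <- data.frame(
    subject_id = rep(panel$subject_id, times = length(panel$methods)),
    method = rep(panel$methods, each = n),
    raw = as.vector(panel$raw),
    adjusted = if (is.null(panel$adjusted)) NA_real_ else as.vector(panel$adjusted),
    pretreat = as.vector(panel$pretreat)
  )
  long <- cbind(long, panel$covariates[rep(seq_len(n), length(panel$methods)), ,
                                       drop = FALSE])
  utils::write.csv(long, path, row.names = FALSE, na = "")
  meta <- list(drug = panel$drug, endpoint = panel$endpoint,
               n_subjects = n, n_dropped = panel$n_dropped,
               adjustment_slopes = as.list(panel$adjustment_slopes))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ids <- unique(long$subject_id)
  n <- length(ids)
  mat <- function(col) {
    m <- sapply(.bp_methods, function(meth)
      long[[col]][long$method == meth][match(ids, long$subject_id[long$method == meth])])
    dimnames(m) <- list(NULL, .bp_methods)
    m
  }
  first <- long[match(ids, long$subject_id), , drop = FALSE]
  cov_keep <- intersect(c(.bp_covariates, "genotype"), names(long))
  adjusted <- mat("adjusted")
  structure(list(
    drug = meta$drug, endpoint = meta$endpoint,
    subject_id = ids, methods = .bp_methods,
    raw = mat("raw"), pretreat = mat("pretreat"),
    adjusted = if (all(is.na(adjusted))) NULL else adjusted,
    adjustment_slopes = unlist(meta$adjustment_slopes),
    covariates = first[, cov_keep, drop = FALSE],
    n_dropped = meta$n_dropped
  ), class = "response_panel")
}

#' @export
print.response_panel <- function(x, ...) {
  cat(sprintf("BP response panel: %s, %s, %d subjects (%d dropped)\n",
              x$drug, x$endpoint, nrow(x$raw), x$n_dropped))
  cat(sprintf("  raw mean response: %s mmHg\n",
              paste(sprintf("%s %.1f", x$methods, colMeans(x$raw)),
                    collapse = ", ")))
  if (!is.null(x$adjusted))
    cat(sprintf("  pretreatment slopes: %s\n",
                paste(sprintf("%.3f", x$adjustment_slopes), collapse = ", ")))
  invisible(x)
}
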