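#' Decompose response variance into signal and method noise
#'
#' Under the same-signal model every pairwise covariance between two methods'
#' adjusted responses is an unbiased estimate of the shared signal variance,
#' so the signal is estimated as the average of the six pairwise covariances
#' of the N x 4 adjusted response matrix (sample covariance, denominator
#' n - 1).  Each method's noise variance is its total variance minus the
#' signal, and its signal-to-noise ratio is signal / noise.  A noise estimate
#' can be negative when a method's variance falls below the mean covariance;
#' such estimates are reported as-is with an undefined (NA) SNR rather than
#' clipped, since silent truncation would bias the power stage.
#'
#' @param panel An adjusted `response_panel` with at least 5 subjects.
#' @return An object of class `signal_noise`; see [signal_noise_from_cov()].
#' @export
estimate_signal_noise <- function(panel) {
  stopifnot(inherits(panel, "response_panel"))
  if (is.null(panel$adjusted))
    stop("panel is not pretreatment-adjusted; run adjust_pretreatment() first",
         call. = FALSE)
  n <- nrow(panel$adjusted)
  if (n < 5) stop("insufficient data: need at least 5 subjects", call. = FALSE)
  if (!all(is.finite(panel$adjusted)))
    stop("non-finite adjusted responses", call. = FALSE)
  signal_noise_from_cov(stats::cov(panel$adjusted), n,
                        drug = panel$drug, endpoint = panel$endpoint)
}

#' Signal/noise decomposition of an inter-method covariance matrix
#'
#' The matrix form of [estimate_signal_noise()], usable directly on a
#' covariance matrix: signal = mean of the off-diagonal upper triangle,
#' noise = diagonal minus signal, SNR = signal / noise where noise > 0.
#'
#' @param cov_matrix Symmetric covariance matrix (mmHg^2), methods in rows
#'   and columns.
#' @param n_subjects Number of subjects behind the estimate (NA if unknown).
#' @param drug,endpoint Optional labels carried through.
#' @return An object of class `signal_noise` with fields `cov_matrix`,
#'   `signal_var`, `noise_vars`, `snr` (NA where noise <= 0, with the
#'   affected methods in `negative_noise`), `n_subjects`, `drug`, `endpoint`.
#' @export
signal_noise_from_cov <- function(cov_matrix, n_subjects = NA,
                                  drug = NA_character_,
                                  endpoint = NA_character_) {
  cov_matrix <- as.matrix(cov_matrix)
  if (nrow(cov_matrix) != ncol(cov_matrix) ||
      max(abs(cov_matrix - t(cov_matrix))) > 1e-8 * max(1, abs(cov_matrix)))
    stop("'cov_matrix' must be symmetric", call. = FALSE)
  if (is.null(colnames(cov_matrix)))
    colnames(cov_matrix) <- rownames(cov_matrix) <-
      .bp_methods[seq_len(ncol(cov_matrix))]
  signal <- mean(cov_matrix[upper.tri(cov_matrix)])
  noise <- diag(cov_matrix) - signal
  snr <- ifelse(noise > 0, signal / noise, NA_real_)
  names(noise) <- names(snr) <- colnames(cov_matrix)
  structure(list(
    drug = drug, endpoint = endpoint,
    cov_matrix = cov_matrix, signal_var = signal,
    noise_vars = noise, snr = snr,
    negative_noise = names(noise)[noise <= 0],
    n_subjects = n_subjects
  ), class = "signal_noise")
}

#' Minimum-variance weights over a subset of methods
#'
#' Among unit-sum linear combinations of the methods' responses, the
#' combination with the smallest variance has weights proportional to the
#' row sums of the inverse of the inter-method covariance submatrix.  The
#' weights are normalized to sum to one, which keeps the weighted average an
#' unbiased estimate of the signal (plus its mean); the combination variance
#' is `w' Sigma w`, its noise is that variance minus the signal variance, and
#' its SNR is signal / noise.
#'
#' @param x A `signal_noise` object, or a covariance matrix (then supply
#'   `signal_var` to obtain the combined noise and SNR).
#' @param methods Subset of method names (default: all columns of the
#'   covariance matrix).  A single method returns weight 1.
#' @param signal_var Signal variance; taken from `x` when it is a
#'   `signal_noise` object.
#' @return An object of class `weighted_average`: `methods`, `weights`
#'   (summing to 1), `combined_var`, `combined_noise`, `combined_snr`.
#' @examples
#' min_variance_weights(matrix(c(2, 1, 1, 4), 2,
#'                             dimnames = list(c("office", "home"),
#'                                             c("office", "home"))),
#'                      signal_var = 1)  # weights 0.75 / 0.25
#' @export
min_variance_weights <- function(x, methods = NULL, signal_var = NULL) {
  if (inherits(x, "signal_noise")) {
    Sigma <- x$cov_matrix
    if (is.null(signal_var)) signal_var <- x$signal_var
  } else {
    Sigma <- as.matrix(x)
    if (is.null(colnames(Sigma)))
      colnames(Sigma) <- rownames(Sigma) <- .bp_methods[seq_len(ncol(Sigma))]
  }
  if (is.null(methods)) methods <- colnames(Sigma)
  missing_m <- setdiff(methods, colnames(Sigma))
  if (length(missing_m))
    stop("methods not in covariance matrix: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  sub <- Sigma[methods, methods, drop = FALSE]
  if (length(methods) == 1L) {
    w <- stats::setNames(1, methods)
    cv <- sub[1, 1]
  } else {
    inv <- tryCatch(solve(sub), error = function(e) NULL)
    if (is.null(inv))
      stop("singular covariance submatrix for subset {",
           paste(methods, collapse = ", "), "}", call. = FALSE)
    rs <- rowSums(inv)
    w <- rs / sum(rs)
    cv <- drop(t(w) %*% sub %*% w)
  }
  noise <- if (is.null(signal_var)) NA_real_ else cv - signal_var
  structure(list(
    methods = methods, weights = w, combined_var = cv,
    combined_noise = noise,
    combined_snr = if (is.na(noise) || noise <= 0) NA_real_
                   else signal_var / noise,
    signal_var = signal_var
  ), class = "weighted_average")
}

#' Apply a weighted-average specification to a panel
#'
#' Per subject, the combined response is the weighted sum of the adjusted
#' responses over the spec's methods.
#'
#' @param panel An adjusted `response_panel` containing the spec's methods.
#' @param spec A `weighted_average` from [min_variance_weights()].
#' @return Numeric vector of combined responses, one per subject.
#' @export
apply_weighted_average <- function(panel, spec) {
  stopifnot(inherits(panel, "response_panel"),
            inherits(spec, "weighted_average"))
  if (is.null(panel$adjusted))
    stop("panel is not pretreatment-adjusted", call. = FALSE)
  missing_m <- setdiff(spec$methods, colnames(panel$adjusted))
  if (length(missing_m))
    stop("panel lacks methods required by the spec: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  unname(drop(panel$adjusted[, spec$methods, drop = FALSE] %*% spec$weights))
}

#' @export
print.signal_noise <- function(x, digits = 3, ...) {
  cat(sprintf("Signal/noise decomposition (%s, %s), n = %s\n",
              x$drug, x$endpoint, format(x$n_subjects)))
  cat(sprintf("  signal variance: %.*f mmHg^2\n", digits, x$signal_var))
  tab <- data.frame(method = names(x$noise_vars),
                    total = diag(x$cov_matrix),
                    noise = x$noise_vars, snr = x$snr, row.names = NULL)
  print(tab, digits = digits, row.names = FALSE)
  if (length(x$negative_noise))
    cat("  note: negative noise estimate for:",
        paste(x$negative_noise, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.weighted_average <- function(x, digits = 3, ...) {
  cat("Minimum-variance weighted average of:",
      paste(x$methods, collapse = ", "), "\n")
  cat("  weights:", paste(sprintf("%.*f", digits, x$weights), collapse = ", "),
      "\n")
  cat(sprintf("  combined variance %.*f, noise %.*f, SNR %.*f\n",
              digits, x$combined_var, digits, x$combined_noise,
              digits, x$combined_snr))
  invisible(x)
}
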