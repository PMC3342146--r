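#' Noncentrality required to detect an association
#'
#' Expected value of the association z-statistic needed so that a two-sided
#' test at level `alpha` rejects with probability `power`.  For a quantitative
#' trait tested by linear regression this is the sum of two standard-normal
#' quantiles, `qnorm(1 - alpha/2) + qnorm(power)`.  At the genome-wide level
#' 5e-8 with 80% power the value is 6.29.
#'
#' @param alpha Two-sided significance level, in (0, 1).
#' @param power Target power, in (0, 1).
#' @return The required noncentrality parameter (dimensionless).
#' @examples
#' required_ncp(5e-8, 0.80)   # 6.29
#' required_ncp(0.05, 0.50)   # 1.96: the power quantile is zero at 50%
#' @export
required_ncp <- function(alpha, power) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0, 1)", call. = FALSE)
  if (!is.numeric(power) || length(power) != 1L || is.na(power) ||
      power <= 0 || power >= 1)
    stop("'power' must be a single number in (0, 1)", call. = FALSE)
  stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
}

#' Fraction of trait variance detectable at a given noncentrality
#'
#' Inverts the large-sample relation ncp = sqrt(n * r2 / (1 - r2)) for the
#' coefficient of determination: `r2 = ncp^2 / (ncp^2 + n)`.  This is the
#' fraction of (signal) variance a polymorphism must explain to be detected
#' with the design behind `ncp`.
#'
#' @param ncp Noncentrality parameter, >= 0 (see [required_ncp()]).
#' @param n Sample size, >= 2.
#' @return Detectable `r2`, in \[0, 1).
#' @examples
#' detectable_r2(required_ncp(5e-8, 0.8), 300)  # about 0.117 (prints as 11.6-11.7%)
#' @export
detectable_r2 <- function(ncp, n) {
  if (!is.numeric(ncp) || length(ncp) != 1L || is.na(ncp) || ncp < 0)
    stop("'ncp' must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2)
    stop("'n' must be a single number >= 2", call. = FALSE)
  ncp^2 / (ncp^2 + n)
}

#' Per-allele effect size for a given explained signal fraction
#'
#' Converts a fraction `r2_signal` of the signal variance explained by an
#' additively coded biallelic polymorphism into a per-allele effect in mmHg.
#' Under Hardy-Weinberg equilibrium the genotype variance is
#' `2 * maf * (1 - maf)`, so
#' `beta = sqrt(r2_signal * signal_var / (2 * maf * (1 - maf)))`.
#'
#' @param r2_signal Fraction of signal variance explained, in \[0, 1).
#' @param signal_var Signal variance in mmHg^2, > 0.
#' @param maf Minor allele frequency, in (0, 1) excluding the endpoints.
#' @return Effect size in mmHg per allele.
#' @export
allele_effect_size <- function(r2_signal, signal_var, maf) {
  if (!is.numeric(r2_signal) || any(is.na(r2_signal)) ||
      any(r2_signal < 0) || any(r2_signal >= 1))
    stop("'r2_signal' must be in [0, 1)", call. = FALSE)
  if (!is.numeric(signal_var) || length(signal_var) != 1L ||
      is.na(signal_var) || signal_var <= 0)
    stop("'signal_var' must be a single positive number", call. = FALSE)
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf <= 0 || maf >= 1)
    stop("degenerate genotype: 'maf' must be strictly inside (0, 1)",
         call. = FALSE)
  sqrt(r2_signal * signal_var / (2 * maf * (1 - maf)))
}

#' Power of the association test at a given sample size
#'
#' Large-sample power of the two-sided additive-SNP regression test:
#' `Phi(sqrt(n * r2 / (1 - r2)) - qnorm(1 - alpha/2))`.  The opposite-tail
#' term is negligible at any usable alpha and is omitted by default; with
#' `r2 = 0` the reported value is therefore `alpha / 2` (one tail).  Set
#' `df_method = "t"` to use the noncentral-t distribution with `n - 2`
#' degrees of freedom instead of the normal approximation.
#'
#' @param n Sample size, >= 2 (>= 3 for the t option).
#' @param r2 Fraction of trait variance explained by the polymorphism under
#'   the measurement scheme, in \[0, 1).
#' @param alpha Two-sided significance level.
#' @param df_method `"normal"` (default) or `"t"`.
#' @return Power, in (0, 1).
#' @export
power_at_n <- function(n, r2, alpha, df_method = c("normal", "t")) {
  df_method <- match.arg(df_method)
  if (!is.numeric(n) || any(is.na(n)) || any(n < 2))
    stop("'n' must be >= 2", call. = FALSE)
  if (!is.numeric(r2) || any(is.na(r2)) || any(r2 < 0) || any(r2 >= 1))
    stop("'r2' must be in [0, 1)", call. = FALSE)
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1))
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  delta <- sqrt(n * r2 / (1 - r2))
  if (df_method == "normal") {
    stats::pnorm(delta - stats::qnorm(1 - alpha / 2))
  } else {
    df <- n - 2
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = delta, lower.tail = FALSE)
  }
}

#' Sample size required for a target power
#'
#' Inverts the power relation: `n = ceiling(ncp^2 * (1 - r2) / r2)` where
#' `ncp = required_ncp(alpha, power)`.  The unrounded value is attached as
#' attribute `"n_exact"`.
#'
#' @param r2 Fraction of trait variance explained under the scheme, in (0, 1).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Integer-valued sample size (ceiling), with attribute `n_exact`.
#'   `r2 = 0` returns `Inf` with a warning (no finite design detects it).
#' @export
sample_size_for_power <- function(r2, alpha, power) {
  if (!is.numeric(r2) || length(r2) != 1L || is.na(r2) || r2 < 0 || r2 >= 1)
    stop("'r2' must be a single number in [0, 1)", call. = FALSE)
  if (r2 == 0) {
    warning("r2 = 0: required sample size is unbounded", call. = FALSE)
    return(structure(Inf, n_exact = Inf))
  }
  ncp <- required_ncp(alpha, power)
  n_exact <- ncp^2 * (1 - r2) / r2
  structure(ceiling(n_exact), n_exact = n_exact)
}

#' Power table across measurement schemes
#'
#' For a signal/noise decomposition and optional weighted-average schemes,
#' tabulates for each scheme the variance-inflation factor
#' `lambda = 1 + 1/SNR`, the attenuated detectable fraction
#' `r2_scheme = r2_signal / lambda`, the power at the reference sample size,
#' and the sample size maintaining the reference power.  The first row is the
#' perfect noise-free measurement of the signal itself (`lambda = 1`), for
#' which power and sample size equal the reference values by construction.
#' Schemes whose noise estimate is negative (SNR undefined) are kept as
#' all-`NA` rows with a warning.
#'
#' @param decomposition A `signal_noise` object (see [estimate_signal_noise()]).
#' @param weighted_specs Optional list of `weighted_average` objects (see
#'   [min_variance_weights()]); each contributes one scheme row.
#' @param spec A `power_spec` (see [power_spec()]).
#' @return A data frame of class `power_table` with one row per scheme:
#'   `scheme`, `snr`, `lambda`, `r2_pct`, `power_at_n_ref`, `n_exact`,
#'   `n_for_target_power`.  The implied per-allele effect on the signal is
#'   attached as attribute `beta_per_allele`.
#' @export
scheme_power_table <- function(decomposition, weighted_specs = list(), spec = power_spec()) {
  stopifnot(inherits(decomposition, "signal_noise"), inherits(spec, "power_spec"))
  ncp <- required_ncp(spec$alpha, spec$power_ref)
  r2_signal <- detectable_r2(ncp, spec$n_ref)

  snrs <- c(signal = Inf, decomposition$snr)
  for (w in weighted_specs) {
    stopifnot(inherits(w, "weighted_average"))
    snrs[paste0("weighted_", paste(w$methods, collapse = "+"))] <- w$combined_snr
  }
  if (anyNA(snrs))
    warning("schemes with negative noise (undefined SNR) reported as NA rows: ",
            paste(names(snrs)[is.na(snrs)], collapse = ", "), call. = FALSE)

  lambda <- 1 + 1 / snrs
  r2s <- r2_signal / lambda
  pw <- vapply(r2s, function(r)
    if (is.na(r)) NA_real_ else power_at_n(spec$n_ref, r, spec$alpha),
    numeric(1))
  n_exact <- ncp^2 * (1 - r2s) / r2s
  out <- data.frame(
    scheme = names(snrs),
    snr = as.numeric(snrs),
    lambda = as.numeric(lambda),
    r2_pct = 100 * as.numeric(r2s),
    power_at_n_ref = as.numeric(pw),
    n_exact = as.numeric(n_exact),
    n_for_target_power = ceiling(as.numeric(n_exact)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "spec") <- spec
  attr(out, "r2_signal") <- r2_signal
  attr(out, "beta_per_allele") <-
    allele_effect_size(r2_signal, decomposition$signal_var, spec$maf)
  class(out) <- c("power_table", "data.frame")
  out
}

#' Association-design assumptions for the power stage
#'
#' @param maf Minor allele frequency of the hypothesized polymorphism.
#' @param alpha Two-sided significance level (genome-wide 5e-8 by default).
#' @param n_ref Reference sample size at which the effect is just detectable.
#' @param power_ref Reference power at `n_ref`.
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(maf = 0.2, alpha = 5e-8, n_ref = 300, power_ref = 0.8) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop("'maf' must be in (0, 0.5]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (power_ref <= 0 || power_ref >= 1)
    stop("'power_ref' must be in (0, 1)", call. = FALSE)
  if (n_ref < 2) stop("'n_ref' must be >= 2", call. = FALSE)
  structure(list(maf = maf, alpha = alpha, n_ref = n_ref, power_ref = power_ref),
            class = "power_spec")
}

#' Monte-Carlo validation of the analytic power engine
#'
#' Simulates the two-sided Wald test of an additive biallelic polymorphism in
#' single-SNP linear regression and reports the empirical rejection rate.
#' Genotypes are Binomial(2, maf); the trait is genotype effect plus normal
#' noise.  The Wald statistic uses the maximum-likelihood residual variance
#' and the standard-normal critical value, matching the large-sample theory
#' behind [power_at_n()].
#'
#' Two effect-size conventions are offered.  `"realized"` (default) scales the
#' effect within each replicate so the drawn genotypes explain exactly `r2` of
#' the trait variance -- the conditional-on-design convention the analytic
#' formula describes.  `"population"` fixes the effect from population
#' variances (`beta = sqrt(r2 / (2 maf (1-maf)))`, residual SD
#' `sqrt(1 - r2)`), letting the realized genotype variance fluctuate; at
#' extreme alpha this sits visibly below the analytic value because of the
#' far-tail t-distribution of the statistic.
#'
#' @param n Sample size per replicate.
#' @param r2 Population fraction of trait variance explained.
#' @param alpha Two-sided significance level.
#' @param maf Minor allele frequency.
#' @param reps Number of replicates.
#' @param effect `"realized"` or `"population"` (see Details).
#' @param chunk Replicates simulated per vectorized block.
#' @return Empirical rejection rate, with attributes `se` (binomial standard
#'   error) and `reps`.
#' @export
simulate_snp_power <- function(n, r2, alpha, maf = 0.2, reps = 10000,
                               effect = c("realized", "population"),
                               chunk = 2000) {
  effect <- match.arg(effect)
  stopifnot(n >= 4, r2 >= 0, r2 < 1, alpha > 0, alpha < 1,
            maf > 0, maf < 1, reps >= 1)
  crit2 <- stats::qnorm(1 - alpha / 2)^2
  beta_pop <- sqrt(r2 / (2 * maf * (1 - maf)))
  sig_e <- sqrt(1 - r2)
  rej <- 0L
  done <- 0L
  while (done < reps) {
    k <- min(chunk, reps - done)
    G <- matrix(stats::rbinom(n * k, 2L, maf), n, k)
    Gc <- sweep(G, 2, colMeans(G))
    sxx <- colSums(Gc^2)
    ok <- sxx > 0  # monomorphic draws carry no test; count as non-rejections
    b <- if (effect == "realized")
      sqrt(r2 / (1 - r2)) * sig_e * sqrt(n / pmax(sxx, 1)) else beta_pop
    Y <- sweep(Gc, 2, b, "*") + matrix(stats::rnorm(n * k, 0, sig_e), n, k)
    Yc <- sweep(Y, 2, colMeans(Y))
    sxy <- colSums(Gc * Yc)
    syy <- colSums(Yc^2)
    rss <- syy - ifelse(ok, sxy^2 / sxx, 0)
    z2 <- ifelse(ok, (sxy / sxx)^2 * sxx / (rss / n), 0)
    rej <- rej + sum(z2 > crit2)
    done <- done + k
  }
  rate <- rej / reps
  structure(rate, se = sqrt(rate * (1 - rate) / reps), reps = reps)
}

#' @export
print.power_table <- function(x, digits = 3, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Power table: maf=%g, alpha=%g, reference N=%d at %.0f%% power\n",
              spec$maf, spec$alpha, as.integer(spec$n_ref), 100 * spec$power_ref))
  cat(sprintf("Detectable signal fraction r2 = %.4f; per-allele effect on signal = %.2f mmHg\n",
              attr(x, "r2_signal"), attr(x, "beta_per_allele")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
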