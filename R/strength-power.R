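#' Overall instrument-strength F statistic
#'
#' `F = (N - k - 1)/k * r2/(1 - r2)`: the regression F statistic for k
#' instruments jointly explaining a fraction `r2` of exposure variance in a
#' sample of size N. Values above 10 conventionally indicate that
#' weak-instrument bias is negligible.
#'
#' @param N Exposure-GWAS sample size (must exceed `k + 1`).
#' @param k Number of instruments.
#' @param r2 Variance in the exposure explained by the instruments, in (0, 1).
#' @return The F value.
#' @export
f_overall <- function(N, k, r2) {
  if (!(N > k + 1)) stop_mrscreen("config", "need N > k + 1")
  if (!(r2 > 0 && r2 < 1)) stop_mrscreen("config", "r2 must lie in (0, 1)")
  (N - k - 1) / k * r2 / (1 - r2)
}

#' Approximate per-variant F statistics
#'
#' The squared z statistic `(beta_exp/se_exp)^2`, a large-sample
#' approximation to the single-variant regression F. It is labeled
#' approximate because published per-variant F columns are often computed
#' from unprinted per-variant variance-explained values and do not equal the
#' squared z of the printed beta/SE; this function never attempts to
#' reproduce such columns.
#'
#' @param ds An `mr_harmonized` dataset (or any data frame with `rsid`,
#'   `beta_exp`, `se_exp` columns).
#' @return Data frame with `rsid` and `f_approx`.
#' @export
f_per_snp <- function(ds) {
  ins <- if (inherits(ds, "mr_harmonized")) ds$instruments else ds
  if (any(ins$se_exp <= 0)) stop_mrscreen("data", "se_exp must be > 0")
  data.frame(rsid = ins$rsid, f_approx = (ins$beta_exp / ins$se_exp)^2,
             stringsAsFactors = FALSE)
}

#' Statistical power for a binary-outcome MR analysis
#'
#' Standard normal approximation for a two-sample MR study of a continuous
#' exposure (instrumented with variance explained `r2`) on a binary outcome:
#' `power = Phi( sqrt(n_total * r2 * K * (1 - K)) * |log(or_alt)| -
#' z_{1-alpha/2} )`, where K is the case fraction of the outcome GWAS. All
#' parameters are explicit inputs — nothing is defaulted silently — and are
#' echoed in the result.
#'
#' @param n_total Outcome-GWAS total sample size (cases + controls).
#' @param case_fraction K, the fraction of cases, in (0, 1).
#' @param r2 Instrument variance explained on the exposure, in (0, 1).
#' @param alpha Two-sided type-I error rate, in (0, 1); default 0.05.
#' @param or_alt Odds ratio per SD of exposure under the alternative.
#' @return A list of class `mr_power`: `power` plus every input echoed.
#' @export
power_binary <- function(n_total, case_fraction, r2, alpha = 0.05, or_alt) {
  if (!(n_total > 0)) stop_mrscreen("config", "n_total must be positive")
  if (!(case_fraction > 0 && case_fraction < 1)) {
    stop_mrscreen("config", "case_fraction must lie in (0, 1)")
  }
  if (!(r2 > 0 && r2 < 1)) stop_mrscreen("config", "r2 must lie in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop_mrscreen("config", "alpha must lie in (0, 1)")
  if (!(or_alt > 0)) stop_mrscreen("config", "or_alt must be positive")
  ncp <- sqrt(n_total * r2 * case_fraction * (1 - case_fraction)) *
    abs(log(or_alt))
  power <- stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
  structure(list(power = power, n_total = n_total,
                 case_fraction = case_fraction, r2 = r2, alpha = alpha,
                 or_alt = or_alt),
            class = "mr_power")
}
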