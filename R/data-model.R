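#' Construct a summary-statistics table
#'
#' A summary-statistics table holds one row per variant: the association of
#' that variant with a single trait, on the scale the source GWAS reports
#' (standard-deviation units for a continuous exposure, log-odds for a binary
#' outcome).
#'
#' @param rsid Character vector of variant identifiers (unique).
#' @param effect_allele,other_allele Allele strings (A/C/G/T or indel
#'   sequences); uppercased on construction.
#' @param beta Signed per-allele effect sizes.
#' @param se Standard errors of `beta`; strictly positive.
#' @param pval Association p-values in (0, 1].
#' @param eaf Optional effect-allele frequencies in (0, 1); `NA` means
#'   unknown (never imputed to 0 or 0.5 — palindrome screening must be able
#'   to distinguish "unknown" from "balanced").
#' @param n Optional per-variant sample sizes.
#' @param trait_label Short label naming the trait.
#'
#' @return A data frame of class `mr_sumstats` with columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`, `eaf`, `n` and a
#'   `trait_label` attribute.
#' @export
summary_stats <- function(rsid, effect_allele, other_allele, beta, se, pval,
                          eaf = NA_real_, n = NA_real_,
                          trait_label = "trait") {
  x <- data.frame(
    rsid = as.character(rsid),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    beta = as.numeric(beta),
    se = as.numeric(se),
    pval = as.numeric(pval),
    eaf = as.numeric(eaf),
    n = as.numeric(n),
    stringsAsFactors = FALSE
  )
  validate_summary_stats(x)
  attr(x, "trait_label") <- trait_label
  class(x) <- c("mr_sumstats", "data.frame")
  x
}

validate_summary_stats <- function(x) {
  if (anyDuplicated(x$rsid)) {
    dup <- unique(x$rsid[duplicated(x$rsid)])
    stop_mrscreen("data", "duplicate rsid(s): ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(x$beta))) {
    stop_mrscreen("data", "missing or non-numeric beta for: ",
                  paste(x$rsid[!is.finite(x$beta)], collapse = ", "))
  }
  if (any(!is.finite(x$se)) || any(x$se <= 0)) {
    bad <- x$rsid[!is.finite(x$se) | x$se <= 0]
    stop_mrscreen("data", "se must be finite and > 0; offending rsid(s): ",
                  paste(bad, collapse = ", "))
  }
  ok_p <- is.finite(x$pval) & x$pval > 0 & x$pval <= 1
  if (any(!ok_p)) {
    stop_mrscreen("data", "pval must lie in (0, 1]; offending rsid(s): ",
                  paste(x$rsid[!ok_p], collapse = ", "))
  }
  empty <- !nzchar(x$effect_allele) | !nzchar(x$other_allele)
  if (any(empty)) {
    stop_mrscreen("data", "empty allele for: ",
                  paste(x$rsid[empty], collapse = ", "))
  }
  same <- x$effect_allele == x$other_allele
  if (any(same)) {
    stop_mrscreen("data", "effect and other allele identical for: ",
                  paste(x$rsid[same], collapse = ", "))
  }
  invisible(x)
}

#' Construct a harmonized two-sample dataset
#'
#' Pairs each instrument's exposure association (gamma, se_gamma) with its
#' outcome association (Gamma, se_Gamma) expressed on the same effect allele,
#' together with the exclusion log produced during harmonization.
#'
#' @param instruments Data frame with columns `rsid`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf`, `flipped`.
#' @param exclusions Data frame with columns `rsid`, `reason` (zero rows if
#'   nothing was dropped).
#' @return An object of class `mr_harmonized`.
#' @export
harmonized_dataset <- function(instruments,
                               exclusions = data.frame(rsid = character(),
                                                       reason = character())) {
  stopifnot(all(c("rsid", "beta_exp", "se_exp", "beta_out", "se_out") %in%
                  names(instruments)))
  if (is.null(instruments$eaf)) instruments$eaf <- NA_real_
  if (is.null(instruments$flipped)) instruments$flipped <- FALSE
  if (nrow(instruments) > 0 &&
      (any(instruments$se_exp <= 0) || any(instruments$se_out <= 0))) {
    stop_mrscreen("data", "harmonized standard errors must be > 0")
  }
  if (length(intersect(instruments$rsid, exclusions$rsid)) > 0) {
    stop_mrscreen("data", "a variant cannot be both instrument and exclusion")
  }
  structure(list(instruments = instruments, exclusions = exclusions),
            class = "mr_harmonized")
}

#' Number of instruments in a harmonized dataset
#' @param ds An `mr_harmonized` object.
#' @return Integer count of retained instruments.
#' @export
n_instruments <- function(ds) nrow(ds$instruments)

#' Construct a causal-effect estimate record
#'
#' One method's causal estimate: the slope on the log-odds-per-SD scale,
#' its standard error, 95% confidence interval, p-value, and the same
#' quantities exponentiated to the odds-ratio scale.
#'
#' @param method One of `"wald_ratio"`, `"ivw_fixed"`, `"ivw_mre"`,
#'   `"egger"`, `"weighted_median"`.
#' @param n_snps Number of instruments used.
#' @param beta,se Point estimate and standard error.
#' @param ci_low,ci_high 95% interval bounds on the beta scale.
#' @param p Two-sided p-value.
#' @return One-row data frame of class `mr_estimate` with columns `method`,
#'   `n_snps`, `beta`, `se`, `ci_low`, `ci_high`, `p`, `or`, `or_low`,
#'   `or_high`.
#' @export
mr_estimate <- function(method, n_snps, beta, se, ci_low, ci_high, p) {
  method <- match.arg(method, c("wald_ratio", "ivw_fixed", "ivw_mre",
                                "egger", "weighted_median"))
  stopifnot(ci_low <= beta + 1e-12, beta <= ci_high + 1e-12, p > 0, p <= 1)
  out <- data.frame(
    method = method, n_snps = as.integer(n_snps),
    beta = beta, se = se, ci_low = ci_low, ci_high = ci_high, p = p,
    or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized two-sample MR dataset: %d instrument(s), %d exclusion(s)\n",
              nrow(x$instruments), nrow(x$exclusions)))
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$reason)
    for (r in names(tab)) cat(sprintf("  excluded (%s): %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (nSNP = %d): OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$method, x$n_snps, x$or, x$or_low, x$or_high, x$p))
  invisible(x)
}

# classed conditions so callers can distinguish configuration, data and
# analysis failures
stop_mrscreen <- function(type = c("config", "data", "analysis", "io"), ...) {
  type <- match.arg(type)
  msg <- paste0(...)
  cond <- structure(
    class = c(paste0("mrscreen_", type, "_error"), "mrscreen_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
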