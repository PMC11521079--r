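#' Is an allele pair palindromic?
#'
#' A palindromic (strand-ambiguous) variant has alleles that are each
#' other's complement — {A,T} or {C,G} — so the same pair is reported on
#' either strand and cannot be oriented from summary data alone. Indels and
#' multi-base alleles are never palindromic.
#'
#' @param effect_allele,other_allele Allele strings (vectorized).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele)
  b <- toupper(other_allele)
  snp <- nchar(a) == 1L & nchar(b) == 1L
  snp & ((a == "A" & b == "T") | (a == "T" & b == "A") |
           (a == "C" & b == "G") | (a == "G" & b == "C"))
}

strand_complement <- function(allele) {
  chartr("ACGT", "TGCA", toupper(allele))
}

#' Harmonization and instrument-screening configuration
#'
#' @param palindrome_policy How to treat palindromic variants:
#'   `"drop_ambiguous"` (default) drops those whose effect-allele frequency
#'   lies inside `ambiguous_eaf_window` or is unknown; `"drop_all"` drops
#'   every palindromic variant; `"keep"` retains them all — appropriate only
#'   for instrument lists already screened for strand ambiguity upstream,
#'   such as a published post-screening table.
#' @param ambiguous_eaf_window Symmetric interval around 0.5 inside which a
#'   palindromic variant's frequency is considered uninformative about
#'   strand; default `c(0.42, 0.58)`.
#' @param pval_threshold Exposure-significance cutoff applied to instruments
#'   (default `5e-9`, the genome-wide threshold used to select the published
#'   instruments).
#' @param deny_list Character vector of rsids excluded a priori (e.g.
#'   variants associated with confounders of the exposure-outcome pair).
#' @param try_strand_flip If `TRUE`, a non-palindromic allele mismatch is
#'   retried after complementing the outcome alleles (A<->T, C<->G) before
#'   being excluded. Off by default: exclusion is the conservative choice.
#' @return A list of class `mr_harmonization_config`.
#' @export
harmonization_config <- function(palindrome_policy = c("drop_ambiguous",
                                                       "drop_all", "keep"),
                                 ambiguous_eaf_window = c(0.42, 0.58),
                                 pval_threshold = 5e-9,
                                 deny_list = character(),
                                 try_strand_flip = FALSE) {
  palindrome_policy <- match.arg(palindrome_policy)
  w <- ambiguous_eaf_window
  if (length(w) != 2 || !(0 < w[1] && w[1] < 0.5 && 0.5 < w[2] && w[2] < 1)) {
    stop_mrscreen("config",
                  "ambiguous_eaf_window must satisfy 0 < low < 0.5 < high < 1")
  }
  if (!is.numeric(pval_threshold) || pval_threshold <= 0 || pval_threshold > 1) {
    stop_mrscreen("config", "pval_threshold must lie in (0, 1]")
  }
  structure(list(palindrome_policy = palindrome_policy,
                 ambiguous_eaf_window = w,
                 pval_threshold = pval_threshold,
                 deny_list = as.character(deny_list),
                 try_strand_flip = try_strand_flip),
            class = "mr_harmonization_config")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every variant shared by the two tables
#' to the exposure's effect allele, then applies the instrument screens:
#' exposure-significance threshold, deny-list, and palindrome policy. When
#' the outcome reports the same allele pair with the roles swapped, the
#' outcome beta is negated, its frequency complemented, and the variant
#' marked `flipped`. Irreconcilable allele pairs (optionally after strand
#' complementing, see [harmonization_config()]) are excluded, never guessed.
#' Every exclusion is logged with a reason; variants present in only one
#' table are not part of the analysis and are not logged.
#'
#' Instruments are assumed LD-pruned upstream (published instrument lists
#' are); no clumping is attempted here.
#'
#' @param exposure,outcome `mr_sumstats` tables.
#' @param config An [harmonization_config()].
#' @return An `mr_harmonized` dataset; `instruments` keeps the exposure
#'   table's row order.
#' @export
harmonize <- function(exposure, outcome, config = harmonization_config()) {
  stopifnot(inherits(exposure, "mr_sumstats"), inherits(outcome, "mr_sumstats"))
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    stop_mrscreen("analysis", "exposure and outcome tables must be non-empty")
  }
  shared <- exposure$rsid[exposure$rsid %in% outcome$rsid]
  if (length(shared) == 0) {
    stop_mrscreen("analysis",
                  "no variant shared between exposure and outcome tables")
  }
  e <- exposure[match(shared, exposure$rsid), , drop = FALSE]
  o <- outcome[match(shared, outcome$rsid), , drop = FALSE]

  same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swap <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  unresolved <- !(same | swap)
  if (config$try_strand_flip && any(unresolved)) {
    # retry on the complementary strand; palindromic pairs gain nothing here
    # because their complement is the same unordered pair
    cea <- strand_complement(o$effect_allele)
    coa <- strand_complement(o$other_allele)
    pure <- grepl("^[ACGT]+$", o$effect_allele) & grepl("^[ACGT]+$", o$other_allele)
    c_same <- unresolved & pure & cea == e$effect_allele & coa == e$other_allele
    c_swap <- unresolved & pure & cea == e$other_allele & coa == e$effect_allele
    same <- same | c_same
    swap <- swap | c_swap
    unresolved <- !(same | swap)
  }

  beta_out <- ifelse(swap, -o$beta, o$beta)
  eaf_out <- ifelse(swap, 1 - o$eaf, o$eaf)
  eaf <- ifelse(is.na(e$eaf), eaf_out, e$eaf)

  reason <- rep(NA_character_, length(shared))
  reason[unresolved] <- "allele_mismatch"
  pend <- is.na(reason)
  reason[pend & shared %in% config$deny_list] <- "deny_list"
  pend <- is.na(reason)
  reason[pend & e$pval >= config$pval_threshold] <- "exposure_pval"
  pend <- is.na(reason)
  pal <- is_palindromic(e$effect_allele, e$other_allele)
  if (config$palindrome_policy == "drop_all") {
    reason[pend & pal] <- "palindromic"
  } else if (config$palindrome_policy == "drop_ambiguous") {
    w <- config$ambiguous_eaf_window
    ambiguous <- is.na(eaf) | (eaf >= w[1] & eaf <= w[2])
    reason[pend & pal & ambiguous] <- "palindromic_ambiguous"
  }

  keep <- is.na(reason)
  instruments <- data.frame(
    rsid = shared[keep],
    beta_exp = e$beta[keep], se_exp = e$se[keep],
    beta_out = beta_out[keep], se_out = o$se[keep],
    eaf = eaf[keep], flipped = swap[keep],
    stringsAsFactors = FALSE
  )
  exclusions <- data.frame(rsid = shared[!keep], reason = reason[!keep],
                           stringsAsFactors = FALSE)
  harmonized_dataset(instruments, exclusions)
}

#' Exclude confounder-associated instruments
#'
#' Moves any instrument whose rsid is on the deny-list into the exclusion
#' log with reason `"confounder-associated"`. Idempotent; exclusions already
#' logged are untouched.
#'
#' @param ds An `mr_harmonized` dataset.
#' @param rsids Character vector of rsids to exclude.
#' @return The filtered `mr_harmonized` dataset.
#' @export
apply_deny_list <- function(ds, rsids) {
  stopifnot(inherits(ds, "mr_harmonized"))
  hit <- ds$instruments$rsid %in% rsids
  if (!any(hit)) return(ds)
  moved <- data.frame(rsid = ds$instruments$rsid[hit],
                      reason = "confounder-associated",
                      stringsAsFactors = FALSE)
  harmonized_dataset(ds$instruments[!hit, , drop = FALSE],
                     rbind(ds$exclusions, moved))
}
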