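#' Configuration for the two-sample summary-statistics generator
#'
#' Describes a linear causal model on summary statistics: each instrument j
#' has a true exposure effect gamma_j and a true outcome effect
#' `Gamma_j = theta * gamma_j + alpha_j`, where `alpha_j` is a direct
#' (horizontally pleiotropic) effect that is zero for valid instruments and
#' drawn `N(alpha_mean, alpha_sd)` for an `invalid_fraction` share of them.
#' Observed effects are the truths plus per-study sampling noise with
#' standard errors `se_scale / sqrt(2 * maf * (1 - maf) * n_eff)`, where the
#' outcome's effective size is `n_out * case_fraction * (1 - case_fraction)`
#' (binary trait on the log-odds scale) and the per-study scale factors
#' absorb the excess of real GWAS standard errors over that idealization
#' (covariate adjustment, meta-analytic heterogeneity, imputation).
#' Pleiotropic effects are drawn independently of instrument strength, so
#' the InSIDE condition holds by construction.
#'
#' Defaults emulate the packaged 63-instrument screen-time/retinopathy
#' dataset: sample sizes, case mix, SE magnitudes and instrument strengths
#' are calibrated to the published table (see the methods vignette).
#'
#' @param L Number of instruments.
#' @param theta True causal effect (log-odds of outcome per SD of exposure).
#' @param gamma_mean,gamma_sd Mean and SD of the true exposure-effect
#'   magnitudes; `gamma_sign` (+1 or -1) sets the sign convention (trait
#'   coding is arbitrary; the published instruments are almost all negative).
#' @param maf_range Allele-frequency range, drawn uniformly; must lie within
#'   (0.05, 0.5).
#' @param n_exp,n_out Per-study sample sizes driving the SE magnitudes.
#' @param case_fraction Outcome case fraction K in (0, 1).
#' @param se_scale_exp,se_scale_out Per-study SE scale factors (>= 1 for
#'   realistic data).
#' @param invalid_fraction Share of instruments given a direct effect, in
#'   [0, 1].
#' @param alpha_mean,alpha_sd Moments of the direct effects (log-odds);
#'   `alpha_mean != 0` makes the pleiotropy directional, `alpha_mean = 0`
#'   with `alpha_sd > 0` balanced.
#' @param palindromic_fraction Share of instruments assigned A/T or C/G
#'   allele pairs.
#' @param seed Integer RNG seed; generation is byte-reproducible under it.
#' @return A list of class `mr_sim_config`.
#' @export
simulation_config <- function(L = 63L,
                              theta = 0.2,
                              gamma_mean = 0.065,
                              gamma_sd = 0.012,
                              gamma_sign = -1,
                              maf_range = c(0.1, 0.4),
                              n_exp = 468924,
                              n_out = 319046,
                              case_fraction = 10413 / 319046,
                              se_scale_exp = 1.7,
                              se_scale_out = 1.0,
                              invalid_fraction = 0,
                              alpha_mean = 0,
                              alpha_sd = 0,
                              palindromic_fraction = 2 / 63,
                              seed = 1L) {
  if (L < 1) stop_mrscreen("config", "L must be >= 1")
  fracs <- c(invalid_fraction, palindromic_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop_mrscreen("config", "fractions must lie in [0, 1]")
  }
  if (!(maf_range[1] >= 0.05 && maf_range[2] <= 0.5 &&
          maf_range[1] < maf_range[2])) {
    stop_mrscreen("config", "maf_range must lie within (0.05, 0.5)")
  }
  if (!(case_fraction > 0 && case_fraction < 1)) {
    stop_mrscreen("config", "case_fraction must lie in (0, 1)")
  }
  if (!gamma_sign %in% c(-1, 1)) stop_mrscreen("config", "gamma_sign is +1 or -1")
  structure(list(L = as.integer(L), theta = theta, gamma_mean = gamma_mean,
                 gamma_sd = gamma_sd, gamma_sign = gamma_sign,
                 maf_range = maf_range, n_exp = n_exp, n_out = n_out,
                 case_fraction = case_fraction,
                 se_scale_exp = se_scale_exp, se_scale_out = se_scale_out,
                 invalid_fraction = invalid_fraction,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 palindromic_fraction = palindromic_fraction,
                 seed = as.integer(seed)),
            class = "mr_sim_config")
}

#' Paper-scale simulation scenario
#'
#' The [simulation_config()] whose generated tables match the packaged
#' 63-instrument dataset's dimensions and noise: 63 instruments, exposure
#' SEs with median near 0.004 (range within 0.003-0.015), outcome SEs near
#' 0.016, instrument strengths in the published per-variant F range, a
#' 10,413-case / 308,633-control binary outcome, and every exposure
#' p-value below the genome-wide 5e-9 threshold because effects are drawn
#' at genome-wide-significant strength.
#'
#' @param theta True causal effect; default 0.2 (about the size estimated on
#'   the packaged dataset).
#' @param invalid_fraction,alpha_mean,alpha_sd Pleiotropy settings, default
#'   none.
#' @param seed RNG seed.
#' @return An `mr_sim_config`.
#' @export
make_paperlike_scenario <- function(theta = 0.2, invalid_fraction = 0,
                                    alpha_mean = 0, alpha_sd = 0, seed = 1L) {
  simulation_config(theta = theta, invalid_fraction = invalid_fraction,
                    alpha_mean = alpha_mean, alpha_sd = alpha_sd, seed = seed)
}

non_palindromic_pairs <- rbind(
  c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T")
)

#' Generate a paired exposure/outcome summary-statistics dataset
#'
#' Draws truths and observed summary statistics under the model described in
#' [simulation_config()]. The two returned tables use identical rsids and
#' allele assignments (already strand-aligned), emit the same TSV dialect
#' [read_summary_stats()] consumes, and are byte-identical across repeated
#' calls with the same config.
#'
#' @param cfg An `mr_sim_config`.
#' @return A list with `exposure` and `outcome` (`mr_sumstats`) and `truth`:
#'   a list of class `mr_sim_truth` holding the config echo, `theta`, and a
#'   per-variant data frame (`rsid`, `maf`, `gamma`, `alpha`, `invalid`,
#'   `palindromic`).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "mr_sim_config"))
  L <- cfg$L
  with_seed(cfg$seed, {
    maf <- stats::runif(L, cfg$maf_range[1], cfg$maf_range[2])
    se_exp <- cfg$se_scale_exp / sqrt(2 * maf * (1 - maf) * cfg$n_exp)
    eff_out <- cfg$n_out * cfg$case_fraction * (1 - cfg$case_fraction)
    se_out <- cfg$se_scale_out / sqrt(2 * maf * (1 - maf) * eff_out)
    gamma <- cfg$gamma_sign * abs(stats::rnorm(L, cfg$gamma_mean, cfg$gamma_sd))
    n_invalid <- round(cfg$invalid_fraction * L)
    invalid <- rep(FALSE, L)
    invalid[sample.int(L, n_invalid)] <- TRUE
    alpha <- numeric(L)
    alpha[invalid] <- stats::rnorm(n_invalid, cfg$alpha_mean, cfg$alpha_sd)
    beta_exp <- stats::rnorm(L, gamma, se_exp)
    beta_out <- stats::rnorm(L, cfg$theta * gamma + alpha, se_out)

    n_pal <- round(cfg$palindromic_fraction * L)
    palindromic <- rep(FALSE, L)
    palindromic[sample.int(L, n_pal)] <- TRUE
    pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    pick_pal <- pal_pairs[sample.int(nrow(pal_pairs), L, replace = TRUE), ,
                          drop = FALSE]
    pick_non <- non_palindromic_pairs[
      sample.int(nrow(non_palindromic_pairs), L, replace = TRUE), ,
      drop = FALSE]
    ea <- ifelse(palindromic, pick_pal[, 1], pick_non[, 1])
    oa <- ifelse(palindromic, pick_pal[, 2], pick_non[, 2])
    rsid <- sprintf("rs%07d", seq_len(L))

    # floor protects the (0,1] p-value invariant from underflow at huge z
    z_to_p <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
    exposure <- summary_stats(
      rsid = rsid, effect_allele = ea, other_allele = oa,
      beta = beta_exp, se = se_exp, pval = z_to_p(beta_exp / se_exp),
      eaf = maf, n = cfg$n_exp, trait_label = "simulated exposure (SD)"
    )
    outcome <- summary_stats(
      rsid = rsid, effect_allele = ea, other_allele = oa,
      beta = beta_out, se = se_out, pval = z_to_p(beta_out / se_out),
      eaf = maf, n = cfg$n_out, trait_label = "simulated outcome (log-odds)"
    )
    truth <- structure(
      list(config = cfg, theta = cfg$theta,
           snps = data.frame(rsid = rsid, maf = maf, gamma = gamma,
                             alpha = alpha, invalid = invalid,
                             palindromic = palindromic,
                             stringsAsFactors = FALSE)),
      class = "mr_sim_truth")
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}
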