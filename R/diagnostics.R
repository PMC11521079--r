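#' Cochran heterogeneity statistic
#'
#' For `method = "ivw"`: the weighted sum of squared deviations of the
#' per-variant Wald ratios about the *fixed-effect* IVW estimate, with
#' first-order weights `(se_out/|beta_exp|)^-2` and L-1 degrees of freedom.
#' The fixed-effect center is used even when the reported estimate is
#' random-effects, so that the dispersion `phi^2 = Q/(L-1)` used by
#' [mr_ivw()] is coherent. For `method = "egger"`: the weighted residual sum
#' of squares of the intercept model (Rucker's Q'), L-2 degrees of freedom.
#' The p-value is the upper chi-square tail.
#'
#' @param ds An `mr_harmonized` dataset.
#' @param method `"ivw"` (default) or `"egger"`.
#' @return One-row data frame of class `mr_heterogeneity`: `method`, `Q`,
#'   `df`, `p`.
#' @export
cochran_q <- function(ds, method = c("ivw", "egger")) {
  method <- match.arg(method)
  L <- n_instruments(ds)
  if (method == "ivw") {
    if (L < 2) stop_mrscreen("analysis", "Cochran Q needs >= 2 instruments")
    ins <- ds$instruments
    b <- ivw_core(ins$beta_exp, ins$beta_out, ins$se_out)$beta
    rw <- ratio_weights(ds)
    Q <- sum(rw$w * (rw$ratio - b)^2)
    df <- L - 1L
  } else {
    if (L < 3) stop_mrscreen("analysis", "Egger Q' needs >= 3 instruments")
    fit <- mr_egger(ds)
    Q <- fit$q_prime
    df <- fit$df
  }
  out <- data.frame(method = method, Q = Q, df = df,
                    p = stats::pchisq(Q, df, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_heterogeneity", "data.frame")
  out
}

#' Egger-intercept pleiotropy test
#'
#' Repackages the intercept of an [mr_egger()] fit as a directional
#' pleiotropy test: the intercept estimates the average direct (pleiotropic)
#' effect of the instruments on the outcome under InSIDE, and differs from
#' zero when pleiotropy is directional. Inference is t with L-2 degrees of
#' freedom; `pleiotropy_suspected` flags p < 0.05.
#'
#' @param fit An `mr_egger_fit`.
#' @return One-row data frame of class `mr_pleiotropy`: `intercept`, `se`,
#'   `p`, `df`, `pleiotropy_suspected`.
#' @export
egger_intercept_test <- function(fit) {
  stopifnot(inherits(fit, "mr_egger_fit"))
  out <- data.frame(intercept = fit$intercept, se = fit$intercept_se,
                    p = fit$intercept_p, df = fit$df,
                    pleiotropy_suspected = fit$intercept_p < 0.05)
  class(out) <- c("mr_pleiotropy", "data.frame")
  out
}

# leave-one-out fixed-effect IVW slopes, closed form, vectorized over j;
# sxy/sxx may be matrices (instruments x simulations)
loo_ivw_beta <- function(gx_w, gy_w) {
  sxy <- colSums(gy_w)
  sxx <- colSums(gx_w)
  (rep(sxy, each = nrow(gy_w)) - gy_w) / (rep(sxx, each = nrow(gx_w)) - gx_w)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based heterogeneity and outlier diagnostic. The observed
#' statistic leaves each variant out in turn, predicts its outcome effect
#' from the remaining instruments' fixed-effect IVW slope, and accumulates
#' the inverse-variance-weighted squared residuals (RSS). The null
#' distribution regenerates both effect columns parametrically — outcome
#' effects normal around the leave-one-out predictions, exposure effects
#' normal around their observed values — and recomputes the RSS identically
#' `n_sim` times. P-values use the add-one estimator, so the global p is
#' never below `1/(n_sim+1)`. Per-variant outlier p-values compare each
#' observed squared residual with its simulated counterparts and are
#' Bonferroni-adjusted across instruments; when outliers are flagged, a
#' distortion test compares the full-data and outlier-removed IVW estimates
#' against a null built by removing random subsets of the same size.
#'
#' @param ds An `mr_harmonized` dataset with at least 4 instruments.
#' @param n_sim Number of parametric simulations (>= 1000 recommended; must
#'   resolve `significance`, i.e. `1/(n_sim+1) <= significance`).
#' @param significance Outlier significance threshold after Bonferroni
#'   adjustment (default 0.05).
#' @param seed Integer RNG seed; the result is bit-reproducible under it.
#' @return A list of class `mr_presso_result`: `rss_observed`, `global_p`,
#'   `n_sim`, `outlier_pvalues` (data frame `rsid`, `p_raw`,
#'   `p_bonferroni`), `outliers`, `distortion_p` (`NA` when no outliers),
#'   `significance`, `seed`.
#' @export
mr_presso <- function(ds, n_sim = 2000L, significance = 0.05, seed) {
  ins <- ds$instruments
  L <- nrow(ins)
  if (L < 4) stop_mrscreen("analysis", "MR-PRESSO needs >= 4 instruments")
  if (missing(seed)) stop_mrscreen("config", "MR-PRESSO requires a seed")
  if (1 / (n_sim + 1) > significance) {
    stop_mrscreen("config", "n_sim too small to resolve significance ",
                  significance, " (minimum attainable p is 1/(n_sim+1))")
  }
  g <- ins$beta_exp
  sg <- ins$se_exp
  G <- ins$beta_out
  sG <- ins$se_out
  w <- 1 / sG^2

  b_loo <- drop(loo_ivw_beta(cbind(g^2 * w), cbind(g * G * w)))
  r_obs <- G - b_loo * g
  rss_obs <- sum(w * r_obs^2)

  sims <- with_seed(seed, {
    g_star <- matrix(stats::rnorm(L * n_sim, g, sg), nrow = L)
    G_star <- matrix(stats::rnorm(L * n_sim, b_loo * g, sG), nrow = L)
    b_loo_star <- loo_ivw_beta(g_star^2 * w, g_star * G_star * w)
    r_star <- G_star - b_loo_star * g_star
    list(rss = colSums(w * r_star^2), r2 = r_star^2)
  })
  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  p_raw <- (1 + rowSums(sims$r2 >= r_obs^2)) / (n_sim + 1)
  p_bonf <- pmin(1, p_raw * L)
  outliers <- ins$rsid[p_bonf < significance]

  distortion_p <- NA_real_
  if (length(outliers) > 0 && length(outliers) < L - 1) {
    out_idx <- match(outliers, ins$rsid)
    b_full <- ivw_core(g, G, sG)$beta
    b_no_out <- ivw_core(g[-out_idx], G[-out_idx], sG[-out_idx])$beta
    d_obs <- b_full - b_no_out
    d_null <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(L, length(out_idx))
        b_full - ivw_core(g[-drop_idx], G[-drop_idx], sG[-drop_idx])$beta
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  }

  structure(list(rss_observed = rss_obs, global_p = global_p,
                 n_sim = as.integer(n_sim),
                 outlier_pvalues = data.frame(rsid = ins$rsid, p_raw = p_raw,
                                              p_bonferroni = p_bonf,
                                              stringsAsFactors = FALSE),
                 outliers = outliers, distortion_p = distortion_p,
                 significance = significance, seed = seed),
            class = "mr_presso_result")
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the default (multiplicative random-effects) IVW estimate with
#' each instrument omitted in turn; an influential variant shows up as a row
#' whose estimate departs from the rest.
#'
#' @param ds An `mr_harmonized` dataset with at least 3 instruments.
#' @return Data frame of class `mr_loo` with one row per omitted variant:
#'   `omitted_rsid`, `beta`, `se`, `p`, `or`, `or_low`, `or_high`.
#' @export
leave_one_out <- function(ds) {
  L <- n_instruments(ds)
  if (L < 3) stop_mrscreen("analysis", "leave-one-out needs >= 3 instruments")
  rows <- lapply(seq_len(L), function(j) {
    sub <- harmonized_dataset(ds$instruments[-j, , drop = FALSE])
    est <- mr_ivw(sub)
    data.frame(omitted_rsid = ds$instruments$rsid[j], beta = est$beta,
               se = est$se, p = est$p, or = est$or, or_low = est$or_low,
               or_high = est$or_high, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mr_loo", "data.frame")
  out
}

#' Funnel-plot table
#'
#' Per-variant Wald ratios against their precisions
#' (`|beta_exp|/se_out`, the reciprocal first-order ratio SE), ready for
#' external plotting; asymmetry about the IVW estimate suggests directional
#' pleiotropy. No rendering is done here.
#'
#' @param ds An `mr_harmonized` dataset (>= 1 instrument).
#' @return Data frame with `rsid`, `ratio`, `precision`.
#' @export
funnel_table <- function(ds) {
  if (n_instruments(ds) < 1) {
    stop_mrscreen("analysis", "funnel table needs >= 1 instrument")
  }
  rw <- ratio_weights(ds)
  data.frame(rsid = rw$rsid, ratio = rw$ratio, precision = sqrt(rw$w),
             stringsAsFactors = FALSE)
}
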