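#' Wald ratio estimate for a single instrument
#'
#' The per-variant causal estimate: outcome effect divided by exposure
#' effect, with a first-order delta-method standard error
#' `se_out / |beta_exp|` (exposure-side uncertainty ignored, the usual
#' two-sample convention given strong instruments).
#'
#' @param inst One-row data frame (or list) with `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out` and optionally `rsid`.
#' @return An [mr_estimate()] with `method = "wald_ratio"`.
#' @export
mr_wald_ratio <- function(inst) {
  g <- inst$beta_exp
  if (length(g) != 1) stop_mrscreen("config", "wald ratio takes one instrument")
  if (g == 0) stop_mrscreen("analysis", "undefined ratio: exposure beta is 0")
  beta <- inst$beta_out / g
  se <- inst$se_out / abs(g)
  z <- beta / se
  mr_estimate("wald_ratio", 1L, beta, se,
              beta - 1.96 * se, beta + 1.96 * se,
              2 * stats::pnorm(-abs(z)))
}

# per-instrument ratios and first-order inverse-variance weights
ratio_weights <- function(ds) {
  ins <- ds$instruments
  if (any(ins$beta_exp == 0)) {
    stop_mrscreen("analysis", "exposure beta of 0 for: ",
                  paste(ins$rsid[ins$beta_exp == 0], collapse = ", "))
  }
  list(rsid = ins$rsid,
       ratio = ins$beta_out / ins$beta_exp,
       w = (ins$se_out / abs(ins$beta_exp))^-2)
}

# closed-form zero-intercept WLS of beta_out on beta_exp, weights 1/se_out^2;
# identical to the inverse-variance-weighted average of the Wald ratios
ivw_core <- function(beta_exp, beta_out, se_out) {
  w <- 1 / se_out^2
  sxx <- sum(beta_exp^2 * w)
  beta <- sum(beta_exp * beta_out * w) / sxx
  list(beta = beta, se_fixed = sqrt(1 / sxx))
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines the per-variant Wald ratios with inverse-variance weights —
#' equivalently, zero-intercept weighted least squares of the outcome
#' effects on the exposure effects with weights `1/se_out^2`. In
#' `"multiplicative_random_effects"` mode (the default, and the dominant
#' convention in applied two-sample MR) the fixed-effect standard error is
#' inflated by the residual dispersion `max(1, sqrt(Q/(L-1)))`, where Q is
#' the Cochran heterogeneity statistic about the fixed-effect estimate, so
#' the standard error never drops below the fixed-effect one. P-values are
#' standard normal; the 95% interval uses 1.96.
#'
#' @param ds An `mr_harmonized` dataset with at least 2 instruments
#'   (`"fixed"` mode accepts a single instrument, where it reduces to the
#'   Wald ratio).
#' @param mode `"multiplicative_random_effects"` (default) or `"fixed"`.
#' @return An [mr_estimate()] with method `"ivw_mre"` or `"ivw_fixed"`.
#' @export
mr_ivw <- function(ds, mode = c("multiplicative_random_effects", "fixed")) {
  mode <- match.arg(mode)
  ins <- ds$instruments
  L <- nrow(ins)
  min_L <- if (mode == "fixed") 1L else 2L
  if (L < min_L) {
    stop_mrscreen("analysis", "insufficient instruments for IVW (need >= ",
                  min_L, ", have ", L, ")")
  }
  fit <- ivw_core(ins$beta_exp, ins$beta_out, ins$se_out)
  if (mode == "fixed") {
    se <- fit$se_fixed
    method <- "ivw_fixed"
  } else {
    rw <- ratio_weights(ds)
    Q <- sum(rw$w * (rw$ratio - fit$beta)^2)
    se <- fit$se_fixed * max(1, sqrt(Q / (L - 1)))
    method <- "ivw_mre"
  }
  z <- fit$beta / se
  mr_estimate(method, L, fit$beta, se,
              fit$beta - 1.96 * se, fit$beta + 1.96 * se,
              2 * stats::pnorm(-abs(z)))
}

# weighted least squares with intercept via normal equations;
# returns coefficients and the unscaled covariance (sigma = 1)
wls_intercept <- function(x, y, w) {
  X <- cbind(1, x)
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  coefs <- unname(drop(V %*% (XtW %*% y)))
  list(intercept = coefs[1], slope = coefs[2],
       se_unscaled = unname(sqrt(diag(V))),
       resid = y - drop(X %*% coefs))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept and weights `1/se_out^2`. Instruments are first
#' oriented so every exposure effect is non-negative (negating both effects
#' where needed); the intercept's sign is only interpretable under a fixed
#' orientation, and this convention is recorded in the fit. The slope is the
#' pleiotropy-adjusted causal estimate; a non-zero intercept indicates
#' directional horizontal pleiotropy (under the InSIDE assumption). Standard
#' errors are inflated by `max(1, sqrt(Q'/(L-2)))` in
#' multiplicative-random-effects mode, and inference uses the t distribution
#' with L-2 degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return A list of class `mr_egger_fit`: `estimate` (an [mr_estimate()]
#'   for the slope), `intercept`, `intercept_se`, `intercept_p`, `slope`,
#'   `slope_se`, `slope_p`, `df`, `phi` (residual scale
#'   `sqrt(Q'/(L-2))`), `q_prime`, `orientation`.
#' @export
mr_egger <- function(ds, mode = c("multiplicative_random_effects", "fixed")) {
  mode <- match.arg(mode)
  ins <- ds$instruments
  L <- nrow(ins)
  if (L < 3) {
    stop_mrscreen("analysis",
                  "insufficient instruments for MR-Egger (need >= 3, have ", L, ")")
  }
  s <- ifelse(ins$beta_exp < 0, -1, 1)
  x <- ins$beta_exp * s
  y <- ins$beta_out * s
  if (max(x) - min(x) < .Machine$double.eps^0.5 * max(abs(x), 1)) {
    stop_mrscreen("analysis",
                  "exposure effects are collinear after orientation; the Egger intercept is not identified")
  }
  w <- 1 / ins$se_out^2
  fit <- wls_intercept(x, y, w)
  df <- L - 2L
  q_prime <- sum(w * fit$resid^2)
  phi <- sqrt(q_prime / df)
  scale <- if (mode == "multiplicative_random_effects") max(1, phi) else 1
  se <- fit$se_unscaled * scale
  tq <- stats::qt(0.975, df)
  slope_p <- 2 * stats::pt(-abs(fit$slope / se[2]), df)
  intercept_p <- 2 * stats::pt(-abs(fit$intercept / se[1]), df)
  estimate <- mr_estimate("egger", L, fit$slope, se[2],
                          fit$slope - tq * se[2], fit$slope + tq * se[2],
                          slope_p)
  structure(list(estimate = estimate,
                 slope = fit$slope, slope_se = se[2], slope_p = slope_p,
                 intercept = fit$intercept, intercept_se = se[1],
                 intercept_p = intercept_p,
                 df = df, phi = phi, q_prime = q_prime,
                 orientation = "exposure effects oriented non-negative"),
            class = "mr_egger_fit")
}

# interpolated weighted median: sort values, form cumulative midpoint
# percentiles p_k = (sum_{i<=k} w_i) - w_k/2 on normalized weights, and
# linearly interpolate value against p at p = 0.5
weighted_median_point <- function(values, weights) {
  o <- order(values)
  v <- values[o]
  w <- weights[o] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(v[1])
  if (0.5 >= p[length(p)]) return(v[length(v)])
  stats::approx(p, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-variant Wald ratios, consistent when
#' instruments carrying at least half the weight are valid. Weights are the
#' first-order inverse variances of the ratios, `(se_out/|beta_exp|)^-2`,
#' normalized to sum to one; the estimate interpolates the weighted
#' empirical distribution at the 50th percentile. The standard error is the
#' standard deviation of the estimate over `n_boot` parametric resamples:
#' each ratio is redrawn normal around its observed value with its
#' first-order standard deviation while the weights stay fixed at their
#' observed values. The point estimate does not depend on the bootstrap;
#' only the standard error (hence CI and p) does, deterministically under
#' `seed`.
#'
#' @param ds An `mr_harmonized` dataset with at least 3 instruments.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer RNG seed for the bootstrap; required so the report is
#'   reproducible.
#' @return An [mr_estimate()] with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(ds, n_boot = 1000L, seed) {
  ins <- ds$instruments
  L <- nrow(ins)
  if (L < 3) {
    stop_mrscreen("analysis",
                  "insufficient instruments for the weighted median (need >= 3, have ", L, ")")
  }
  if (n_boot < 100) stop_mrscreen("config", "n_boot must be >= 100")
  if (missing(seed)) stop_mrscreen("config", "weighted median requires a seed")
  rw <- ratio_weights(ds)
  beta <- weighted_median_point(rw$ratio, rw$w)
  ratio_sd <- ins$se_out / abs(ins$beta_exp)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      weighted_median_point(stats::rnorm(L, rw$ratio, ratio_sd), rw$w)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  z <- beta / se
  mr_estimate("weighted_median", L, beta, se,
              beta - 1.96 * se, beta + 1.96 * se,
              2 * stats::pnorm(-abs(z)))
}

# evaluate an expression with a local, restored RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
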