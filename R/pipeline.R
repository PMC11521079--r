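#' Configuration for a full two-sample MR run
#'
#' Bundles everything [run_analysis()] needs: the input tables (or paths),
#' the harmonization/screening settings, estimator modes, resampling counts
#' and the root seed. Every threshold and seed is echoed into the report so
#' a run is reproducible from its own output.
#'
#' @param exposure,outcome `mr_sumstats` tables, or paths readable by
#'   [read_summary_stats()] with `column_map`.
#' @param harmonization An [harmonization_config()].
#' @param ivw_mode `"multiplicative_random_effects"` (default) or `"fixed"`.
#' @param n_boot Weighted-median bootstrap resamples.
#' @param n_sim MR-PRESSO simulation count.
#' @param significance MR-PRESSO outlier threshold.
#' @param seed Root RNG seed; the weighted-median bootstrap uses `seed` and
#'   MR-PRESSO `seed + 1`.
#' @param r2,n_exposure Optional variance explained and exposure sample size
#'   for the overall instrument-strength F.
#' @param power Optional list of [power_binary()] arguments (`n_total`,
#'   `case_fraction`, `r2`, `alpha`, `or_alt`); `or_alt = NULL` uses the
#'   run's IVW odds ratio.
#' @param column_map Column mapping used when `exposure`/`outcome` are paths.
#' @param out_dir Optional directory; when set, [write_report()] is called on
#'   the result.
#' @return A list of class `mr_run_config`.
#' @export
run_config <- function(exposure, outcome,
                       harmonization = harmonization_config(),
                       ivw_mode = c("multiplicative_random_effects", "fixed"),
                       n_boot = 1000L, n_sim = 2000L, significance = 0.05,
                       seed = 1L, r2 = NULL, n_exposure = NULL, power = NULL,
                       column_map = default_column_map(), out_dir = NULL) {
  structure(list(exposure = exposure, outcome = outcome,
                 harmonization = harmonization,
                 ivw_mode = match.arg(ivw_mode),
                 n_boot = as.integer(n_boot), n_sim = as.integer(n_sim),
                 significance = significance, seed = as.integer(seed),
                 r2 = r2, n_exposure = n_exposure, power = power,
                 column_map = column_map, out_dir = out_dir),
            class = "mr_run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, mrscreen_error = function(e) {
    e$message <- paste0("[stage: ", name, "] ", conditionMessage(e))
    stop(e)
  })
}

#' Run the full two-sample MR analysis
#'
#' Executes the whole workflow: read the exposure and outcome tables,
#' harmonize and screen instruments, estimate the causal effect (IVW,
#' weighted median, MR-Egger), run the diagnostics (Cochran Q for both
#' models, Egger intercept test, MR-PRESSO, leave-one-out, funnel table),
#' compute instrument strength (and power, when requested), and assemble
#' everything — config echo, exclusion log, per-variant table — into a
#' report. Analysis errors carry the name of the stage that raised them.
#'
#' @param cfg An [run_config()].
#' @param truth Optional `mr_sim_truth` from [simulate_pair()]; when given,
#'   the report gains a `truth_comparison` block (true theta vs each
#'   method's estimate).
#' @return A list of class `mr_report`; written to `cfg$out_dir` via
#'   [write_report()] when that is set.
#' @export
run_analysis <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "mr_run_config"))
  exposure <- stage("read_exposure", {
    if (inherits(cfg$exposure, "mr_sumstats")) cfg$exposure
    else read_summary_stats(cfg$exposure, cfg$column_map)
  })
  outcome <- stage("read_outcome", {
    if (inherits(cfg$outcome, "mr_sumstats")) cfg$outcome
    else read_summary_stats(cfg$outcome, cfg$column_map)
  })
  ds <- stage("harmonization", harmonize(exposure, outcome, cfg$harmonization))
  if (n_instruments(ds) < 3) {
    stop_mrscreen("analysis", "[stage: harmonization] only ",
                  n_instruments(ds),
                  " instrument(s) survive screening; need >= 3")
  }
  estimates <- stage("estimation", {
    rbind(mr_ivw(ds, cfg$ivw_mode),
          mr_weighted_median(ds, n_boot = cfg$n_boot, seed = cfg$seed),
          mr_egger(ds, cfg$ivw_mode)$estimate)
  })
  egger_fit <- stage("estimation", mr_egger(ds, cfg$ivw_mode))
  diagnostics <- stage("diagnostics", {
    list(heterogeneity = rbind(cochran_q(ds, "ivw"), cochran_q(ds, "egger")),
         pleiotropy = egger_intercept_test(egger_fit),
         presso = if (n_instruments(ds) >= 4) {
           unclass(mr_presso(ds, n_sim = cfg$n_sim,
                             significance = cfg$significance,
                             seed = cfg$seed + 1L))
         })
  })
  loo <- stage("diagnostics", leave_one_out(ds))
  funnel <- stage("diagnostics", funnel_table(ds))
  strength <- stage("strength_power", {
    out <- list(per_snp_f = f_per_snp(ds))
    if (!is.null(cfg$r2) && !is.null(cfg$n_exposure)) {
      out$f_overall <- f_overall(cfg$n_exposure, n_instruments(ds), cfg$r2)
      out$r2 <- cfg$r2
      out$n_exposure <- cfg$n_exposure
    }
    out
  })
  power <- if (!is.null(cfg$power)) {
    stage("strength_power", {
      p <- cfg$power
      if (is.null(p$or_alt)) p$or_alt <- estimates$or[estimates$method %in%
                                                        c("ivw_mre", "ivw_fixed")]
      unclass(do.call(power_binary, p))
    })
  }
  truth_comparison <- if (!is.null(truth)) {
    data.frame(method = estimates$method, estimate = estimates$beta,
               true_theta = truth$theta,
               error = estimates$beta - truth$theta,
               covered = estimates$ci_low <= truth$theta &
                 truth$theta <= estimates$ci_high,
               stringsAsFactors = FALSE)
  }
  config_echo <- list(
    ivw_mode = cfg$ivw_mode, n_boot = cfg$n_boot, n_sim = cfg$n_sim,
    significance = cfg$significance, seed = cfg$seed,
    pval_threshold = cfg$harmonization$pval_threshold,
    palindrome_policy = cfg$harmonization$palindrome_policy,
    ambiguous_eaf_window = cfg$harmonization$ambiguous_eaf_window,
    deny_list = cfg$harmonization$deny_list,
    egger_orientation = "exposure effects oriented non-negative",
    distortion_null_draws = cfg$n_sim
  )
  report <- structure(
    list(config = config_echo,
         n_instruments = n_instruments(ds),
         estimates = estimates,
         heterogeneity = diagnostics$heterogeneity,
         pleiotropy = diagnostics$pleiotropy,
         presso = diagnostics$presso,
         leave_one_out = loo,
         funnel = funnel,
         snps = ds$instruments,
         exclusions = ds$exclusions,
         strength = strength,
         power = power,
         truth_comparison = truth_comparison),
    class = "mr_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("Two-sample MR report: %d instruments, %d exclusion(s)\n",
              x$n_instruments, nrow(x$exclusions)))
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %-16s OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                est$method[i], est$or[i], est$or_low[i], est$or_high[i],
                est$p[i]))
  }
  h <- x$heterogeneity
  cat(sprintf("  Cochran Q (IVW) %.2f on %d df, p = %.3f; Q' (Egger) %.2f on %d df, p = %.3f\n",
              h$Q[1], h$df[1], h$p[1], h$Q[2], h$df[2], h$p[2]))
  cat(sprintf("  Egger intercept %.4f (SE %.4f), p = %.3f\n",
              x$pleiotropy$intercept, x$pleiotropy$se, x$pleiotropy$p))
  if (!is.null(x$presso)) {
    cat(sprintf("  MR-PRESSO global p = %.4g, %d outlier(s)\n",
                x$presso$global_p, length(x$presso$outliers)))
  }
  invisible(x)
}
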