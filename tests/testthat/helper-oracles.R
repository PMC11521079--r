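# Independent oracles and small-data builders used across the suite.
# Each oracle re-derives its quantity by a different route than the
# implementation (grid search, CDF inversion, explicit summation) so that
# agreement is evidence, not tautology.

# minimizer of sum w_j (G_j - b g_j)^2 by iterative grid refinement
oracle_ivw_grid <- function(beta_exp, beta_out, se_out) {
  w <- 1 / se_out^2
  obj <- function(b) sum(w * (beta_out - b * beta_exp)^2)
  ratios <- beta_out / beta_exp
  lo <- min(ratios) - 1
  hi <- max(ratios) + 1
  for (iter in 1:8) {
    grid <- seq(lo, hi, length.out = 2001)
    vals <- vapply(grid, obj, numeric(1))
    k <- which.min(vals)
    step <- grid[2] - grid[1]
    lo <- grid[k] - 2 * step
    hi <- grid[k] + 2 * step
  }
  (lo + hi) / 2
}

# weighted median by direct inversion of the weighted empirical CDF:
# build the piecewise-linear CDF through the cumulative-midpoint knots and
# root-find where it crosses one half
oracle_weighted_median_cdf <- function(values, weights) {
  o <- order(values)
  v <- values[o]
  w <- weights[o] / sum(weights)
  p <- numeric(length(w))
  acc <- 0
  for (k in seq_along(w)) {
    p[k] <- acc + w[k] / 2
    acc <- acc + w[k]
  }
  if (0.5 <= p[1]) return(v[1])
  if (0.5 >= p[length(p)]) return(v[length(v)])
  cdf <- stats::approxfun(v, p, ties = "ordered")
  stats::uniroot(function(b) cdf(b) - 0.5, range(v), tol = 1e-12)$root
}

# Cochran Q by explicit term-by-term summation about the ratio-weighted mean
oracle_q_sum <- function(beta_exp, beta_out, se_out) {
  r <- beta_out / beta_exp
  w <- (se_out / abs(beta_exp))^-2
  center <- sum(w * r) / sum(w)
  q <- 0
  for (j in seq_along(r)) q <- q + w[j] * (r[j] - center)^2
  q
}

# small random harmonized dataset with heteroscedastic errors
random_harmonized <- function(L, seed, theta = 0.3) {
  set.seed(seed)
  g <- stats::rnorm(L, 0.1, 0.04)
  g[abs(g) < 0.02] <- 0.02  # keep ratios well-defined
  sg <- stats::runif(L, 0.005, 0.02)
  sG <- stats::runif(L, 0.02, 0.1)
  G <- stats::rnorm(L, theta * g, sG)
  harmonized_dataset(data.frame(
    rsid = sprintf("rs%d", seq_len(L)),
    beta_exp = g, se_exp = sg, beta_out = G, se_out = sG,
    eaf = NA_real_, flipped = FALSE, stringsAsFactors = FALSE
  ))
}

# harmonized dataset straight from a simulated pair, instruments pre-screened
harmonize_sim <- function(sim) {
  harmonize(sim$exposure, sim$outcome,
            harmonization_config(palindrome_policy = "keep"))
}

# the packaged instrument table, harmonized with the screening already done
# upstream of the published list
fixture_dataset <- function() {
  fx <- load_table1_fixture()
  harmonize(fx$exposure, fx$outcome,
            harmonization_config(palindrome_policy = "keep"))
}

rbind_sumstats <- function(a, b) {
  summary_stats(c(a$rsid, b$rsid),
                c(a$effect_allele, b$effect_allele),
                c(a$other_allele, b$other_allele),
                c(a$beta, b$beta), c(a$se, b$se), c(a$pval, b$pval),
                eaf = c(a$eaf, b$eaf), n = c(a$n, b$n),
                trait_label = attr(a, "trait_label"))
}

write_sumstats_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
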