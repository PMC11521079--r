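test_that("wald ratio divides outcome by exposure effect", {
  ds <- fixture_dataset()
  inst <- ds$instruments[ds$instruments$rsid == "rs12617870", ]
  est <- mr_wald_ratio(inst)
  # direct division of the published effects
  expect_equal(est$beta, -0.038 / -0.026, tolerance = 1e-12)
  expect_equal(est$se, 0.015 / 0.026, tolerance = 1e-12)
  # zero outcome effect: beta 0, se = se_out
  flat <- list(beta_exp = 1, se_exp = 0.1, beta_out = 0, se_out = 0.2)
  est0 <- mr_wald_ratio(flat)
  expect_equal(est0$beta, 0)
  expect_equal(est0$se, 0.2)
  # ratio symmetry under joint negation
  neg <- list(beta_exp = -inst$beta_exp, se_exp = inst$se_exp,
              beta_out = -inst$beta_out, se_out = inst$se_out)
  expect_equal(mr_wald_ratio(neg)$beta, est$beta)
  expect_error(mr_wald_ratio(list(beta_exp = 0, se_exp = 1, beta_out = 1,
                                  se_out = 1)),
               class = "mrscreen_analysis_error")
})

test_that("IVW equals the weighted-least-squares minimizer on random data", {
  for (seed in 1:25) {
    ds <- random_harmonized(10, seed = 100 + seed)
    est <- mr_ivw(ds, "fixed")
    oracle <- oracle_ivw_grid(ds$instruments$beta_exp,
                              ds$instruments$beta_out,
                              ds$instruments$se_out)
    expect_lt(abs(est$beta - oracle), 1e-6)
  }
})

test_that("IVW degenerates sensibly", {
  # identical duplicated pair: average equals the single Wald ratio
  ins <- data.frame(rsid = c("a", "b"), beta_exp = 0.04, se_exp = 0.01,
                    beta_out = 0.02, se_out = 0.05)
  ds <- harmonized_dataset(ins)
  expect_equal(mr_ivw(ds)$beta, 0.5, tolerance = 1e-12)
  # single instrument, fixed mode relaxed: equals the Wald ratio
  ds1 <- harmonized_dataset(ins[1, ])
  wald <- mr_wald_ratio(ins[1, ])
  ivw1 <- mr_ivw(ds1, "fixed")
  expect_equal(ivw1$beta, wald$beta)
  expect_equal(ivw1$se, wald$se)
  expect_error(mr_ivw(ds1), class = "mrscreen_analysis_error")
  # random-effects se never drops below the fixed-effect se
  ds10 <- random_harmonized(10, seed = 77)
  expect_gte(mr_ivw(ds10)$se, mr_ivw(ds10, "fixed")$se)
})

test_that("Egger regression recovers an exact linear relation", {
  g <- c(-0.05, -0.03, 0.02, 0.04, -0.01)
  ds <- harmonized_dataset(data.frame(
    rsid = paste0("rs", 1:5), beta_exp = g, se_exp = 0.004,
    beta_out = 0.3 * g, se_out = c(0.01, 0.02, 0.015, 0.01, 0.03)))
  fit <- mr_egger(ds)
  expect_equal(fit$slope, 0.3, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$q_prime, 0, tolerance = 1e-18)
  # offset relation: intercept absorbs the shift under positive orientation
  ds2 <- harmonized_dataset(data.frame(
    rsid = paste0("rs", 1:5), beta_exp = abs(g), se_exp = 0.004,
    beta_out = 0.01 + 0.3 * abs(g), se_out = 0.02))
  fit2 <- mr_egger(ds2)
  expect_equal(fit2$intercept, 0.01, tolerance = 1e-10)
  expect_equal(fit2$slope, 0.3, tolerance = 1e-10)
})

test_that("Egger matches a weighted lm oracle and uses t inference", {
  ds <- random_harmonized(12, seed = 42)
  ins <- ds$instruments
  s <- ifelse(ins$beta_exp < 0, -1, 1)
  fit <- mr_egger(ds)
  lmfit <- stats::lm(I(ins$beta_out * s) ~ I(ins$beta_exp * s),
                     weights = 1 / ins$se_out^2)
  cf <- stats::coef(lmfit)
  expect_equal(fit$intercept, unname(cf[1]), tolerance = 1e-10)
  expect_equal(fit$slope, unname(cf[2]), tolerance = 1e-10)
  # lm's sigma-rescaled SEs equal ours when the dispersion exceeds 1
  sm <- summary(lmfit)$coefficients
  if (fit$phi > 1) {
    expect_equal(fit$slope_se, unname(sm[2, 2]), tolerance = 1e-10)
    expect_equal(fit$slope_p, unname(sm[2, 4]), tolerance = 1e-10)
  }
  expect_equal(fit$df, 10)
  expect_error(mr_egger(harmonized_dataset(ins[1:2, ])),
               class = "mrscreen_analysis_error")
  # equal exposure effects after orientation: intercept not identified
  coll <- harmonized_dataset(data.frame(
    rsid = paste0("rs", 1:4), beta_exp = c(0.03, 0.03, -0.03, -0.03),
    se_exp = 0.004, beta_out = c(0.01, 0.02, 0.0, 0.01), se_out = 0.02))
  expect_error(mr_egger(coll), class = "mrscreen_analysis_error")
})

test_that("weighted median interpolates the weighted ratio CDF at one half", {
  # equal weights: plain median of {0.1, 0.2, 0.9}
  ds <- harmonized_dataset(data.frame(
    rsid = paste0("rs", 1:3), beta_exp = 1, se_exp = 0.01,
    beta_out = c(0.1, 0.2, 0.9), se_out = 0.05))
  est <- mr_weighted_median(ds, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.2, tolerance = 1e-12)
  # general case matches the CDF-inversion oracle
  for (seed in 1:25) {
    ds <- random_harmonized(5, seed = 300 + seed)
    est <- mr_weighted_median(ds, n_boot = 100, seed = 2)
    rw <- with(ds$instruments, list(r = beta_out / beta_exp,
                                    w = (se_out / abs(beta_exp))^-2))
    oracle <- oracle_weighted_median_cdf(rw$r, rw$w)
    expect_equal(est$beta, oracle, tolerance = 1e-8)
    expect_gte(est$beta, min(rw$r))
    expect_lte(est$beta, max(rw$r))
  }
  # bootstrap SE is reproducible under seed and requires one
  e1 <- mr_weighted_median(ds, n_boot = 150, seed = 9)
  e2 <- mr_weighted_median(ds, n_boot = 150, seed = 9)
  expect_identical(e1$se, e2$se)
  expect_error(mr_weighted_median(ds, n_boot = 150),
               class = "mrscreen_config_error")
  expect_error(mr_weighted_median(ds, n_boot = 50, seed = 1),
               class = "mrscreen_config_error")
})

test_that("estimators are scale-equivariant in the outcome", {
  ds <- random_harmonized(8, seed = 5)
  c_ <- 3.7
  scaled <- ds$instruments
  scaled$beta_out <- scaled$beta_out * c_
  scaled$se_out <- scaled$se_out * c_
  ds2 <- harmonized_dataset(scaled)
  for (f in list(function(d) mr_ivw(d),
                 function(d) mr_ivw(d, "fixed"),
                 function(d) mr_egger(d)$estimate,
                 function(d) mr_weighted_median(d, n_boot = 100, seed = 3))) {
    a <- f(ds); b <- f(ds2)
    expect_equal(b$beta, c_ * a$beta, tolerance = 1e-9)
    expect_equal(b$se, c_ * a$se, tolerance = 1e-9)
  }
})

test_that("estimates are invariant to allele-coding sign flips", {
  ds <- random_harmonized(9, seed = 6)
  flip <- ds$instruments
  idx <- c(2, 5, 7)
  flip$beta_exp[idx] <- -flip$beta_exp[idx]
  flip$beta_out[idx] <- -flip$beta_out[idx]
  ds2 <- harmonized_dataset(flip)
  expect_equal(mr_ivw(ds2)$beta, mr_ivw(ds)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(ds2, n_boot = 100, seed = 4)$beta,
               mr_weighted_median(ds, n_boot = 100, seed = 4)$beta,
               tolerance = 1e-12)
  f1 <- mr_egger(ds); f2 <- mr_egger(ds2)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-12)
})

test_that("or fields are the exponentiated beta-scale fields", {
  ds <- random_harmonized(6, seed = 13)
  est <- mr_ivw(ds)
  expect_equal(est$or, exp(est$beta))
  expect_equal(est$or_low, exp(est$ci_low))
  expect_equal(est$or_high, exp(est$ci_high))
  expect_true(est$ci_low <= est$beta && est$beta <= est$ci_high)
})
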