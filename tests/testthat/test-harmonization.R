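make_table <- function(rsid, ea, oa, beta, se, pval = 1e-10, eaf = NA_real_,
                       label = "t") {
  summary_stats(rsid, ea, oa, beta, se, pval, eaf = eaf, trait_label = label)
}

test_that("palindromic pairs are exactly {A,T} and {C,G}", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("t", "a"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("TA", "T"))  # indels cannot be palindromic
  expect_identical(is_palindromic(c("A", "A"), c("T", "C")), c(TRUE, FALSE))
})

test_that("swapped outcome alleles flip the outcome beta and eaf", {
  exp <- make_table("rs1", "A", "G", 0.02, 0.004)
  out <- make_table("rs1", "G", "A", 0.01, 0.01, eaf = 0.3)
  ds <- harmonize(exp, out, harmonization_config())
  expect_equal(ds$instruments$beta_out, -0.01)
  expect_true(ds$instruments$flipped)
  # aligned alleles pass through untouched
  out2 <- make_table("rs1", "A", "G", 0.01, 0.01)
  ds2 <- harmonize(exp, out2)
  expect_equal(ds2$instruments$beta_out, 0.01)
  expect_false(ds2$instruments$flipped)
})

test_that("irreconcilable alleles are excluded unless strand flip is enabled", {
  exp <- make_table("rs1", "A", "G", 0.02, 0.004)
  out <- make_table("rs1", "T", "C", 0.01, 0.01)  # other strand
  ds <- harmonize(exp, out)
  expect_equal(nrow(ds$instruments), 0)
  expect_equal(ds$exclusions$reason, "allele_mismatch")
  ds_flip <- harmonize(exp, out, harmonization_config(try_strand_flip = TRUE))
  expect_equal(nrow(ds_flip$instruments), 1)
  expect_equal(ds_flip$instruments$beta_out, 0.01)
  # complement-then-swap also resolves, with a sign flip
  out_swap <- make_table("rs1", "C", "T", 0.01, 0.01)
  ds_swap <- harmonize(exp, out_swap,
                       harmonization_config(try_strand_flip = TRUE))
  expect_equal(ds_swap$instruments$beta_out, -0.01)
})

test_that("palindrome policies drop what they should", {
  exp <- make_table(c("rs1", "rs2", "rs3", "rs4"),
                    c("A", "A", "C", "A"), c("T", "T", "G", "G"),
                    rep(0.02, 4), rep(0.004, 4),
                    eaf = c(0.10, 0.50, NA, 0.50))
  out <- make_table(c("rs1", "rs2", "rs3", "rs4"),
                    c("A", "A", "C", "A"), c("T", "T", "G", "G"),
                    rep(0.01, 4), rep(0.01, 4))
  amb <- harmonize(exp, out, harmonization_config("drop_ambiguous"))
  # rs1 has a decisive frequency; rs2 is balanced, rs3 unknown -> dropped;
  # rs4 is not palindromic at all
  expect_setequal(amb$instruments$rsid, c("rs1", "rs4"))
  expect_setequal(amb$exclusions$rsid[amb$exclusions$reason ==
                                        "palindromic_ambiguous"],
                  c("rs2", "rs3"))
  all_drop <- harmonize(exp, out, harmonization_config("drop_all"))
  expect_identical(all_drop$instruments$rsid, "rs4")
  keep <- harmonize(exp, out, harmonization_config("keep"))
  expect_equal(nrow(keep$instruments), 4)
})

test_that("significance and deny-list screens exclude with named reasons", {
  exp <- make_table(c("rs1", "rs6857"), c("A", "C"), c("G", "T"),
                    c(0.02, 0.03), c(0.004, 0.004), pval = c(1e-10, 1e-12))
  out <- make_table(c("rs1", "rs6857"), c("A", "C"), c("G", "T"),
                    c(0.01, 0.02), c(0.01, 0.01))
  ds <- harmonize(exp, out, harmonization_config(deny_list = "rs6857"))
  expect_identical(ds$instruments$rsid, "rs1")
  expect_identical(ds$exclusions,
                   data.frame(rsid = "rs6857", reason = "deny_list",
                              stringsAsFactors = FALSE))
  weak <- make_table("rs2", "A", "G", 0.01, 0.004, pval = 1e-6)
  ds2 <- harmonize(rbind_sumstats(exp, weak), rbind_sumstats(out,
                   make_table("rs2", "A", "G", 0.01, 0.01)),
                   harmonization_config(pval_threshold = 5e-9))
  expect_true("rs2" %in% ds2$exclusions$rsid)
  expect_equal(ds2$exclusions$reason[ds2$exclusions$rsid == "rs2"],
               "exposure_pval")
})

test_that("every shared variant lands in exactly one of instruments/exclusions", {
  sim <- simulate_pair(simulation_config(L = 40, seed = 8,
                                         palindromic_fraction = 0.3))
  cfgs <- list(harmonization_config("drop_all"),
               harmonization_config("drop_ambiguous"),
               harmonization_config("keep", deny_list = c("rs0000001",
                                                          "rs0000002")))
  for (cfg in cfgs) {
    ds <- harmonize(sim$exposure, sim$outcome, cfg)
    expect_equal(nrow(ds$instruments) + nrow(ds$exclusions), 40)
    expect_length(intersect(ds$instruments$rsid, ds$exclusions$rsid), 0)
  }
})

test_that("harmonization is involution-safe", {
  sim <- simulate_pair(simulation_config(L = 15, seed = 21))
  ds <- harmonize_sim(sim)
  ins <- ds$instruments
  # feed the harmonized dataset back in as two aligned tables
  exp2 <- summary_stats(ins$rsid, "A", "G", ins$beta_exp, ins$se_exp,
                        1e-12, eaf = ins$eaf)
  out2 <- summary_stats(ins$rsid, "A", "G", ins$beta_out, ins$se_out, 0.5,
                        eaf = ins$eaf)
  ds2 <- harmonize(exp2, out2, harmonization_config("keep"))
  expect_equal(ds2$instruments$beta_out, ins$beta_out)
  expect_equal(ds2$instruments$beta_exp, ins$beta_exp)
  expect_false(any(ds2$instruments$flipped))
})

test_that("relabeling outcome alleles flips beta_out's sign and nothing else", {
  sim <- simulate_pair(simulation_config(L = 10, seed = 4,
                                         palindromic_fraction = 0))
  base <- harmonize_sim(sim)
  swapped <- sim$outcome
  tmp <- swapped$effect_allele
  swapped$effect_allele <- swapped$other_allele
  swapped$other_allele <- tmp
  swapped$beta <- -swapped$beta
  swapped$eaf <- 1 - swapped$eaf
  ds2 <- harmonize(sim$exposure, swapped,
                   harmonization_config(palindrome_policy = "keep"))
  expect_equal(ds2$instruments$beta_out, base$instruments$beta_out)
  expect_equal(ds2$instruments$se_out, base$instruments$se_out)
  expect_true(all(ds2$instruments$flipped))
})

test_that("the packaged table harmonizes to 63 instruments with no exclusion", {
  ds <- fixture_dataset()
  expect_equal(n_instruments(ds), 63)
  expect_equal(nrow(ds$exclusions), 0)
  # the six variants the screening removed upstream are indeed absent
  upstream <- c("rs12992995", "rs13107325", "rs3791033", "rs6010651",
                "rs6857", "rs71658797")
  expect_length(intersect(ds$instruments$rsid, upstream), 0)
  # so the deny-list pass leaves the dataset unchanged
  expect_identical(apply_deny_list(ds, upstream), ds)
})

test_that("apply_deny_list moves instruments with reason and is idempotent", {
  ds <- fixture_dataset()
  hit <- ds$instruments$rsid[1:3]
  out <- apply_deny_list(ds, hit)
  expect_equal(n_instruments(out), 60)
  expect_setequal(out$exclusions$rsid, hit)
  expect_true(all(out$exclusions$reason == "confounder-associated"))
  expect_identical(apply_deny_list(out, hit), out)
  # boundary: denying everything leaves an analysis-unusable dataset
  all_out <- apply_deny_list(ds, ds$instruments$rsid)
  expect_equal(n_instruments(all_out), 0)
  expect_equal(nrow(all_out$exclusions), 63)
  # empty intersection of tables is an analysis error
  exp <- make_table("rs1", "A", "G", 0.02, 0.004)
  out2 <- make_table("rs2", "A", "G", 0.01, 0.01)
  expect_error(harmonize(exp, out2), class = "mrscreen_analysis_error")
})
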