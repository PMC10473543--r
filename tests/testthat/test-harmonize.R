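test_that("palindrome detection matches enumeration of all ordered pairs", {
  expect_true(is_palindromic("A", "T"))
  expect_false(is_palindromic("A", "G"))
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ea = bases, oa = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  res <- is_palindromic(pairs$ea, pairs$oa)
  expect_equal(sum(res), 4)
  expect_setequal(paste0(pairs$ea, pairs$oa)[res], c("AT", "TA", "CG", "GC"))
  expect_error(is_palindromic("A", "A"), "invalid")
  expect_error(is_palindromic("A", "N"), "invalid")
})

rec <- function(snp = "rs1", ea = "A", oa = "G", beta = 0.1, se = 0.01,
                eaf = 0.3) {
  data.frame(snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = 1e-8, n = 1e5,
             stringsAsFactors = FALSE)
}

test_that("harmonize_pair handles identity, swap, strand flip, exclusions", {
  # identity orientation
  h <- harmonize_pair(rec(), rec(beta = 0.2))
  expect_equal(h$beta_out, 0.2)
  expect_equal(h$wald_ratio, 2)
  expect_false(h$flipped)
  # swapped alleles: beta negated, eaf complemented
  h2 <- harmonize_pair(rec(), rec(ea = "G", oa = "A", beta = -0.2, eaf = 0.7))
  expect_equal(h2$beta_out, 0.2)
  expect_true(h2$flipped)
  # strand complement, same orientation (A/G vs T/C)
  h3 <- harmonize_pair(rec(), rec(ea = "T", oa = "C", beta = 0.2))
  expect_equal(h3$beta_out, 0.2)
  expect_false(h3$flipped)
  # strand complement + swap (A/G vs C/T)
  h4 <- harmonize_pair(rec(), rec(ea = "C", oa = "T", beta = -0.2, eaf = 0.7))
  expect_equal(h4$beta_out, 0.2)
  expect_true(h4$flipped)
  # palindromic under default policy
  expect_equal(harmonize_pair(rec(ea = "A", oa = "T"),
                              rec(ea = "A", oa = "T", beta = 0.2)),
               "palindromic")
  # irreconcilable allele sets
  expect_equal(harmonize_pair(rec(), rec(ea = "A", oa = "C")),
               "allele_mismatch")
  expect_error(harmonize_pair(rec(snp = "rs1"), rec(snp = "rs2")),
               "mismatch")
})

test_that("frequency inference can rescue palindromes away from 0.5", {
  x <- rec(ea = "A", oa = "T", eaf = 0.2)
  # concordant frequencies: kept as-is
  h <- harmonize_pair(x, rec(ea = "A", oa = "T", beta = 0.2, eaf = 0.22),
                      policy = "infer")
  expect_equal(h$beta_out, 0.2)
  # discordant frequencies: flipped
  h2 <- harmonize_pair(x, rec(ea = "A", oa = "T", beta = 0.2, eaf = 0.78),
                       policy = "infer")
  expect_equal(h2$beta_out, -0.2)
  # too close to 0.5: still excluded
  expect_equal(harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.48),
                              rec(ea = "A", oa = "T", eaf = 0.49),
                              policy = "infer"),
               "palindromic")
})

test_that("harmonization is an involution on already-harmonized pairs", {
  h <- harmonize_pair(rec(), rec(ea = "G", oa = "A", beta = -0.2, eaf = 0.7))
  again <- harmonize_pair(rec(),
                          rec(beta = h$beta_out, eaf = 1 - 0.7))
  expect_equal(again$beta_out, h$beta_out)
  expect_equal(again$wald_ratio, h$wald_ratio)
})

test_that("harmonize_sets bookkeeping matches the generator's injections", {
  sim <- simulate_sumstats(sim_config(n_snps = 50, n_snps_med = 0,
                                      frac_palindromic = 0.1,
                                      frac_allele_swapped = 0.2, seed = 31))
  hs <- suppressMessages(harmonize_sets(sim$exposure, sim$outcome))
  rep <- harmonize_report(hs)
  expect_equal(unname(rep["n_palindromic_excluded"]),
               length(sim$truth$palindromic_snps))
  swapped_nonpal <- setdiff(sim$truth$swapped_out,
                            sim$truth$palindromic_snps)
  expect_equal(unname(rep["n_flipped"]), length(swapped_nonpal))
  expect_equal(unname(rep["n_input"]),
               unname(rep["n_harmonized"] + rep["n_palindromic_excluded"] +
                        rep["n_allele_mismatch"] + rep["n_zero_beta"]))
  expect_error(suppressMessages(harmonize_sets(
    mrmediate:::.subset_set(sim$exposure, 1:5),
    mrmediate:::.subset_set(sim$outcome, 6:10))), "no shared")
})

test_that("estimates after random allele swaps equal the no-swap truth", {
  for (seed in c(101, 202)) {
    sim_swap <- simulate_sumstats(sim_config(n_snps = 40, n_snps_med = 0,
                                             frac_palindromic = 0,
                                             frac_allele_swapped = 0.5,
                                             seed = seed))
    sim_none <- simulate_sumstats(sim_config(n_snps = 40, n_snps_med = 0,
                                             frac_palindromic = 0,
                                             frac_allele_swapped = 0,
                                             seed = seed))
    hs_swap <- suppressMessages(harmonize_sets(sim_swap$exposure,
                                               sim_swap$outcome))
    hs_none <- suppressMessages(harmonize_sets(sim_none$exposure,
                                               sim_none$outcome))
    expect_equal(ivw(hs_swap, "fixed")$beta, ivw(hs_none, "fixed")$beta,
                 tolerance = 1e-12)
  }
})
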