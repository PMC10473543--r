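test_that("p-value filtering is strict and matches brute force", {
  df <- toy_sumstats_df()
  df$pval <- c(1e-9, 1e-7, 4.9e-8)
  s <- sumstat_set(df, "x", check_pval = FALSE)
  kept <- filter_by_pvalue(s, 5e-8)
  expect_equal(kept$snp, c("rs1", "rs3"))
  expect_equal(nrow(filter_by_pvalue(s, 1)), 3)

  set.seed(11)
  big <- sumstat_set(data.frame(
    snp = sprintf("rs%04d", 1:1000), effect_allele = "A",
    other_allele = "G", beta = 0.1, se = 0.05,
    pval = runif(1000)), "x", check_pval = FALSE)
  out <- filter_by_pvalue(big, 0.05)
  expect_equal(nrow(out), sum(big$pval < 0.05))
  # idempotence
  expect_equal(as.data.frame(filter_by_pvalue(out, 0.05)),
               as.data.frame(out))
})

test_that("ld_clump keeps independent SNPs and drops dominated ones", {
  df <- toy_sumstats_df()
  s <- sumstat_set(df, "x", check_pval = FALSE)
  ld0 <- ld_matrix(snp_ids = df$snp)
  expect_equal(nrow(ld_clump(s, ld0)), 3)

  r2 <- diag(3); r2[1, 2] <- r2[2, 1] <- 0.5
  dimnames(r2) <- list(df$snp, df$snp)
  s2 <- s; s2$pval <- c(1e-10, 1e-9, 1e-3)
  kept <- ld_clump(s2, ld_matrix(r2), r2_max = 0.1)
  expect_true("rs1" %in% kept$snp)
  expect_false("rs2" %in% kept$snp)

  expect_error(ld_clump(s, ld_matrix(snp_ids = c("rs1", "rs2"))), "rs3")
})

test_that("ld_clump agrees with a pairwise-check oracle on block LD", {
  set.seed(21)
  J <- 20
  ids <- sprintf("rs%03d", 1:J)
  block <- rep(1:4, each = 5)
  r2 <- outer(block, block, function(a, b) ifelse(a == b, 0.8, 0))
  diag(r2) <- 1
  dimnames(r2) <- list(ids, ids)
  s <- sumstat_set(data.frame(snp = ids, effect_allele = "A",
                              other_allele = "G", beta = 0.1, se = 0.02,
                              pval = runif(J, 1e-12, 1e-6)),
                   "x", check_pval = FALSE)
  ld <- ld_matrix(r2)
  kept <- ld_clump(s, ld, r2_max = 0.1)
  # every retained pair has r2 below threshold
  for (a in kept$snp) for (b in kept$snp)
    if (a != b) expect_lt(r2[a, b], 0.1)
  # every discarded SNP conflicts with a retained SNP of smaller p
  for (d in setdiff(s$snp, kept$snp)) {
    conflicts <- kept$snp[r2[d, kept$snp] >= 0.1]
    expect_true(any(s$pval[match(conflicts, s$snp)] <=
                      s$pval[s$snp == d]))
  }
  # invariance to input row order
  perm <- sample(J)
  kept2 <- ld_clump(mrmediate:::.subset_set(s, perm), ld, r2_max = 0.1)
  expect_setequal(kept2$snp, kept$snp)
})

test_that("distance window applies only when positions are given", {
  ids <- c("rs1", "rs2")
  r2 <- diag(2); r2[1, 2] <- r2[2, 1] <- 0.9
  dimnames(r2) <- list(ids, ids)
  s <- sumstat_set(data.frame(snp = ids, effect_allele = "A",
                              other_allele = "G", beta = 0.1, se = 0.02,
                              pval = c(1e-10, 1e-9)), "x",
                   check_pval = FALSE)
  # r2-only input: rs2 discarded
  expect_equal(ld_clump(s, ld_matrix(r2), r2_max = 0.5)$snp, "rs1")
  # far apart in position: correlated but outside the window, both kept
  ld_far <- ld_matrix(r2, positions = c(rs1 = 0, rs2 = 2e7))
  expect_equal(nrow(ld_clump(s, ld_far, r2_max = 0.5, window_kb = 10000)), 2)
})

test_that("F-statistic is beta^2/se^2 and matches the z^2 identity", {
  expect_equal(f_statistic(0.05, 0.01), 25)
  expect_equal(f_statistic(0, 0.3), 0)
  expect_error(f_statistic(0.1, 0), "positive")
  set.seed(5)
  beta <- rnorm(50); se <- runif(50, 0.01, 1)
  expect_equal(f_statistic(beta, se), (beta / se)^2, tolerance = 1e-12)
})

test_that("F filtering is strict at the boundary and matches brute force", {
  df <- data.frame(snp = c("weak", "strong"), effect_allele = "A",
                   other_allele = "G", beta = c(0.03, 0.05), se = 0.01,
                   pval = 1e-9)
  s <- sumstat_set(df, "x", check_pval = FALSE)
  kept <- suppressMessages(filter_by_f(s, 10))
  expect_equal(kept$snp, "strong")   # F = 9 dropped, F = 25 kept
  set.seed(9)
  big <- sumstat_set(data.frame(snp = sprintf("rs%03d", 1:100),
                                effect_allele = "A", other_allele = "G",
                                beta = rnorm(100, 0, 0.05),
                                se = runif(100, 0.005, 0.02), pval = 1e-9),
                     "x", check_pval = FALSE)
  kept2 <- suppressMessages(filter_by_f(big, 10))
  expect_setequal(kept2$snp, big$snp[big$beta^2 / big$se^2 > 10])
})

test_that("variance explained sums 2*eaf*(1-eaf)*beta^2 and is additive", {
  one <- sumstat_set(data.frame(snp = "rs1", effect_allele = "A",
                                other_allele = "G", eaf = 0.5, beta = 0.1,
                                se = 0.01, pval = 1e-9), "x",
                     check_pval = FALSE)
  expect_equal(total_variance_explained(one), 0.005)

  s <- sumstat_set(toy_sumstats_df(), "x")
  expect_equal(total_variance_explained(s),
               sum(2 * s$eaf * (1 - s$eaf) * s$beta^2))
  # permutation invariance and additivity over disjoint subsets
  perm <- mrmediate:::.subset_set(s, c(3, 1, 2))
  expect_equal(total_variance_explained(perm), total_variance_explained(s))
  expect_equal(total_variance_explained(mrmediate:::.subset_set(s, 1:2)) +
                 total_variance_explained(mrmediate:::.subset_set(s, 3)),
               total_variance_explained(s))

  s_na <- s; s_na$eaf[2] <- NA
  expect_error(total_variance_explained(s_na), "rs2")
})

test_that("instrument metrics report F and per-SNP variance explained", {
  s <- sumstat_set(toy_sumstats_df(), "x")
  m <- instrument_metrics(s)
  expect_equal(m$f_stat, (s$beta / s$se)^2)
  expect_equal(sum(m$r2_explained), total_variance_explained(s))
})
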