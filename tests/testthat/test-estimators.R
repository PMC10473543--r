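test_that("Wald ratio arithmetic, sign handling, and failure mode", {
  h <- h_set(0.1, 0.02, se_out = 0.01)
  e <- wald_ratio(h)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.1)
  expect_equal(wald_ratio(h_set(0.1, 0))$beta, 0)
  e2 <- wald_ratio(h_set(-0.1, 0.02, se_out = 0.01))
  expect_equal(e2$se, 0.1)  # |beta_exp| in the denominator
  expect_error(wald_ratio(list(beta_exp = 0, beta_out = 1, se_out = 1)),
               "undefined")
})

test_that("IVW reduces correctly in homogeneous and replicated cases", {
  # identical Wald ratios: beta recovered exactly, Q = 0, fixed model
  h <- h_set(c(0.1, 0.2), c(0.01, 0.02))
  e <- ivw(h, "auto")
  expect_equal(e$beta, 0.1)
  expect_equal(e$effects_model, "fixed")
  expect_equal(cochran_q(h, "ivw")$q_stat, 0, tolerance = 1e-20)

  # J copies of one instrument: same beta, SE shrunk by sqrt(J)
  one <- h_set(0.1, 0.015, se_out = 0.02)
  e1 <- ivw(rbind(one, one), "fixed")
  e4 <- ivw(do.call(rbind, rep(list(one), 8)), "fixed")
  expect_equal(e4$beta, e1$beta)
  expect_equal(e4$se, e1$se / 2)
  expect_error(ivw(one), "wald_ratio")

  # equal se_out and equal beta_exp: simple mean of Wald ratios
  h_eq <- h_set(rep(0.1, 5), c(0.01, 0.013, 0.009, 0.011, 0.012),
                se_out = 0.01)
  expect_equal(ivw(h_eq, "fixed")$beta,
               mean(h_eq$beta_out / h_eq$beta_exp), tolerance = 1e-12)
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  for (seed in 1:20) {
    h <- random_h_set(10, seed)
    o <- wls_oracle(matrix(h$beta_exp), h$beta_out, 1 / h$se_out^2,
                    clip = FALSE)
    e <- ivw(h, "fixed")
    expect_equal(e$beta, unname(o$coefs), tolerance = 1e-10)
    expect_equal(e$se, 1 / sqrt(sum(h$beta_exp^2 / h$se_out^2)),
                 tolerance = 1e-10)
    # random-effects SE inflates by max(1, sqrt(Q/(J-1)))
    q <- cochran_q(h, "ivw")$q_stat
    expect_equal(ivw(h, "random")$se,
                 e$se * max(1, sqrt(q / (nrow(h) - 1))), tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers exact linear and affine structures", {
  x <- c(0.05, 0.1, 0.15, 0.2)
  h <- h_set(x, 0.1 * x)
  eg <- mr_egger(h)
  expect_equal(eg$estimate$beta, 0.1, tolerance = 1e-10)
  expect_equal(eg$pleiotropy$intercept, 0, tolerance = 1e-10)

  h2 <- h_set(x, 0.05 + 0.1 * x)
  eg2 <- mr_egger(h2)
  expect_equal(eg2$estimate$beta, 0.1, tolerance = 1e-10)
  expect_equal(eg2$pleiotropy$intercept, 0.05, tolerance = 1e-10)
  expect_error(mr_egger(h_set(c(0.1, 0.2), c(0.01, 0.02))), ">= 3")
})

test_that("MR-Egger matches a generic weighted-regression oracle", {
  for (seed in 1:20) {
    h <- random_h_set(20, seed + 100)
    flip <- ifelse(h$beta_exp < 0, -1, 1)
    o <- wls_oracle(cbind(1, h$beta_exp * flip), h$beta_out * flip,
                    1 / h$se_out^2)
    eg <- mr_egger(h)
    expect_equal(eg$pleiotropy$intercept, unname(o$coefs[1]),
                 tolerance = 1e-10)
    expect_equal(eg$estimate$beta, unname(o$coefs[2]), tolerance = 1e-10)
    expect_equal(eg$pleiotropy$se, unname(o$ses[1]), tolerance = 1e-10)
    expect_equal(eg$estimate$se, unname(o$ses[2]), tolerance = 1e-10)
  }
})

test_that("Egger slope is orientation-invariant when beta_exp > 0", {
  h <- random_h_set(15, 3)
  h$beta_exp <- abs(h$beta_exp)
  h$wald_ratio <- h$beta_out / h$beta_exp
  eg <- mr_egger(h)
  o <- wls_oracle(cbind(1, h$beta_exp), h$beta_out, 1 / h$se_out^2)
  expect_equal(eg$estimate$beta, unname(o$coefs[2]), tolerance = 1e-12)
})

test_that("weighted median handles symmetric and outlier-contaminated sets", {
  # ratios {1,2,3}, equal weights
  h <- h_set(rep(0.1, 3), c(0.1, 0.2, 0.3), se_out = 0.01)
  expect_equal(weighted_median(h, n_boot = 100, seed = 1)$beta, 2)
  # one gross outlier does not move the median
  h2 <- h_set(rep(0.1, 3), c(0.1, 0.2, 10), se_out = 0.01)
  expect_equal(weighted_median(h2, n_boot = 100, seed = 1)$beta, 2)
  expect_error(weighted_median(h_set(0.1, 0.1), n_boot = 100, seed = 1),
               ">= 3")
})

test_that("weighted median equals the grid-search oracle and the plain
           median under equal weights", {
  for (seed in 1:10) {
    h <- random_h_set(15, seed + 300)
    est <- weighted_median(h, n_boot = 100, seed = 1)$beta
    oracle <- grid_median_oracle(h$beta_out / h$beta_exp,
                                 (abs(h$beta_exp) / h$se_out)^2)
    expect_equal(est, oracle, tolerance = 1e-3)
  }
  # equal weights reduce to the interpolated ordinary median
  r <- c(0.05, 0.21, 0.13, 0.4, 0.18, 0.3)
  h_eq <- h_set(rep(0.1, 6), 0.1 * r, se_out = 0.01)
  est <- weighted_median(h_eq, n_boot = 100, seed = 1)$beta
  s <- (seq_along(r) - 0.5) / length(r)
  rs <- sort(r)
  j <- max(which(s < 0.5))
  expected <- rs[j] + (rs[j + 1] - rs[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
  expect_equal(est, expected, tolerance = 1e-12)
})

test_that("estimators are permutation-invariant; median is seed-stable", {
  h <- random_h_set(12, 77)
  perm <- h[sample(nrow(h)), ]
  expect_equal(ivw(perm, "fixed")$beta, ivw(h, "fixed")$beta,
               tolerance = 1e-14)
  expect_equal(mr_egger(perm)$estimate$beta, mr_egger(h)$estimate$beta,
               tolerance = 1e-12)
  wm1 <- weighted_median(h, n_boot = 200, seed = 42)
  wm2 <- weighted_median(h, n_boot = 200, seed = 42)
  expect_identical(wm1$beta, wm2$beta)
  expect_identical(wm1$se, wm2$se)
})

test_that("odds-ratio conversion exponentiates estimate and CI", {
  h <- random_h_set(10, 8)
  e <- to_odds_ratio(ivw(h, "fixed"))
  expect_equal(e$or, exp(e$beta), tolerance = 1e-12)
  expect_equal(e$or_ci_low, exp(e$ci_low), tolerance = 1e-12)
  expect_equal(e$or_ci_high, exp(e$ci_high), tolerance = 1e-12)
  e0 <- e; e0$beta <- 0; e0$ci_low <- 0; e0$ci_high <- 0
  expect_equal(to_odds_ratio(e0)$or, 1)
  # OR(-x) = 1/OR(x)
  em <- e; em$beta <- -e$beta
  expect_equal(to_odds_ratio(em)$or, 1 / e$or, tolerance = 1e-12)
  # the headline scale: beta = log(1.06) maps to OR 1.06
  e106 <- e; e106$beta <- log(1.06)
  expect_equal(to_odds_ratio(e106)$or, 1.06)
})
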