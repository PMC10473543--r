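#' Analytic power for two-sample MR with a binary outcome
#'
#' Normal-approximation non-centrality calculation: the IVW z-statistic
#' for a true odds ratio OR has expectation
#' `sqrt(n * r2_xz * k * (1 - k)) * |log(OR)|`, where `n` is the outcome
#' GWAS sample size, `k` the case fraction (case-control variance factor
#' k(1-k)) and `r2_xz` the variance in the exposure explained by the
#' instruments. Power at two-sided level `alpha` is
#' `pnorm(ncp - qnorm(1 - alpha/2))`.
#'
#' @param n total outcome sample size (cases + controls).
#' @param k case fraction in (0, 1).
#' @param r2_xz instrument variance explained, in (0, 1).
#' @param odds_ratio hypothesized causal OR per exposure unit (> 0).
#' @param alpha two-sided type-I error (default 0.05).
#' @return Power in \[0, 1\].
#' @export
#' @examples
#' mr_power_binary(n = 228951, k = 0.54, r2_xz = 0.2093, odds_ratio = 1.03)
mr_power_binary <- function(n, k, r2_xz, odds_ratio, alpha = 0.05) {
  stopifnot(n > 0, k > 0, k < 1, r2_xz > 0, r2_xz <= 1, odds_ratio > 0,
            alpha > 0, alpha < 1)
  ncp <- sqrt(n * r2_xz * k * (1 - k)) * abs(log(odds_ratio))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Minimum detectable odds ratio at a target power
#'
#' Smallest OR above 1 at which [mr_power_binary()] reaches
#' `target_power`, found by bisection to 1e-6 on the log-OR scale.
#'
#' @param n,k,r2_xz,alpha as in [mr_power_binary()].
#' @param target_power in (alpha, 1).
#' @return The minimum detectable odds ratio.
#' @export
min_detectable_or <- function(n, k, r2_xz, target_power = 0.8,
                              alpha = 0.05) {
  stopifnot(target_power > alpha, target_power < 1)
  f <- function(or) mr_power_binary(n, k, r2_xz, or, alpha) - target_power
  hi <- 2
  while (f(hi) < 0 && hi < 1e6) hi <- hi^2
  if (f(hi) < 0) stop("target power unreachable at any odds ratio")
  lo <- 1
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  hi
}

#' Power grid over odds ratios and case fractions
#'
#' Tabulates [mr_power_binary()] over a parameter grid, the usual way
#' power for subtype analyses is reported.
#'
#' @param n total outcome sample size.
#' @param k vector of case fractions.
#' @param r2_xz instrument variance explained.
#' @param odds_ratios vector of ORs (default 1.01 to 1.15).
#' @param alpha type-I error.
#' @return Data frame: `k`, `odds_ratio`, `power`.
#' @export
power_table <- function(n, k, r2_xz, odds_ratios = seq(1.01, 1.15, 0.01),
                        alpha = 0.05) {
  grid <- expand.grid(k = k, odds_ratio = odds_ratios,
                      KEEP.OUT.ATTRS = FALSE)
  grid$power <- mapply(function(kk, or)
    mr_power_binary(n, kk, r2_xz, or, alpha), grid$k, grid$odds_ratio)
  grid
}
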