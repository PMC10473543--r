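#' Cochran's Q heterogeneity test
#'
#' Q = sum over instruments of w_j (r_j - fitted_j)^2 with w_j the IVW
#' weights and r_j the Wald ratios. For `method = "ivw"` the fitted value
#' is the fixed-effect IVW estimate (df = J - 1); for `method = "egger"` it
#' is the Egger regression's fitted Wald ratio at each instrument
#' (df = J - 2). The p-value is the upper-tail chi-square probability.
#'
#' @param hs a `harmonized_set`.
#' @param method `"ivw"` (needs >= 2 instruments) or `"egger"` (>= 3).
#' @return List: `q_stat`, `df`, `pval`.
#' @export
cochran_q <- function(hs, method = c("ivw", "egger")) {
  method <- match.arg(method)
  J <- nrow(hs)
  w <- hs$beta_exp^2 / hs$se_out^2
  r <- hs$beta_out / hs$beta_exp
  if (method == "ivw") {
    if (J < 2) stop("Q (IVW) needs >= 2 instruments")
    fitted <- sum(w * r) / sum(w)
    df <- J - 1
  } else {
    if (J < 3) stop("Q (Egger) needs >= 3 instruments")
    eg <- mr_egger(hs)
    # Egger fitted outcome effect at instrument j, as a Wald ratio
    flip <- ifelse(hs$beta_exp < 0, -1, 1)
    fitted_out <- flip * (eg$pleiotropy$intercept +
                            eg$estimate$beta * hs$beta_exp * flip)
    fitted <- fitted_out / hs$beta_exp
    df <- J - 2
  }
  q <- sum(w * (r - fitted)^2)
  list(q_stat = q, df = df,
       pval = stats::pchisq(q, df = df, lower.tail = FALSE))
}

#' Fixed- vs random-effects decision rule
#'
#' Fixed effects when the heterogeneity p-value exceeds `alpha` (no
#' evidence of heterogeneity); random effects otherwise, including at
#' exactly `alpha` (strict ">").
#'
#' @param het result of [cochran_q()], or a list with `pval`.
#' @param alpha threshold (default 0.05).
#' @return `"fixed"` or `"random"`.
#' @export
select_effects_model <- function(het, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (het$pval > alpha) "fixed" else "random"
}

#' Egger-intercept pleiotropy check
#'
#' Directional pleiotropy is judged absent ("pass") when the intercept's
#' magnitude is below `intercept_bound` AND its p-value exceeds `alpha`.
#'
#' @param pleio list with `intercept` and `pval` (from [mr_egger()]).
#' @param intercept_bound magnitude bound (default 0.1).
#' @param alpha significance level (default 0.05).
#' @return `"pass"` or `"fail"`.
#' @export
egger_pleiotropy_check <- function(pleio, intercept_bound = 0.1,
                                   alpha = 0.05) {
  stopifnot(intercept_bound > 0, alpha > 0)
  if (abs(pleio$intercept) < intercept_bound && pleio$pval > alpha)
    "pass" else "fail"
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate J times, excluding one instrument each
#' time, with the same effects-model policy throughout. The robustness
#' flag is `TRUE` when no single exclusion flips the sign of the estimate
#' or moves a significant full-set estimate to non-significance (CI
#' crossing zero).
#'
#' @param hs a `harmonized_set` with >= 3 instruments.
#' @param effects_model,alpha passed to [ivw()].
#' @return List: `table` (data frame: snp, beta, se, ci_low, ci_high,
#'   pval), `full` (full-set `mr_estimate`), `robust` (logical).
#' @export
leave_one_out <- function(hs, effects_model = "auto", alpha = 0.05) {
  J <- nrow(hs)
  if (J < 3) stop("leave-one-out needs >= 3 instruments")
  full <- ivw(hs, effects_model, alpha)
  rows <- lapply(seq_len(J), function(j) {
    e <- ivw(hs[-j, , drop = FALSE], effects_model, alpha)
    data.frame(snp = hs$snp[j], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sign_stable <- all(sign(tab$beta) == sign(full$beta))
  signif_stable <- if (full$pval < alpha)
    all(tab$ci_low > 0 | tab$ci_high < 0) else TRUE
  list(table = tab, full = full, robust = sign_stable && signif_stable)
}

# leave-one-out IVW betas, vectorized: drop instrument j's contribution
# from the full-set weighted sums
.loo_ivw_beta <- function(beta_exp, beta_out, se_out) {
  w <- beta_exp^2 / se_out^2
  wr <- beta_exp * beta_out / se_out^2   # w * wald ratio
  (sum(wr) - wr) / (sum(w) - w)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Simulation-based residual diagnostic. For each instrument j the
#' leave-one-out IVW estimate b_(-j) gives an expected outcome effect
#' b_(-j) * beta_exp_j; the observed weighted residual
#' d_j^2 / se_out_j^2 contributes to the global RSS. `n_sim` parametric
#' simulations (exposure betas resampled around their observed values,
#' outcome betas around the leave-one-out expectations) give the null RSS
#' distribution; the global p uses the add-one Monte-Carlo convention.
#' Per-SNP outlier p-values come from each instrument's simulated residual
#' distribution, Bonferroni-adjusted across instruments; flagged
#' instruments are removed for the corrected IVW estimate, and a
#' distortion p compares corrected vs original estimates against random
#' removals of equally many instruments.
#'
#' @param hs a `harmonized_set` with >= 4 instruments.
#' @param n_sim simulation count (default 1000).
#' @param seed integer seed (mandatory).
#' @param outlier_alpha threshold on Bonferroni-adjusted outlier p
#'   (default 0.05).
#' @return List: `global_rss`, `global_pval`, `outlier_indices`,
#'   `outlier_pvals` (adjusted), `corrected_estimate` (`mr_estimate` or
#'   `NULL` when nothing was flagged), `distortion_pval` (or `NULL`).
#' @export
mr_presso <- function(hs, n_sim = 1000, seed, outlier_alpha = 0.05) {
  J <- nrow(hs)
  if (J < 4) stop("MR-PRESSO needs >= 4 instruments")
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_sim >= 100)

  loo_beta <- .loo_ivw_beta(hs$beta_exp, hs$beta_out, hs$se_out)
  d <- hs$beta_out - loo_beta * hs$beta_exp
  wres_obs <- d^2 / hs$se_out^2
  rss_obs <- sum(wres_obs)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sim_res <- matrix(NA_real_, n_sim, J)
  for (s in seq_len(n_sim)) {
    bx <- stats::rnorm(J, hs$beta_exp, hs$se_exp)
    by <- stats::rnorm(J, loo_beta * hs$beta_exp, hs$se_out)
    loo_s <- .loo_ivw_beta(bx, by, hs$se_out)
    ds <- by - loo_s * bx
    sim_res[s, ] <- ds^2 / hs$se_out^2
  }
  rss_sim <- rowSums(sim_res)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  p_raw <- vapply(seq_len(J), function(j)
    (1 + sum(sim_res[, j] >= wres_obs[j])) / (n_sim + 1), numeric(1))
  p_adj <- pmin(1, p_raw * J)
  flagged <- which(p_adj < outlier_alpha)
  if (length(flagged) == J) stop("all instruments flagged as outliers")

  corrected <- NULL
  distortion_pval <- NULL
  if (length(flagged)) {
    keep <- setdiff(seq_len(J), flagged)
    corrected <- ivw(hs[keep, , drop = FALSE], "auto")
    orig <- ivw(hs, "auto")
    obs_shift <- abs(corrected$beta - orig$beta)
    n_rem <- length(flagged)
    shifts <- vapply(seq_len(min(n_sim, 1000)), function(s) {
      drop_idx <- sample(J, n_rem)
      abs(ivw(hs[-drop_idx, , drop = FALSE], "fixed")$beta - orig$beta)
    }, numeric(1))
    distortion_pval <- (1 + sum(shifts >= obs_shift)) / (length(shifts) + 1)
  }
  list(global_rss = rss_obs, global_pval = global_pval,
       outlier_indices = flagged, outlier_pvals = p_adj,
       corrected_estimate = corrected, distortion_pval = distortion_pval)
}
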