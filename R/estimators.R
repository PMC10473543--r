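.mr_estimate <- function(method, beta, se, nsnp, effects_model = "not_applicable",
                         df = Inf) {
  stopifnot(se > 0)
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  z <- beta / se
  pval <- if (is.finite(df)) 2 * stats::pt(-abs(z), df) else 2 * stats::pnorm(-abs(z))
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pval = pval, nsnp = nsnp, effects_model = effects_model,
                 or = NULL, or_ci_low = NULL, or_ci_high = NULL),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (nsnp = %d, %s): beta = %.4f, se = %.4f, 95%% CI [%.4f, %.4f], p = %.4g\n",
              x$method, x$nsnp, x$effects_model, x$beta, x$se,
              x$ci_low, x$ci_high, x$pval))
  if (!is.null(x$or))
    cat(sprintf("  OR = %.4f (95%% CI %.4f-%.4f)\n", x$or, x$or_ci_low,
                x$or_ci_high))
  invisible(x)
}

#' Wald ratio estimate from a single instrument
#'
#' beta = beta_out / beta_exp with first-order SE = se_out / |beta_exp|;
#' normal CI and p-value.
#'
#' @param h one-row `harmonized_set` (or list with `beta_exp`, `beta_out`,
#'   `se_out`).
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(h) {
  if (is.data.frame(h)) {
    stopifnot(nrow(h) == 1)
    h <- as.list(h)
  }
  if (h$beta_exp == 0) stop("beta_exp = 0: Wald ratio undefined")
  .mr_estimate("wald", h$beta_out / h$beta_exp, h$se_out / abs(h$beta_exp),
               nsnp = 1L)
}

#' Cochran's Q for a set of Wald ratios (internal core)
#' @noRd
.ivw_core <- function(hs) {
  w <- hs$beta_exp^2 / hs$se_out^2
  r <- hs$beta_out / hs$beta_exp
  beta <- sum(w * r) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (r - beta)^2)
  list(beta = beta, se_fixed = se_fixed, q = q, w = w, r = r)
}

#' Inverse-variance-weighted estimate
#'
#' Meta-analysis of per-SNP Wald ratios with first-order weights
#' w_j = beta_exp_j^2 / se_out_j^2 — algebraically the weighted
#' least-squares regression of `beta_out` on `beta_exp` through the origin
#' with weights `se_out^-2`. Fixed-effect SE is `(sum w)^-1/2`; the
#' multiplicative random-effects SE inflates it by
#' `max(1, sqrt(Q / (J - 1)))`. `effects_model = "auto"` applies the
#' heterogeneity decision rule: fixed when the Cochran Q p-value exceeds
#' `alpha`, random otherwise.
#'
#' @param hs a `harmonized_set` with at least 2 instruments.
#' @param effects_model `"fixed"`, `"random"`, or `"auto"`.
#' @param alpha heterogeneity test level for `"auto"` (default 0.05).
#' @return An `mr_estimate`.
#' @export
ivw <- function(hs, effects_model = c("auto", "fixed", "random"),
                alpha = 0.05) {
  effects_model <- match.arg(effects_model)
  if (nrow(hs) < 2)
    stop("IVW needs >= 2 instruments; use wald_ratio() for one")
  core <- .ivw_core(hs)
  J <- nrow(hs)
  if (effects_model == "auto") {
    q_p <- stats::pchisq(core$q, df = J - 1, lower.tail = FALSE)
    effects_model <- if (q_p > alpha) "fixed" else "random"
  }
  se <- if (effects_model == "fixed") core$se_fixed
        else core$se_fixed * max(1, sqrt(core$q / (J - 1)))
  .mr_estimate("ivw", core$beta, se, J, effects_model)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' an intercept, weights `se_out^-2`, after orienting every instrument so
#' its exposure beta is positive (both betas negated where needed). The
#' slope is the pleiotropy-adjusted causal estimate; the intercept
#' estimates the average directional pleiotropy. SEs are inflated by
#' `max(1, sqrt(RSS_w / (J - 2)))`; p-values use t with J - 2 df.
#'
#' @param hs a `harmonized_set` with at least 3 instruments.
#' @return List with elements `estimate` (`mr_estimate` for the slope) and
#'   `pleiotropy` (list: `intercept`, `se`, `pval`).
#' @export
mr_egger <- function(hs) {
  J <- nrow(hs)
  if (J < 3) stop("MR-Egger needs >= 3 instruments")
  flip <- ifelse(hs$beta_exp < 0, -1, 1)
  x <- hs$beta_exp * flip
  y <- hs$beta_out * flip
  w <- 1 / hs$se_out^2
  X <- cbind(intercept = 1, x = x)
  XtWX <- crossprod(X, w * X)
  coefs <- drop(solve(XtWX, crossprod(X, w * y)))
  resid <- y - drop(X %*% coefs)
  rss_w <- sum(w * resid^2)
  # model-based covariance with multiplicative overdispersion, clipped at 1
  phi <- max(1, rss_w / (J - 2))
  ses <- sqrt(diag(solve(XtWX)) * phi)
  slope <- coefs[["x"]]
  intercept <- coefs[["intercept"]]
  se_slope <- ses[["x"]]
  se_int <- ses[["intercept"]]
  est <- .mr_estimate("egger", slope, se_slope, J, "random", df = J - 2)
  pleio <- list(intercept = intercept, se = se_int,
                pval = 2 * stats::pt(-abs(intercept / se_int), J - 2))
  list(estimate = est, pleiotropy = pleio)
}

#' Weighted-median estimate
#'
#' Sorts Wald ratios ascending and takes the value where the normalized
#' cumulative weight (midpoint convention
#' `s_j = (cumsum(w)_j - w_j / 2) / sum(w)`) crosses one half, with linear
#' interpolation between the bracketing ratios. Weights are the inverse
#' first-order Wald-ratio variances. Consistent when at least half the
#' total weight comes from valid instruments. The SE comes from a
#' parametric bootstrap: exposure and outcome betas are resampled from
#' normal distributions with their reported SEs and the estimate
#' recomputed.
#'
#' @param hs a `harmonized_set` with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000, minimum 100).
#' @param seed integer seed (mandatory, for reproducibility).
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(hs, n_boot = 1000, seed) {
  if (nrow(hs) < 3) stop("weighted median needs >= 3 instruments")
  if (missing(seed)) stop("seed is mandatory for the bootstrap SE")
  stopifnot(n_boot >= 100)
  est <- .weighted_median_point(hs$beta_out / hs$beta_exp,
                                (abs(hs$beta_exp) / hs$se_out)^2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boots <- replicate(n_boot, {
    bx <- stats::rnorm(nrow(hs), hs$beta_exp, hs$se_exp)
    by <- stats::rnorm(nrow(hs), hs$beta_out, hs$se_out)
    ok <- bx != 0
    .weighted_median_point(by[ok] / bx[ok], (abs(bx[ok]) / hs$se_out[ok])^2)
  })
  .mr_estimate("weighted_median", est, stats::sd(boots), nrow(hs))
}

# weighted median point estimate: interpolate where cumulative weight
# midpoints cross 1/2
.weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]; w <- weights[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(s)])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Convert an estimate to the odds-ratio scale
#'
#' Populates `or`, `or_ci_low`, `or_ci_high` by exponentiating the log-odds
#' estimate and its CI. Only meaningful for binary outcomes.
#'
#' @param e an `mr_estimate`.
#' @return The estimate with odds-ratio fields populated.
#' @export
to_odds_ratio <- function(e) {
  stopifnot(inherits(e, "mr_estimate"))
  e$or <- exp(e$beta)
  e$or_ci_low <- exp(e$ci_low)
  e$or_ci_high <- exp(e$ci_high)
  e
}
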