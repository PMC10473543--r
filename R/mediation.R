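#' Classify a two-step MR mediation pattern
#'
#' Decision table on the significance of the total effect (beta0), the
#' exposure-to-mediator effect (beta1) and the mediator-to-outcome effect
#' (beta2), all at two-sided level `alpha`:
#' \itemize{
#'   \item all three significant: \strong{partial} mediation;
#'   \item beta0 not significant, beta1 and beta2 both significant:
#'     \strong{full} mediation;
#'   \item beta0 significant but beta1 or beta2 not: \strong{none} (the
#'     mediator carries no detectable indirect path);
#'   \item beta0 not significant and beta1 or beta2 not:
#'     \strong{no_causal_path}.
#' }
#' The proportion mediated is reported only for partial/full
#' classifications.
#'
#' @param beta0,beta1,beta2 lists (or `mr_estimate` objects) carrying
#'   `beta`, `se`, `pval`.
#' @param alpha significance threshold (default 0.05).
#' @return A `mediation_result`: list with `classification`,
#'   `indirect_effect` (beta1 * beta2), `indirect_se` (delta method),
#'   `proportion_mediated` (NA unless partial/full), and the three input
#'   effects.
#' @export
classify_mediation <- function(beta0, beta1, beta2, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  g <- function(e) list(beta = e$beta, se = e$se, pval = e$pval)
  b0 <- g(beta0); b1 <- g(beta1); b2 <- g(beta2)
  stopifnot(b0$se > 0, b1$se > 0, b2$se > 0)
  s0 <- b0$pval < alpha; s1 <- b1$pval < alpha; s2 <- b2$pval < alpha
  classification <-
    if (s1 && s2) { if (s0) "partial" else "full" }
    else { if (s0) "none" else "no_causal_path" }
  indirect <- b1$beta * b2$beta
  prop <- if (classification %in% c("partial", "full") && b0$beta != 0)
    proportion_mediated(b0$beta, b1$beta, b2$beta) else NA_real_
  structure(list(classification = classification,
                 indirect_effect = indirect,
                 indirect_se = indirect_effect_se(b1$beta, b1$se,
                                                  b2$beta, b2$se),
                 proportion_mediated = prop,
                 beta0 = b0, beta1 = b1, beta2 = b2, alpha = alpha),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation classification:", x$classification, "\n")
  cat(sprintf("  beta0 = %.4f (p = %.4g), beta1 = %.4f (p = %.4g), beta2 = %.4f (p = %.4g)\n",
              x$beta0$beta, x$beta0$pval, x$beta1$beta, x$beta1$pval,
              x$beta2$beta, x$beta2$pval))
  cat(sprintf("  indirect effect = %.4f (se %.4f)", x$indirect_effect,
              x$indirect_se))
  if (!is.na(x$proportion_mediated))
    cat(sprintf(", proportion mediated = %.2f%%",
                100 * x$proportion_mediated))
  cat("\n")
  invisible(x)
}

#' Proportion of a total effect carried by a mediator
#'
#' beta1 * beta2 / beta0: the product-of-coefficients indirect effect as a
#' fraction of the total effect. Values outside \[0, 1\] (inconsistent
#' mediation, e.g. opposing direct and indirect paths) are returned as
#' computed with a warning, not clipped.
#'
#' @param beta0 total effect (nonzero; log-odds scale for binary
#'   outcomes).
#' @param beta1 exposure-to-mediator effect.
#' @param beta2 mediator-to-outcome effect.
#' @return The proportion (dimensionless).
#' @export
#' @examples
#' proportion_mediated(log(1.06), 0.0438, 0.1467) # ~0.11
proportion_mediated <- function(beta0, beta1, beta2) {
  if (beta0 == 0) stop("beta0 = 0: proportion undefined")
  p <- beta1 * beta2 / beta0
  if (p < 0 || p > 1)
    warning("proportion mediated ", signif(p, 4),
            " outside [0, 1]: inconsistent mediation")
  p
}

#' Delta-method SE of the indirect effect beta1 * beta2
#'
#' sqrt(beta2^2 * se1^2 + beta1^2 * se2^2), the first-order approximation
#' assuming independent estimates (the two steps use non-overlapping
#' samples in a two-step design).
#'
#' @param beta1,se1 exposure-to-mediator estimate and SE.
#' @param beta2,se2 mediator-to-outcome estimate and SE.
#' @return Standard error of the product.
#' @export
indirect_effect_se <- function(beta1, se1, beta2, se2) {
  stopifnot(se1 >= 0, se2 >= 0)
  sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
}
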