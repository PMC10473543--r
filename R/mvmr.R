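#' Assemble a multivariable MR input
#'
#' Instruments are the union of each exposure's genome-wide-significant,
#' clumped SNPs; the union is jointly clumped (best p across exposures per
#' SNP), then every SNP is harmonized against each exposure and the
#' outcome on the first exposure's effect-allele orientation. SNPs missing
#' from any trait, palindromic or irreconcilable, are dropped with logged
#' counts.
#'
#' @param exposure_sets list of >= 2 [sumstat_set] objects (the exposure of
#'   interest plus mediators / covariate exposures).
#' @param outcome_set outcome [sumstat_set].
#' @param ld optional [ld_matrix()] for the joint clump; `NULL` skips
#'   clumping.
#' @param p_threshold,r2_max,window_kb instrument-selection thresholds.
#' @return An `mvmr_input`: list with `snp_ids`, `exposure_beta`
#'   (J x K matrix), `exposure_se`, `beta_out`, `se_out`,
#'   `exposure_labels`, `n_dropped`.
#' @export
build_mvmr_input <- function(exposure_sets, outcome_set, ld = NULL,
                             p_threshold = 5e-8, r2_max = 0.001,
                             window_kb = 10000) {
  stopifnot(is.list(exposure_sets), length(exposure_sets) >= 2)
  K <- length(exposure_sets)
  labels <- vapply(exposure_sets, function(s)
    attr(s, "trait_label"), character(1))

  # per-exposure instrument selection, then union
  insts <- lapply(exposure_sets, function(s) {
    out <- filter_by_pvalue(s, p_threshold)
    if (!is.null(ld) && nrow(out)) out <- ld_clump(out, ld, r2_max, window_kb)
    out$snp
  })
  union_snps <- unique(unlist(insts))
  if (!length(union_snps)) stop("no instruments selected for any exposure")

  # joint clump on the union, ranked by each SNP's best p across exposures
  if (!is.null(ld)) {
    best_p <- vapply(union_snps, function(id) {
      min(vapply(exposure_sets, function(s) {
        p <- s$pval[s$snp == id]
        if (length(p)) p else Inf
      }, numeric(1)))
    }, numeric(1))
    pseudo <- sumstat_set(data.frame(
      snp = union_snps, effect_allele = "A", other_allele = "G",
      beta = 1, se = 1, pval = best_p, stringsAsFactors = FALSE),
      trait_label = "union", check_pval = FALSE)
    union_snps <- ld_clump(pseudo, ld, r2_max, window_kb)$snp
  }

  # keep SNPs present in every exposure and the outcome
  present <- Reduce(intersect, c(lapply(exposure_sets, function(s) s$snp),
                                 list(outcome_set$snp)))
  snps <- intersect(union_snps, present)
  n_missing <- length(union_snps) - length(snps)
  if (n_missing)
    message("build_mvmr_input: dropped ", n_missing,
            " SNP(s) missing from at least one trait")
  if (!length(snps)) stop("no SNPs shared across all traits")

  # harmonize each exposure and the outcome to exposure 1's orientation
  ref <- .subset_set(exposure_sets[[1]], match(snps, exposure_sets[[1]]$snp))
  beta_x <- matrix(NA_real_, length(snps), K,
                   dimnames = list(snps, labels))
  se_x <- beta_x
  keep <- rep(TRUE, length(snps))
  align <- function(set) {
    hlist <- lapply(seq_along(snps), function(i) {
      rec <- as.data.frame(set)[set$snp == snps[i], ]
      harmonize_pair(as.data.frame(ref)[i, ], rec)
    })
    hlist
  }
  beta_x[, 1] <- ref$beta
  se_x[, 1] <- ref$se
  for (k in seq_len(K)[-1]) {
    hk <- align(exposure_sets[[k]])
    for (i in seq_along(snps)) {
      if (is.character(hk[[i]])) keep[i] <- FALSE
      else { beta_x[i, k] <- hk[[i]]$beta_out; se_x[i, k] <- hk[[i]]$se_out }
    }
  }
  ho <- align(outcome_set)
  beta_out <- se_out <- rep(NA_real_, length(snps))
  for (i in seq_along(snps)) {
    if (is.character(ho[[i]])) keep[i] <- FALSE
    else { beta_out[i] <- ho[[i]]$beta_out; se_out[i] <- ho[[i]]$se_out }
  }
  n_dropped <- n_missing + sum(!keep)
  if (any(!keep))
    message("build_mvmr_input: excluded ", sum(!keep),
            " SNP(s) during harmonization (palindromic or mismatched)")
  if (!any(keep)) stop("no SNPs survived MVMR harmonization")
  structure(list(snp_ids = snps[keep],
                 exposure_beta = beta_x[keep, , drop = FALSE],
                 exposure_se = se_x[keep, , drop = FALSE],
                 beta_out = beta_out[keep], se_out = se_out[keep],
                 exposure_labels = labels, n_dropped = n_dropped),
            class = "mvmr_input")
}

#' Construct an MVMR input directly from matrices
#'
#' Lower-level constructor for already-harmonized data (e.g. simulator
#' output).
#'
#' @param snp_ids character vector, length J.
#' @param exposure_beta,exposure_se J x K numeric matrices.
#' @param beta_out,se_out numeric vectors, length J.
#' @return An `mvmr_input`.
#' @export
mvmr_input <- function(snp_ids, exposure_beta, exposure_se, beta_out,
                       se_out) {
  exposure_beta <- as.matrix(exposure_beta)
  exposure_se <- as.matrix(exposure_se)
  stopifnot(length(snp_ids) == nrow(exposure_beta),
            all(dim(exposure_beta) == dim(exposure_se)),
            length(beta_out) == length(snp_ids),
            length(se_out) == length(snp_ids),
            all(se_out > 0), all(exposure_se > 0),
            !anyNA(exposure_beta))
  if (is.null(colnames(exposure_beta)))
    colnames(exposure_beta) <- paste0("x", seq_len(ncol(exposure_beta)))
  structure(list(snp_ids = snp_ids, exposure_beta = exposure_beta,
                 exposure_se = exposure_se, beta_out = beta_out,
                 se_out = se_out,
                 exposure_labels = colnames(exposure_beta),
                 n_dropped = 0L),
            class = "mvmr_input")
}

#' Multivariable MR fit
#'
#' Weighted least squares of outcome effects on the K exposure-effect
#' columns, no intercept, weights `se_out^-2`. SEs carry a multiplicative
#' overdispersion factor `max(1, sqrt(RSS_w / (J - K)))`; p-values use t
#' with J - K df. With K = 1 this reduces to the multiplicative
#' random-effects IVW estimate. Conditional F-statistics per exposure are
#' reported as a weak-instrument diagnostic (regression of each exposure
#' column on the others).
#'
#' @param input an `mvmr_input`.
#' @return An `mvmr_estimate`: data frame with one row per exposure
#'   (`exposure`, `beta`, `se`, `pval`, `conditional_f`).
#' @export
mvmr_fit <- function(input) {
  stopifnot(inherits(input, "mvmr_input"))
  X <- input$exposure_beta
  J <- nrow(X); K <- ncol(X)
  if (J <= K) stop("need more SNPs (", J, ") than exposures (", K, ")")
  qrX <- qr(X)
  if (qrX$rank < K)
    stop("rank-deficient exposure matrix; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):K]], collapse = ", "))
  w <- 1 / input$se_out^2
  XtWX <- crossprod(X, w * X)
  coefs <- drop(solve(XtWX, crossprod(X, w * input$beta_out)))
  resid <- input$beta_out - drop(X %*% coefs)
  rss_w <- sum(w * resid^2)
  phi <- max(1, rss_w / (J - K))
  ses <- sqrt(diag(solve(XtWX)) * phi)
  pvals <- 2 * stats::pt(-abs(coefs / ses), J - K)

  cond_f <- vapply(seq_len(K), function(k) {
    if (K == 1) return(mean(X[, 1]^2 / input$exposure_se[, 1]^2))
    others <- X[, -k, drop = FALSE]
    fit <- stats::lm.fit(others, X[, k])
    r <- fit$residuals
    mean(r^2 / input$exposure_se[, k]^2)
  }, numeric(1))

  structure(data.frame(exposure = input$exposure_labels,
                       beta = unname(coefs), se = unname(ses),
                       pval = unname(pvals), conditional_f = cond_f,
                       stringsAsFactors = FALSE, row.names = NULL),
            nsnp = J, class = c("mvmr_estimate", "data.frame"))
}
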