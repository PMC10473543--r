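#' Filter summary statistics at a p-value threshold
#'
#' Retains SNPs with `pval < threshold` (strict inequality, matching the
#' conventional genome-wide significance rule p < 5e-8). Order preserved.
#'
#' @param set a [sumstat_set].
#' @param threshold p-value threshold in (0, 1].
#' @return The filtered [sumstat_set] (possibly empty of rows, with a
#'   message).
#' @export
filter_by_pvalue <- function(set, threshold = 5e-8) {
  stopifnot(inherits(set, "sumstat_set"),
            is.numeric(threshold), threshold > 0, threshold <= 1)
  keep <- set$pval < threshold
  if (!any(keep))
    message("filter_by_pvalue: no SNPs pass p < ", format(threshold))
  .subset_set(set, keep)
}

.subset_set <- function(set, keep) {
  out <- as.data.frame(set)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_label = attr(set, "trait_label"),
            trait_type = attr(set, "trait_type"),
            drop_report = attr(set, "drop_report"),
            class = c("sumstat_set", "data.frame"))
}

#' Construct an LD matrix object
#'
#' Pairwise squared correlations (r2) between SNPs, used as input to
#' [ld_clump()]. Symmetric, unit diagonal, values in \[0,1\].
#'
#' @param r2 square numeric matrix with dimnames giving SNP ids, or `NULL`
#'   with `snp_ids` for an identity matrix.
#' @param snp_ids character vector of SNP ids (required when `r2` lacks
#'   dimnames).
#' @param positions optional named numeric vector of base-pair coordinates.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(r2 = NULL, snp_ids = NULL, positions = NULL) {
  if (is.null(r2)) {
    stopifnot(!is.null(snp_ids))
    r2 <- diag(length(snp_ids))
    dimnames(r2) <- list(snp_ids, snp_ids)
  }
  if (is.null(rownames(r2))) {
    stopifnot(!is.null(snp_ids), length(snp_ids) == nrow(r2))
    dimnames(r2) <- list(snp_ids, snp_ids)
  }
  stopifnot(nrow(r2) == ncol(r2), identical(rownames(r2), colnames(r2)))
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix is not symmetric")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("r2 diagonal must be 1")
  if (min(r2) < -1e-12 || max(r2) > 1 + 1e-12)
    stop("r2 values must lie in [0, 1]")
  if (!is.null(positions)) {
    stopifnot(!is.null(names(positions)),
              all(rownames(r2) %in% names(positions)))
    positions <- positions[rownames(r2)]
  }
  structure(list(snp_ids = rownames(r2), r2 = r2, positions = positions),
            class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Accepts either a square layout (header row of SNP ids, first column of
#' SNP ids) or a long 3-column layout (`snp_a`, `snp_b`, `r2`; unlisted
#' pairs are taken as r2 = 0).
#'
#' @param path file path.
#' @return An [ld_matrix()] object.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) == 3 && all(c("snp_a", "snp_b", "r2") %in% names(df))) {
    ids <- sort(unique(c(df$snp_a, df$snp_b)))
    m <- diag(length(ids)); dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(df))) {
      m[df$snp_a[i], df$snp_b[i]] <- df$r2[i]
      m[df$snp_b[i], df$snp_a[i]] <- df$r2[i]
    }
    return(ld_matrix(m))
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(ids, colnames(m))
  ld_matrix(m)
}

#' Greedy LD clumping
#'
#' Standard index-SNP selection: repeatedly take the remaining SNP with the
#' smallest p-value, then discard all remaining SNPs with squared
#' correlation `r2 >= r2_max` against it and — when positions are available —
#' within `window_kb` of it. Ties in p are broken by lexicographic snp id,
#' so the result is invariant to input row order.
#'
#' @param set a [sumstat_set].
#' @param ld an [ld_matrix()] covering every SNP in `set`.
#' @param r2_max clumping threshold (default 0.001).
#' @param window_kb distance window in kb (default 10000); applied only when
#'   `ld` carries positions.
#' @return The clumped [sumstat_set], index SNPs in selection order.
#' @export
ld_clump <- function(set, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(set, "sumstat_set"), inherits(ld, "ld_matrix"),
            r2_max > 0, r2_max < 1, window_kb > 0)
  missing_ids <- setdiff(set$snp, ld$snp_ids)
  if (length(missing_ids))
    stop("SNP(s) missing from LD matrix: ",
         paste(missing_ids, collapse = ", "))
  remaining <- set$snp[order(set$pval, set$snp)]
  pos <- ld$positions
  selected <- character(0)
  while (length(remaining)) {
    idx <- remaining[1]
    selected <- c(selected, idx)
    remaining <- remaining[-1]
    if (!length(remaining)) break
    conflict <- ld$r2[idx, remaining] >= r2_max
    if (!is.null(pos)) {
      near <- abs(pos[remaining] - pos[idx]) <= window_kb * 1000
      conflict <- conflict & near
    }
    remaining <- remaining[!conflict]
  }
  .subset_set(set, match(selected, set$snp))
}

#' Instrument-strength F-statistic
#'
#' F = beta^2 / se^2, the square of the z-score; values above 10
#' conventionally indicate low weak-instrument bias.
#'
#' @param beta,se per-SNP effect and standard error (vectorized); `se > 0`.
#' @return Numeric vector of F-statistics.
#' @export
#' @examples
#' f_statistic(0.05, 0.01) # 25
f_statistic <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) stop("se must be positive")
  beta^2 / se^2
}

#' Filter instruments by F-statistic
#'
#' Retains SNPs with `F > f_min` (strict) and logs the retained F range,
#' as reported in instrument-strength summaries.
#'
#' @param set a [sumstat_set].
#' @param f_min minimum F (default 10).
#' @return Filtered [sumstat_set].
#' @export
filter_by_f <- function(set, f_min = 10) {
  stopifnot(inherits(set, "sumstat_set"), f_min >= 0)
  f <- f_statistic(set$beta, set$se)
  keep <- f > f_min
  if (any(keep))
    message("filter_by_f: retained ", sum(keep), " SNPs, F range ",
            sprintf("%.2f-%.2f", min(f[keep]), max(f[keep])))
  else message("filter_by_f: no SNPs retained at F > ", f_min)
  .subset_set(set, keep)
}

#' Total variance explained by an instrument set
#'
#' R^2 = sum over SNPs of 2 * EAF * (1 - EAF) * beta^2, the standard
#' per-allele approximation for a standardized trait.
#'
#' @param set a [sumstat_set] whose records all carry `eaf`.
#' @return Proportion of variance explained.
#' @export
total_variance_explained <- function(set) {
  stopifnot(inherits(set, "sumstat_set"))
  miss <- is.na(set$eaf)
  if (any(miss))
    stop("missing eaf for SNP(s): ", paste(set$snp[miss], collapse = ", "))
  sum(2 * set$eaf * (1 - set$eaf) * set$beta^2)
}

#' Per-SNP instrument metrics
#'
#' @param set a [sumstat_set].
#' @return Data frame with `snp`, `f_stat`, `r2_explained` (NA when eaf is
#'   missing).
#' @export
instrument_metrics <- function(set) {
  stopifnot(inherits(set, "sumstat_set"))
  data.frame(snp = set$snp,
             f_stat = f_statistic(set$beta, set$se),
             r2_explained = ifelse(is.na(set$eaf), NA_real_,
                                   2 * set$eaf * (1 - set$eaf) * set$beta^2),
             stringsAsFactors = FALSE)
}

#' Select instruments: significance filter, clumping, strength filter
#'
#' Convenience wrapper chaining [filter_by_pvalue()], [ld_clump()] and
#' [filter_by_f()] at the usual thresholds.
#'
#' @param set a [sumstat_set].
#' @param ld an [ld_matrix()]; `NULL` skips clumping (instruments assumed
#'   quasi-independent).
#' @param p_threshold,r2_max,window_kb,f_min selection thresholds.
#' @return Filtered [sumstat_set].
#' @export
select_instruments <- function(set, ld = NULL, p_threshold = 5e-8,
                               r2_max = 0.001, window_kb = 10000,
                               f_min = 10) {
  out <- filter_by_pvalue(set, p_threshold)
  if (!is.null(ld) && nrow(out)) out <- ld_clump(out, ld, r2_max, window_kb)
  if (nrow(out)) out <- filter_by_f(out, f_min)
  out
}
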