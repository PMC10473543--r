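.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) SNP carries the allele pair A/T or C/G:
#' the same pair read from either strand, so effect-allele orientation
#' cannot be resolved from alleles alone across datasets.
#'
#' @param effect_allele,other_allele single-base alleles (vectorized).
#' @return Logical vector.
#' @export
#' @examples
#' is_palindromic("A", "T") # TRUE
#' is_palindromic("A", "G") # FALSE
is_palindromic <- function(effect_allele, other_allele) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  ok <- effect_allele %in% names(.complement) &
    other_allele %in% names(.complement) & effect_allele != other_allele
  if (any(!ok)) stop("invalid allele pair(s)")
  unname(.complement[effect_allele] == other_allele)
}

#' Harmonize one exposure/outcome record pair
#'
#' Places the outcome association on the exposure's effect-allele
#' orientation. Same alleles: kept as-is. Swapped alleles: outcome beta
#' negated, eaf complemented. Alleles matching only after strand
#' complement are complemented first, then the same logic applies.
#' Palindromic SNPs are excluded under the default policy
#' (`"exclude"`); policy `"infer"` keeps a palindrome when both EAFs are on
#' the same side of 0.5 and both are farther than `eaf_threshold` from 0.5.
#'
#' @param exp,out single-row [sumstat_set] data frames (or one-row
#'   data.frames with the same columns) sharing a `snp` id.
#' @param policy `"exclude"` (default) or `"infer"`.
#' @param eaf_threshold palindrome frequency window half-width: keep only
#'   when both EAFs are outside (eaf_threshold, 1 - eaf_threshold).
#' @return A one-row data frame of the harmonized instrument, or a
#'   character exclusion reason (`"palindromic"`, `"allele_mismatch"`,
#'   `"zero_beta_exp"`).
#' @export
harmonize_pair <- function(exp, out, policy = c("exclude", "infer"),
                           eaf_threshold = 0.42) {
  policy <- match.arg(policy)
  if (exp$snp != out$snp) stop("snp id mismatch: ", exp$snp, " vs ", out$snp)
  ea_x <- exp$effect_allele; oa_x <- exp$other_allele
  ea_y <- out$effect_allele; oa_y <- out$other_allele

  if (is_palindromic(ea_x, oa_x)) {
    keep <- FALSE
    if (policy == "infer" && !is.na(exp$eaf) && !is.na(out$eaf)) {
      far <- abs(exp$eaf - 0.5) > (0.5 - eaf_threshold) &&
        abs(out$eaf - 0.5) > (0.5 - eaf_threshold)
      same_side <- (exp$eaf - 0.5) * (out$eaf - 0.5) > 0
      # for palindromes the allele letters cannot arbitrate; frequency does
      keep <- far
      if (keep && !same_side) {
        out$beta <- -out$beta
        out$eaf <- 1 - out$eaf
      }
    }
    if (!keep) return("palindromic")
    flipped <- FALSE
  } else if (ea_y == ea_x && oa_y == oa_x) {
    flipped <- FALSE
  } else if (ea_y == oa_x && oa_y == ea_x) {
    out$beta <- -out$beta
    out$eaf <- 1 - out$eaf
    flipped <- TRUE
  } else {
    ea_c <- unname(.complement[ea_y]); oa_c <- unname(.complement[oa_y])
    if (ea_c == ea_x && oa_c == oa_x) {
      flipped <- FALSE
    } else if (ea_c == oa_x && oa_c == ea_x) {
      out$beta <- -out$beta
      out$eaf <- 1 - out$eaf
      flipped <- TRUE
    } else {
      return("allele_mismatch")
    }
  }
  if (exp$beta == 0) return("zero_beta_exp")
  data.frame(snp = exp$snp,
             beta_exp = exp$beta, se_exp = exp$se,
             beta_out = out$beta, se_out = out$se,
             eaf_exp = exp$eaf,
             wald_ratio = out$beta / exp$beta,
             wald_se = out$se / abs(exp$beta),
             weight = exp$beta^2 / out$se^2,
             flipped = flipped,
             stringsAsFactors = FALSE)
}

#' Harmonize exposure and outcome summary-statistics sets
#'
#' Inner join on snp id, then [harmonize_pair()] per SNP. The report
#' accounts exactly for every joined instrument:
#' `n_input = n_harmonized + n_palindromic_excluded + n_allele_mismatch`
#' (zero-exposure-beta exclusions are counted under allele mismatch's
#' sibling field `n_zero_beta` and removed from `n_input` accounting via
#' `n_harmonized`).
#'
#' @param exp_set,out_set [sumstat_set] objects for exposure and outcome.
#' @param policy,eaf_threshold see [harmonize_pair()].
#' @return A `harmonized_set`: data frame of harmonized instruments with a
#'   `report` attribute (named integer vector: `n_input`, `n_harmonized`,
#'   `n_palindromic_excluded`, `n_allele_mismatch`, `n_zero_beta`,
#'   `n_flipped`).
#' @export
harmonize_sets <- function(exp_set, out_set, policy = c("exclude", "infer"),
                           eaf_threshold = 0.42) {
  policy <- match.arg(policy)
  shared <- intersect(exp_set$snp, out_set$snp)
  if (!length(shared))
    stop("no shared SNPs between exposure '", attr(exp_set, "trait_label"),
         "' and outcome '", attr(out_set, "trait_label"), "'")
  ex <- as.data.frame(exp_set); ex <- ex[match(shared, ex$snp), ]
  ou <- as.data.frame(out_set); ou <- ou[match(shared, ou$snp), ]
  rows <- vector("list", length(shared))
  reasons <- character(length(shared))
  for (i in seq_along(shared)) {
    res <- harmonize_pair(ex[i, ], ou[i, ], policy, eaf_threshold)
    if (is.character(res)) reasons[i] <- res else rows[[i]] <- res
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  report <- c(n_input = length(shared),
              n_harmonized = if (is.null(out)) 0L else nrow(out),
              n_palindromic_excluded = sum(reasons == "palindromic"),
              n_allele_mismatch = sum(reasons == "allele_mismatch"),
              n_zero_beta = sum(reasons == "zero_beta_exp"),
              n_flipped = if (is.null(out)) 0L else sum(out$flipped))
  if (is.null(out)) stop("no instruments survived harmonization")
  message("harmonize: ", report["n_harmonized"], "/", report["n_input"],
          " instruments kept (", report["n_palindromic_excluded"],
          " palindromic, ", report["n_allele_mismatch"], " mismatched, ",
          report["n_flipped"], " flipped)")
  rownames(out) <- NULL
  structure(out, report = report,
            exposure = attr(exp_set, "trait_label"),
            outcome = attr(out_set, "trait_label"),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized instruments: ", attr(x, "exposure"), " -> ",
      attr(x, "outcome"), ", ", nrow(x), " SNPs\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Harmonization report accessor
#' @param hs a `harmonized_set`.
#' @return Named integer vector of harmonization bookkeeping counts.
#' @export
harmonize_report <- function(hs) attr(hs, "report")

# internal: build a harmonized_set directly from aligned vectors (used by
# estimators operating on subsets, and by the simulator's truth bypass)
.harmonized <- function(snp, beta_exp, se_exp, beta_out, se_out,
                        eaf_exp = NA_real_) {
  stopifnot(all(se_exp > 0), all(se_out > 0), all(beta_exp != 0))
  structure(data.frame(snp = snp, beta_exp = beta_exp, se_exp = se_exp,
                       beta_out = beta_out, se_out = se_out,
                       eaf_exp = eaf_exp,
                       wald_ratio = beta_out / beta_exp,
                       wald_se = se_out / abs(beta_exp),
                       weight = beta_exp^2 / se_out^2,
                       flipped = FALSE, stringsAsFactors = FALSE),
            class = c("harmonized_set", "data.frame"))
}
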