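#' Construct a GWAS summary-statistics set
#'
#' A `sumstat_set` is a data frame of per-SNP association records for one
#' trait, one row per SNP, with columns `snp`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. Binary-trait betas are
#' on the log-odds scale; quantitative traits are in trait units.
#'
#' Rows violating hard invariants (non-ACGT or identical alleles,
#' non-positive `se`, `eaf` outside \[0,1\], `pval` outside (0,1\]) are
#' dropped with a count recorded in the `drop_report` attribute. A p-value
#' inconsistent with the two-sided normal p of `beta/se` by more than a
#' factor of 10 triggers a warning only, since published statistics are
#' routinely rounded.
#'
#' @param df data frame with at least `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`; `eaf`, `pval`, `n` optional (filled with
#'   `NA` / recomputed p when absent).
#' @param trait_label character scalar naming the trait.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param check_pval logical; warn on p-value / z-score inconsistency.
#' @return A `sumstat_set`: the validated data frame with attributes
#'   `trait_label`, `trait_type` and `drop_report` (named integer vector).
#' @export
#' @examples
#' df <- data.frame(snp = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'                  other_allele = c("G", "T"), eaf = c(0.3, 0.5),
#'                  beta = c(0.08, -0.05), se = c(0.01, 0.012),
#'                  pval = c(1e-15, 3e-5), n = 50000)
#' s <- sumstat_set(df, "exposure")
#' nrow(s)
sumstat_set <- function(df, trait_label = "trait",
                        trait_type = c("binary", "quantitative"),
                        check_pval = TRUE) {
  trait_type <- match.arg(trait_type)
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (!nrow(df)) stop("empty summary-statistics table for trait '",
                      trait_label, "'")

  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  df$snp <- as.character(df$snp)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "n")) df[[col]] <- as.numeric(df[[col]])
  if (!"pval" %in% names(df)) {
    df$pval <- 2 * stats::pnorm(-abs(df$beta / df$se))
  } else {
    df$pval <- as.numeric(df$pval)
  }

  bases <- c("A", "C", "G", "T")
  bad_allele <- !(df$effect_allele %in% bases) |
    !(df$other_allele %in% bases) |
    df$effect_allele == df$other_allele
  bad_se <- !is.finite(df$se) | df$se <= 0
  bad_beta <- !is.finite(df$beta)
  bad_eaf <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  bad_p <- !is.finite(df$pval) | df$pval <= 0 | df$pval > 1

  drop_report <- c(allele = sum(bad_allele), se = sum(bad_se & !bad_allele),
                   beta = sum(bad_beta & !bad_allele & !bad_se),
                   eaf = sum(bad_eaf & !bad_allele & !bad_se & !bad_beta),
                   pval = sum(bad_p & !bad_allele & !bad_se & !bad_beta & !bad_eaf))
  keep <- !(bad_allele | bad_se | bad_beta | bad_eaf | bad_p)
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(trait_label, ": dropped ", n_dropped,
            " record(s) failing validation (",
            paste(names(drop_report)[drop_report > 0], collapse = ", "), ")")
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("no valid records remain for trait '", trait_label, "'")
  if (anyDuplicated(df$snp))
    stop("duplicate snp ids: ",
         paste(unique(df$snp[duplicated(df$snp)]), collapse = ", "))

  if (check_pval) {
    p_z <- 2 * stats::pnorm(-abs(df$beta / df$se))
    ratio <- ifelse(p_z > 0, df$pval / p_z, 1)
    off <- is.finite(ratio) & (ratio > 10 | ratio < 0.1) & p_z > 1e-300
    if (any(off))
      warning(sum(off), " record(s) have p-values inconsistent with beta/se ",
              "beyond a factor of 10 (kept; likely rounding)")
  }

  df <- df[, c("snp", "effect_allele", "other_allele", "eaf", "beta",
               "se", "pval", "n")]
  rownames(df) <- NULL
  structure(df, trait_label = trait_label, trait_type = trait_type,
            drop_report = drop_report, class = c("sumstat_set", "data.frame"))
}

#' @export
print.sumstat_set <- function(x, ...) {
  cat("GWAS summary statistics: ", attr(x, "trait_label"),
      " (", attr(x, "trait_type"), "), ", nrow(x), " SNPs\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

# canonical column order for on-disk files
.canonical_cols <- c("snp", "effect_allele", "other_allele", "eaf", "beta",
                     "se", "pval", "n")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- (or otherwise) delimited file with a header row into a
#' validated [sumstat_set]. Column names different from the canonical ones
#' are absorbed by the `dialect` mapping, e.g. GWAS exports using
#' `A1/A2/b/se/p`. Gzipped files are read transparently.
#'
#' @param path file path (plain or `.gz`).
#' @param dialect named character vector mapping canonical names
#'   (`snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`) to the file's column names. Only mappings that differ from the
#'   canonical names need be given.
#' @param trait_label,trait_type passed to [sumstat_set()].
#' @param sep field separator (default tab).
#' @return A [sumstat_set].
#' @export
read_sumstats <- function(path, dialect = NULL, trait_label = basename(path),
                          trait_type = c("binary", "quantitative"),
                          sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE)
  if (!nrow(df)) stop("empty file: ", path)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(df))
        stop("dialect maps '", canon, "' to missing column '", src, "'")
      names(df)[names(df) == src] <- canon
    }
  }
  sumstat_set(df, trait_label = trait_label, trait_type = trait_type)
}

#' Write a summary-statistics set as canonical TSV
#'
#' Fixed column order `snp, effect_allele, other_allele, eaf, beta, se,
#' pval, n`, tab-separated, header row, `NA` token for missing values.
#' Numeric fields are written to 10 significant digits so that
#' `read_sumstats(write_sumstats(s))` reproduces `s`.
#'
#' @param set a [sumstat_set].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(set, path) {
  stopifnot(inherits(set, "sumstat_set"))
  out <- as.data.frame(set)[, .canonical_cols]
  for (col in c("eaf", "beta", "se", "pval", "n"))
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         formatC(out[[col]], digits = 10, format = "g"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a harmonized-instrument table as TSV
#'
#' @param hs a `harmonized_set` from [harmonize_sets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(hs, path) {
  cols <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out",
            "wald_ratio", "wald_se")
  utils::write.table(as.data.frame(hs)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
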