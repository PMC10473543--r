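#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Defines a three-trait causal system (exposure -> mediator -> binary
#' outcome, plus a direct exposure -> outcome path) from which paired
#' summary statistics are generated. Defaults emulate a
#' psychiatric-exposure / behavioural-mediator / breast-cancer-scale
#' setting: 150 exposure instruments explaining about 21% of exposure
#' variance, an outcome GWAS of 228,951 with 54% cases, total exposure
#' effect log(1.06) decomposed into a direct path and an indirect path
#' b1 * b2 with b1 = 0.0438 and b2 = 0.1467.
#'
#' @param n_snps exposure-instrument count (default 150).
#' @param n_snps_med mediator-specific instrument count (default 50);
#'   these SNPs have zero exposure effect and identify the mediator column
#'   in multivariable fits.
#' @param n_exp,n_med,n_out GWAS sample sizes (defaults 1e5, 1e5, 228951).
#' @param k_cases outcome case fraction (default 0.54); the outcome's
#'   effective sample size is `n_out * k_cases * (1 - k_cases)`.
#' @param gamma_sd SD of true SNP-exposure effects (default 0.0596, which
#'   yields instrument variance explained near 0.21 for 150 SNPs at the
#'   default MAF range).
#' @param delta_sd SD of mediator-specific SNP effects (default 0.0596).
#' @param direct_effect exposure -> outcome effect not through the
#'   mediator (log-odds; default `log(1.06) - b1 * b2`).
#' @param b1 exposure -> mediator effect (default 0.0438).
#' @param b2 mediator -> outcome effect (log-odds; default 0.1467).
#' @param pleiotropy_frac fraction of exposure instruments with direct
#'   outcome effects (default 0).
#' @param pleiotropy_mean,pleiotropy_sd distribution of those effects;
#'   mean 0 is balanced, nonzero is directional.
#' @param frac_palindromic fraction of SNPs assigned A/T or C/G allele
#'   pairs (default 0.06, about nine per 150 instruments).
#' @param frac_allele_swapped fraction of SNPs whose mediator/outcome
#'   records are emitted with swapped allele coding (beta negated, EAF
#'   complemented; default 0.1).
#' @param maf_range uniform range for minor-allele frequencies
#'   (default c(0.1, 0.5)).
#' @param ld_blocks,ld_r2 optional block LD: number of equal blocks and
#'   within-block r2 (defaults 0 and 0: identity LD, quasi-independent
#'   instruments).
#' @param seed integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 150, n_snps_med = 50,
                       n_exp = 1e5, n_med = 1e5, n_out = 228951,
                       k_cases = 0.54,
                       gamma_sd = 0.0596, delta_sd = 0.0596,
                       b1 = 0.0438, b2 = 0.1467,
                       direct_effect = log(1.06) - b1 * b2,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       frac_palindromic = 0.06,
                       frac_allele_swapped = 0.1,
                       maf_range = c(0.1, 0.5),
                       ld_blocks = 0, ld_r2 = 0,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_snps >= 1, n_snps_med >= 0,
            k_cases > 0, k_cases < 1,
            gamma_sd >= 0, delta_sd >= 0, pleiotropy_sd >= 0,
            pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            frac_palindromic >= 0, frac_palindromic <= 1,
            frac_allele_swapped >= 0, frac_allele_swapped <= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5)
  if (gamma_sd == 0 && (direct_effect != 0 || b1 != 0))
    stop("gamma_sd = 0 with nonzero exposure effects: no signal can flow")
  structure(list(n_snps = n_snps, n_snps_med = n_snps_med, n_exp = n_exp,
                 n_med = n_med, n_out = n_out, k_cases = k_cases,
                 gamma_sd = gamma_sd, delta_sd = delta_sd,
                 direct_effect = direct_effect, b1 = b1, b2 = b2,
                 pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 frac_palindromic = frac_palindromic,
                 frac_allele_swapped = frac_allele_swapped,
                 maf_range = maf_range, ld_blocks = ld_blocks,
                 ld_r2 = ld_r2, seed = as.integer(seed)),
            class = "sim_config")
}

# non-palindromic allele pairs (effect, other)
.nonpal_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                       c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate paired exposure / mediator / outcome summary statistics
#'
#' Draws per-SNP true effects according to the mediation diagram in
#' [sim_config()]: exposure effects gamma_j ~ N(0, gamma_sd^2); mediator
#' effects delta_j = b1 * gamma_j plus mediator-specific instruments;
#' outcome effects direct_effect * gamma_j + b2 * delta_j + alpha_j, with
#' alpha_j nonzero for the configured pleiotropic subset. Observed betas
#' are the true effects plus normal noise with
#' se = 1 / sqrt(2 * maf * (1 - maf) * n_eff), where n_eff is the GWAS
#' sample size (times k(1-k) for the binary outcome); p-values are the
#' exact two-sided normal p of beta/se. Palindromic allele pairs and
#' swapped allele codings are injected at the configured fractions, with
#' full bookkeeping in the returned truth.
#'
#' @param cfg a [sim_config()].
#' @return List: `exposure`, `mediator`, `outcome` ([sumstat_set]s), `ld`
#'   ([ld_matrix()]), `truth` (list: per-SNP `gamma`, `delta`,
#'   `alpha_pleio`, the path coefficients, `total_effect`,
#'   `proportion_mediated_true`, and bookkeeping vectors
#'   `palindromic_snps`, `swapped_med`, `swapped_out`,
#'   `pleiotropic_snps`, `mediator_specific_snps`).
#' @export
simulate_sumstats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  J <- cfg$n_snps + cfg$n_snps_med
  snp <- sprintf("rs%05d", seq_len(J))
  is_med_snp <- c(rep(FALSE, cfg$n_snps), rep(TRUE, cfg$n_snps_med))
  maf <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])

  gamma <- ifelse(is_med_snp, 0, stats::rnorm(J, 0, cfg$gamma_sd))
  delta <- cfg$b1 * gamma +
    ifelse(is_med_snp, stats::rnorm(J, 0, cfg$delta_sd), 0)
  alpha <- numeric(J)
  n_pleio <- round(cfg$pleiotropy_frac * cfg$n_snps)
  pleio_idx <- if (n_pleio) sample(which(!is_med_snp), n_pleio) else integer(0)
  if (n_pleio)
    alpha[pleio_idx] <- stats::rnorm(n_pleio, cfg$pleiotropy_mean,
                                     cfg$pleiotropy_sd)
  Gamma <- cfg$direct_effect * gamma + cfg$b2 * delta + alpha

  het <- 2 * maf * (1 - maf)
  se_exp <- 1 / sqrt(het * cfg$n_exp)
  se_med <- 1 / sqrt(het * cfg$n_med)
  se_out <- 1 / sqrt(het * cfg$n_out * cfg$k_cases * (1 - cfg$k_cases))

  beta_exp <- stats::rnorm(J, gamma, se_exp)
  beta_med <- stats::rnorm(J, delta, se_med)
  beta_out <- stats::rnorm(J, Gamma, se_out)

  n_pal <- round(cfg$frac_palindromic * J)
  pal_idx <- if (n_pal) sample(J, n_pal) else integer(0)
  alleles <- .nonpal_pairs[sample(nrow(.nonpal_pairs), J, replace = TRUE), ,
                           drop = FALSE]
  if (n_pal)
    alleles[pal_idx, ] <- .pal_pairs[sample(nrow(.pal_pairs), n_pal,
                                            replace = TRUE), , drop = FALSE]

  swap_med <- stats::runif(J) < cfg$frac_allele_swapped
  swap_out <- stats::runif(J) < cfg$frac_allele_swapped

  mk <- function(beta, se, n, swap, label, type) {
    ea <- alleles[, 1]; oa <- alleles[, 2]
    eaf <- maf
    b <- beta
    ea[swap] <- alleles[swap, 2]; oa[swap] <- alleles[swap, 1]
    eaf[swap] <- 1 - maf[swap]
    b[swap] <- -beta[swap]
    sumstat_set(data.frame(snp = snp, effect_allele = ea, other_allele = oa,
                           eaf = eaf, beta = b, se = se,
                           pval = pmax(2 * stats::pnorm(-abs(b / se)),
                                       .Machine$double.xmin), n = n,
                           stringsAsFactors = FALSE),
                trait_label = label, trait_type = type, check_pval = FALSE)
  }
  exposure <- mk(beta_exp, se_exp, cfg$n_exp, rep(FALSE, J), "exposure",
                 "binary")
  mediator <- mk(beta_med, se_med, cfg$n_med, swap_med, "mediator",
                 "quantitative")
  outcome <- mk(beta_out, se_out, cfg$n_out, swap_out, "outcome", "binary")

  if (cfg$ld_blocks > 0 && cfg$ld_r2 > 0) {
    block <- sort(rep_len(seq_len(cfg$ld_blocks), J))
    r2 <- outer(block, block, function(a, b)
      ifelse(a == b, cfg$ld_r2, 0))
    diag(r2) <- 1
    dimnames(r2) <- list(snp, snp)
    ld <- ld_matrix(r2)
  } else {
    ld <- ld_matrix(snp_ids = snp)
  }

  total_effect <- cfg$direct_effect + cfg$b1 * cfg$b2
  truth <- list(gamma = stats::setNames(gamma, snp),
                delta = stats::setNames(delta, snp),
                alpha_pleio = stats::setNames(alpha, snp),
                direct_effect = cfg$direct_effect, b1 = cfg$b1, b2 = cfg$b2,
                total_effect = total_effect,
                proportion_mediated_true =
                  if (total_effect != 0) cfg$b1 * cfg$b2 / total_effect
                  else NA_real_,
                palindromic_snps = snp[pal_idx],
                swapped_med = snp[swap_med], swapped_out = snp[swap_out],
                pleiotropic_snps = snp[pleio_idx],
                mediator_specific_snps = snp[is_med_snp])
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       ld = ld, truth = truth)
}

#' Named fixture scenarios for regression tests
#'
#' Deterministic small datasets (30 exposure instruments or fewer) with
#' known structure:
#' \describe{
#'   \item{clean}{no pleiotropy, no palindromes, no swaps; total effect
#'     log(1.06).}
#'   \item{directional_pleiotropy}{30% of instruments carry positive-mean
#'     direct outcome effects.}
#'   \item{one_outlier}{clean, then the first instrument's outcome beta is
#'     displaced by 10 outcome SEs.}
#'   \item{full_mediation}{direct effect zero; the whole exposure effect
#'     flows through the mediator.}
#'   \item{null}{all causal paths zero.}
#' }
#'
#' @param name scenario label.
#' @param seed integer seed (default 20230901).
#' @return As [simulate_sumstats()], plus `name`.
#' @export
make_fixture <- function(name = c("clean", "directional_pleiotropy",
                                  "one_outlier", "full_mediation", "null"),
                         seed = 20230901) {
  if (!is.character(name) || !name[1] %in%
      c("clean", "directional_pleiotropy", "one_outlier", "full_mediation",
        "null"))
    stop("unknown fixture '", name[1], "'; registry: clean, ",
         "directional_pleiotropy, one_outlier, full_mediation, null")
  name <- name[1]
  base <- function(...) sim_config(n_snps = 30, n_snps_med = 12,
                                   frac_palindromic = 0,
                                   frac_allele_swapped = 0, seed = seed, ...)
  cfg <- switch(name,
    clean = base(),
    directional_pleiotropy = base(pleiotropy_frac = 0.3,
                                  pleiotropy_mean = 0.02,
                                  pleiotropy_sd = 0.005),
    one_outlier = base(),
    full_mediation = base(direct_effect = 0, b1 = 0.1, b2 = 0.3),
    null = base(direct_effect = 0, b1 = 0, b2 = 0))
  out <- simulate_sumstats(cfg)
  if (name == "one_outlier") {
    shift <- 10 * out$outcome$se[1]
    out$outcome$beta[1] <- out$outcome$beta[1] + shift
    out$outcome$pval[1] <- 2 * stats::pnorm(-abs(out$outcome$beta[1] /
                                                   out$outcome$se[1]))
    out$truth$alpha_pleio[1] <- out$truth$alpha_pleio[1] + shift
    out$truth$pleiotropic_snps <- union(out$truth$pleiotropic_snps,
                                        out$outcome$snp[1])
  }
  out$name <- name
  out
}

#' Write a simulated dataset to disk
#'
#' Emits the three summary-statistics TSVs plus the generating truth as
#' JSON, so a dataset can be re-analysed from files alone.
#'
#' @param sim result of [simulate_sumstats()] or [make_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  truth <- sim$truth
  truth$gamma <- as.list(truth$gamma)
  truth$delta <- as.list(truth$delta)
  truth$alpha_pleio <- as.list(truth$alpha_pleio)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
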