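#' Pipeline configuration
#'
#' Collects every threshold the analysis workflow uses, with defaults set
#' to the usual two-sample MR conventions: genome-wide significance
#' p < 5e-8, clumping at r2 < 0.001 over 10,000 kb, instrument strength
#' F > 10, significance level 0.05, Egger intercept bound 0.1.
#'
#' @param p_instrument instrument p-value threshold.
#' @param clump_r2,clump_kb LD-clumping parameters.
#' @param f_min F-statistic floor.
#' @param alpha significance level used throughout.
#' @param egger_intercept_bound magnitude bound for the pleiotropy check.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed integer seed (mandatory: drives the bootstrap and
#'   MR-PRESSO).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(p_instrument = 5e-8, clump_r2 = 0.001,
                            clump_kb = 10000, f_min = 10, alpha = 0.05,
                            egger_intercept_bound = 0.1,
                            presso_n_sim = 1000, n_boot = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(p_instrument = p_instrument, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min, alpha = alpha,
                 egger_intercept_bound = egger_intercept_bound,
                 presso_n_sim = presso_n_sim, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Two-sample MR analysis for one exposure-outcome pair
#'
#' Full workflow: instrument selection (p-value filter, optional LD clump,
#' F filter), harmonization, IVW with the heterogeneity-driven
#' fixed/random choice, MR-Egger with intercept test, weighted median,
#' Cochran's Q for IVW and Egger, leave-one-out, and MR-PRESSO.
#'
#' @param exposure,outcome [sumstat_set] objects.
#' @param config a [pipeline_config()].
#' @param ld optional [ld_matrix()] for clumping.
#' @param instruments_preselected logical: when `TRUE`, `exposure` is
#'   taken as the instrument list as-is (no p/F filtering), e.g. when
#'   instruments were published as a curated table.
#' @return A `two_sample_result`: list with `estimates` (data frame:
#'   method, nsnp, beta, se, OR, CI, p, effects model), `heterogeneity`,
#'   `pleiotropy`, `pleiotropy_check`, `leave_one_out`, `presso`,
#'   `harmonize_report`, `instruments` (SNP ids), `harmonized`.
#' @export
run_two_sample <- function(exposure, outcome, config, ld = NULL,
                           instruments_preselected = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  inst <- if (instruments_preselected) exposure
          else select_instruments(exposure, ld,
                                  p_threshold = config$p_instrument,
                                  r2_max = config$clump_r2,
                                  window_kb = config$clump_kb,
                                  f_min = config$f_min)
  if (!nrow(inst)) stop("no instruments selected for '",
                        attr(exposure, "trait_label"), "'")
  hs <- harmonize_sets(inst, outcome)
  binary <- identical(attr(outcome, "trait_type"), "binary")

  het_ivw <- cochran_q(hs, "ivw")
  est_ivw <- ivw(hs, "auto", alpha = config$alpha)
  eg <- mr_egger(hs)
  het_egger <- cochran_q(hs, "egger")
  wm <- weighted_median(hs, n_boot = config$n_boot, seed = config$seed)
  if (binary) {
    est_ivw <- to_odds_ratio(est_ivw)
    eg$estimate <- to_odds_ratio(eg$estimate)
    wm <- to_odds_ratio(wm)
  }
  loo <- leave_one_out(hs, "auto", config$alpha)
  presso <- if (nrow(hs) >= 4)
    mr_presso(hs, n_sim = config$presso_n_sim, seed = config$seed,
              outlier_alpha = config$alpha) else NULL

  row <- function(e, het_p = NA_real_, pleio_p = NA_real_) {
    data.frame(method = e$method, nsnp = e$nsnp, beta = e$beta, se = e$se,
               or = if (binary) e$or else NA_real_,
               or_ci_low = if (binary) e$or_ci_low else NA_real_,
               or_ci_high = if (binary) e$or_ci_high else NA_real_,
               pval = e$pval, effects_model = e$effects_model,
               het_pval = het_p, pleiotropy_pval = pleio_p,
               stringsAsFactors = FALSE)
  }
  estimates <- rbind(row(est_ivw, het_p = het_ivw$pval),
                     row(eg$estimate, het_p = het_egger$pval,
                         pleio_p = eg$pleiotropy$pval),
                     row(wm))
  structure(list(exposure = attr(exposure, "trait_label"),
                 outcome = attr(outcome, "trait_label"),
                 estimates = estimates,
                 heterogeneity = list(ivw = het_ivw, egger = het_egger),
                 pleiotropy = eg$pleiotropy,
                 pleiotropy_check = egger_pleiotropy_check(
                   eg$pleiotropy, config$egger_intercept_bound,
                   config$alpha),
                 leave_one_out = loo, presso = presso,
                 harmonize_report = harmonize_report(hs),
                 instruments = hs$snp, harmonized = hs),
            class = "two_sample_result")
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat("Two-sample MR: ", x$exposure, " -> ", x$outcome, " (",
      length(x$instruments), " instruments)\n", sep = "")
  print.data.frame(x$estimates, digits = 4)
  cat("Egger intercept check:", x$pleiotropy_check,
      "| leave-one-out robust:", x$leave_one_out$robust, "\n")
  invisible(x)
}

#' Two-step MR mediation analysis
#'
#' Step 0: total effect beta0 of the exposure on the outcome
#' ([run_two_sample()], IVW row). Step 1: beta1 per mediator by
#' two-sample MR of the exposure on the mediator. Step 2: beta2 per
#' mediator from a multivariable MR of the outcome on mediator plus
#' exposure (the mediator's coefficient, conditional on the exposure).
#' Each mediator is then classified with [classify_mediation()] and, for
#' partial/full mediation, the proportion mediated beta1 * beta2 / beta0
#' is reported.
#'
#' @param exposure [sumstat_set] for the exposure.
#' @param mediators named list of [sumstat_set] objects.
#' @param outcome [sumstat_set] for the outcome.
#' @param config a [pipeline_config()].
#' @param ld optional [ld_matrix()].
#' @param instruments_preselected as in [run_two_sample()].
#' @return A `two_step_result`: list with `total` (the beta0
#'   `two_sample_result`), `mediators` (per-mediator list: `beta1` result,
#'   `beta2` MVMR row, `mediation` classification), and `summary` data
#'   frame (mediator, beta0/1/2, p-values, classification,
#'   proportion_mediated_pct).
#' @export
run_two_step <- function(exposure, mediators, outcome, config, ld = NULL,
                         instruments_preselected = FALSE) {
  stopifnot(is.list(mediators), length(mediators) >= 1)
  if (is.null(names(mediators)))
    names(mediators) <- vapply(mediators, function(s)
      attr(s, "trait_label"), character(1))
  total <- run_two_sample(exposure, outcome, config, ld,
                          instruments_preselected)
  b0_row <- total$estimates[total$estimates$method == "ivw", ]
  beta0 <- list(beta = b0_row$beta, se = b0_row$se, pval = b0_row$pval)

  per_med <- lapply(names(mediators), function(nm) {
    med <- mediators[[nm]]
    step1 <- run_two_sample(exposure, med, config, ld,
                            instruments_preselected)
    b1_row <- step1$estimates[step1$estimates$method == "ivw", ]
    beta1 <- list(beta = b1_row$beta, se = b1_row$se, pval = b1_row$pval)

    mv_in <- build_mvmr_input(list(exposure, med), outcome, ld,
                              p_threshold = if (instruments_preselected) 1
                                            else config$p_instrument,
                              r2_max = config$clump_r2,
                              window_kb = config$clump_kb)
    mv <- mvmr_fit(mv_in)
    b2_row <- mv[mv$exposure == attr(med, "trait_label"), ]
    beta2 <- list(beta = b2_row$beta, se = b2_row$se, pval = b2_row$pval)

    med_res <- classify_mediation(beta0, beta1, beta2, config$alpha)
    list(name = nm, beta1_result = step1, mvmr = mv, beta1 = beta1,
         beta2 = beta2, mediation = med_res)
  })
  names(per_med) <- names(mediators)

  summary <- do.call(rbind, lapply(per_med, function(m) {
    data.frame(mediator = m$name,
               beta0 = beta0$beta, p0 = beta0$pval,
               beta1 = m$beta1$beta, p1 = m$beta1$pval,
               beta2 = m$beta2$beta, p2 = m$beta2$pval,
               classification = m$mediation$classification,
               proportion_mediated_pct =
                 round(100 * m$mediation$proportion_mediated, 2),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(total = total, mediators = per_med, summary = summary,
                 config = config),
            class = "two_step_result")
}

#' @export
print.two_step_result <- function(x, ...) {
  cat("Two-step MR mediation analysis\n")
  cat(sprintf("Total effect (IVW): beta0 = %.4f, p = %.4g\n",
              x$summary$beta0[1], x$summary$p0[1]))
  print.data.frame(x$summary, digits = 4)
  invisible(x)
}
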