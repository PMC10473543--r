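# Shared fixtures and independent oracles for the test suite.

# build a harmonized_set directly from vectors (bypasses file I/O)
h_set <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01,
                  snp = sprintf("rs%03d", seq_along(beta_exp))) {
  se_exp <- rep_len(se_exp, length(beta_exp))
  se_out <- rep_len(se_out, length(beta_exp))
  mrmediate:::.harmonized(snp, beta_exp, se_exp, beta_out, se_out)
}

# random harmonized set for property tests
random_h_set <- function(J, seed) {
  set.seed(seed)
  h_set(beta_exp = rnorm(J, 0.1, 0.03) + 0.02,
        beta_out = rnorm(J, 0.01, 0.005),
        se_exp = runif(J, 0.005, 0.02),
        se_out = runif(J, 0.005, 0.02))
}

# generic WLS oracle: coefficients and model-based SEs with multiplicative
# overdispersion clipped at 1, for design matrix X, response y, weights w
wls_oracle <- function(X, y, w, clip = TRUE) {
  X <- as.matrix(X)
  XtWX <- crossprod(X, w * X)
  coefs <- drop(solve(XtWX, crossprod(X, w * y)))
  resid <- y - drop(X %*% coefs)
  rss_w <- sum(w * resid^2)
  df <- nrow(X) - ncol(X)
  phi <- if (clip) max(1, rss_w / df) else rss_w / df
  list(coefs = coefs, ses = sqrt(diag(solve(XtWX)) * phi), rss_w = rss_w)
}

# grid-search oracle for the weighted median: scan candidate values and
# return the first one where the piecewise-linear weighted CDF (midpoint
# convention at the observed ratios) reaches one half
grid_median_oracle <- function(ratios, weights, n_grid = 2e5) {
  o <- order(ratios)
  r <- ratios[o]; w <- weights[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  grid <- seq(min(r), max(r), length.out = n_grid)
  cdf_vals <- approx(r, s, xout = grid, rule = 2)$y
  grid[which(cdf_vals >= 0.5)[1]]
}

# small well-formed sumstat data frame
toy_sumstats_df <- function() {
  data.frame(snp = c("rs1", "rs2", "rs3"),
             effect_allele = c("A", "C", "G"),
             other_allele = c("G", "T", "A"),
             eaf = c(0.3, 0.45, 0.2),
             beta = c(0.08, -0.06, 0.05),
             se = c(0.010, 0.012, 0.009),
             pval = c(1.3e-15, 5.7e-7, 2.8e-8),
             n = c(50000, 50000, 50000),
             stringsAsFactors = FALSE)
}
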