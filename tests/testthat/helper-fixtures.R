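# Shared fixture builders. Everything is generated in code; no stored data.

# A small harmonized pair with independent SNPs and clean alleles.
make_pair <- function(p = 5, seed = 1, freq = NULL) {
  set.seed(seed)
  snp <- paste0("rs", seq_len(p))
  if (is.null(freq)) freq <- runif(p, 0.2, 0.45)
  exposure <- marginal_summary(snp, rep("A", p), rep("G", p),
                               beta = rnorm(p, 0.2, 0.05),
                               se = runif(p, 0.01, 0.03),
                               n = 5000, freq = freq)
  outcome <- marginal_summary(snp, rep("A", p), rep("G", p),
                              beta = rnorm(p, 0, 0.02),
                              se = runif(p, 0.01, 0.03),
                              n = 8000, freq = freq)
  harmonize(exposure, outcome, ld_diag_from_freq(freq, snp))
}

# Individual-level two-sample dataset with known genotypes, returning both
# the raw data and the exact summary statistics, for oracle comparisons.
make_individual <- function(n = 1500, p = 6, maf = 0.3, rho = 0,
                            beta = 0, seed = 2) {
  set.seed(seed)
  G <- gen_genotypes(n, p, maf, rho)
  omega <- runif(p, 0.1, 0.3)
  X <- drop(G %*% omega) + rnorm(n)
  Y <- beta * X + rnorm(n)
  list(G = G, X = X, Y = Y, omega = omega)
}

# Marginal (with-intercept) per-SNP regression done the slow, obvious way.
slow_marginal <- function(G, y) {
  p <- ncol(G)
  beta <- se <- numeric(p)
  for (j in seq_len(p)) {
    fit <- summary(lm(y ~ G[, j]))
    beta[j] <- fit$coefficients[2, 1]
    se[j] <- fit$coefficients[2, 2]
  }
  list(beta = beta, se = se)
}
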