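# Two-sample generative models and the rejection-rate experiment harness.
# Genotypes, a hidden confounder, exposure and outcome are simulated under
# configurable pleiotropy scenarios; marginal summary statistics are emitted
# per sample and fed back through the summary-statistic testing pipeline.

#' Configuration of one simulation scenario
#'
#' The generative model, on independent samples of sizes `n1` (exposure) and
#' `n2` (outcome), is
#' \deqn{U = G delta + eps_U, \quad X = G omega + U + e, \quad
#'       Y = beta X + G upsilon + U + eps}
#' with all noise terms i.i.d. standard normal. SNP-to-exposure effects are
#' drawn from `N(0, omega_sd^2)` truncated to `(omega_min, Inf)` (all
#' positive, guaranteeing instrument strength) and rescaled so the SNPs
#' explain a fraction `h2_gx` of `Var(X)`. A random fraction `prop_invalid`
#' of SNPs is invalid, with direct effects on Y per scenario:
#' * `"S1"` balanced pleiotropy: `upsilon ~ N(0, 0.075)`, `delta = 0`;
#' * `"S2"` directional pleiotropy: `upsilon ~ N(0.1 sign(omega), 0.025)`,
#'   `delta = 0`;
#' * `"S3"` directional pleiotropy with the InSIDE assumption violated:
#'   `upsilon` as in S2 and `delta ~ Unif(0, delta_max)` on invalid SNPs
#'   (`delta` is not rescaled, so the confounder channel grows with the
#'   number of invalid instruments).
#'
#' `upsilon` is rescaled so its genetic channel explains `h2_direct` of the
#' non-causal outcome variance (the variance of Y with `beta = 0`, so the
#' direct-effect signal does not grow with the causal effect); `beta` is
#' then solved so X explains `h2_xy` of the full `Var(Y)` (zero when
#' `h2_xy = 0`). The second parameter of the scenario normals is read as a
#' variance by default (`dispersion = "variance"`); set `"sd"` for the
#' standard-deviation reading. The rescaling makes the choice nearly
#' immaterial.
#'
#' @param p number of SNPs.
#' @param n1,n2 exposure / outcome GWAS sample sizes.
#' @param maf minor allele frequency of every SNP.
#' @param rho AR(1) LD parameter: `Cor(G_j, G_k) = rho^|j-k|`; `0` gives
#'   independent SNPs.
#' @param scenario `"S1"`, `"S2"` or `"S3"` (identical when
#'   `prop_invalid = 0`).
#' @param prop_invalid fraction of invalid instruments.
#' @param h2_xy fraction of `Var(Y)` explained by X (0 means no causal
#'   effect).
#' @param h2_gx fraction of `Var(X)` explained by the SNPs.
#' @param h2_direct fraction of `Var(Y)` explained by the direct genetic
#'   channel `G upsilon`.
#' @param omega_sd,omega_min truncated-normal parameters of the raw
#'   SNP-to-exposure effects.
#' @param s1_var,s2_var dispersion parameters of the scenario draws.
#' @param delta_max upper bound of the uniform SNP-to-confounder effects of
#'   invalid instruments in S3.
#' @param dispersion `"variance"` or `"sd"`: reading of `s1_var`/`s2_var`.
#' @param n_ref reference-panel size for LD estimation (a third independent
#'   genotype sample); used when `rho > 0` and `ld_source = "panel"`.
#' @param ld_source LD supplied to the tests when `rho > 0`: `"analytic"`
#'   (default) uses the model-implied AR correlation, `"panel"` estimates it
#'   from a finite reference panel of `n_ref` samples (which adds
#'   reconstruction noise and visibly inflates the score test's size at
#'   small panel sizes).
#' @param n_reps number of simulation replicates.
#' @param alpha_level nominal test level.
#' @param B Monte-Carlo sample count for the aSPU tests.
#' @param seed RNG seed for the whole experiment.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(p = 30, n1 = 10000, n2 = 10000, maf = 0.3,
                            rho = 0, scenario = c("S1", "S2", "S3"),
                            prop_invalid = 0, h2_xy = 0, h2_gx = 0.2,
                            h2_direct = 0.003, omega_sd = 0.15,
                            omega_min = 0.08, s1_var = 0.075, s2_var = 0.025,
                            delta_max = 0.1,
                            dispersion = c("variance", "sd"),
                            n_ref = 503, ld_source = c("analytic", "panel"),
                            n_reps = 1000, alpha_level = 0.05,
                            B = 1000, seed = 1) {
  scenario <- match.arg(scenario)
  dispersion <- match.arg(dispersion)
  ld_source <- match.arg(ld_source)
  stopifnot(p >= 2, n1 >= 100, n2 >= 100, maf > 0, maf <= 0.5,
            rho >= 0, rho < 1, prop_invalid >= 0, prop_invalid < 1,
            h2_xy >= 0, h2_xy < 1, h2_gx > 0, h2_gx < 1,
            h2_direct >= 0, h2_direct < 1)
  if (h2_xy + h2_direct >= 1)
    stop("infeasible variance budget: h2_xy + h2_direct must be < 1")
  structure(as.list(environment()), class = "scenario_config")
}

# ---- correlated genotypes via a Gaussian copula ----------------------------

# P(Z1 <= t, Z2 <= t) for standard bivariate normal with correlation r.
.binorm_cdf_tt <- function(t, r) {
  if (r >= 1) return(stats::pnorm(t))
  if (r == 0) return(stats::pnorm(t)^2)
  stats::integrate(function(z)
    stats::dnorm(z) * stats::pnorm((t - r * z) / sqrt(1 - r^2)),
    -Inf, t, rel.tol = 1e-10)$value
}

# Latent haplotype correlation giving allele-count correlation `target`
# at frequency f: solves (Phi2(t,t;r) - f^2) / (f(1-f)) = target.
.calibrate_latent <- function(target, f, tol = 1e-9) {
  if (target < 1e-10) return(0)
  t <- stats::qnorm(f)
  g <- function(r) (.binorm_cdf_tt(t, r) - f^2) / (f * (1 - f)) - target
  stats::uniroot(g, c(0, 1 - 1e-9), tol = tol)$root
}

# Square root (upper-triangular or eigen) of the latent correlation matrix
# for an AR(rho) allele-count target; each distinct lag is calibrated so the
# count correlation matches rho^lag exactly.
.copula_root <- function(p, maf, rho) {
  lag_r <- vapply(seq_len(p - 1L),
                  function(d) .calibrate_latent(rho^d, maf), numeric(1))
  R <- diag(p)
  for (d in seq_len(p - 1L)) {
    idx <- seq_len(p - d)
    R[cbind(idx, idx + d)] <- lag_r[d]
    R[cbind(idx + d, idx)] <- lag_r[d]
  }
  tryCatch(chol(R), error = function(e) {
    ed <- eigen(R, symmetric = TRUE)
    t(ed$vectors %*% (t(ed$vectors) * sqrt(pmax(ed$values, 0))))
  })
}

#' Simulate genotypes with AR(rho) linkage disequilibrium
#'
#' Each entry is an allele count in `{0, 1, 2}` with marginal distribution
#' `Binomial(2, maf)`. For `rho > 0`, two independent latent Gaussian
#' haplotype vectors are thresholded at the `maf` quantile and summed; the
#' latent correlations are calibrated (per lag, by root-finding on the
#' bivariate normal orthant probability) so the allele-count correlation is
#' `rho^|j-k|`.
#'
#' @param n sample size.
#' @param p number of SNPs.
#' @param maf allele frequency in (0, 0.5].
#' @param rho AR LD parameter in \[0, 1).
#' @param copula_root optional precomputed latent root from the internal
#'   calibration (reused across replicates by the experiment harness).
#' @return n x p numeric matrix of allele counts.
#' @export
gen_genotypes <- function(n, p, maf = 0.3, rho = 0, copula_root = NULL) {
  stopifnot(maf > 0, maf <= 0.5, rho >= 0, rho < 1)
  if (rho == 0)
    return(matrix(stats::rbinom(n * p, 2L, maf), n, p))
  if (is.null(copula_root)) copula_root <- .copula_root(p, maf, rho)
  t <- stats::qnorm(maf)
  H1 <- matrix(stats::rnorm(n * p), n, p) %*% copula_root < t
  H2 <- matrix(stats::rnorm(n * p), n, p) %*% copula_root < t
  H1 + H2
}

# ---- effect draws under the variance budget --------------------------------

#' Draw true effect sizes for one replicate
#'
#' Implements the truncated-normal instrument effects, the scenario-specific
#' direct effects, and the analytic rescaling of `omega`, `upsilon` and
#' `beta` to the configured variance fractions. Scaling constants are solved
#' from the exact variance identities of the generative equations (including
#' the confounder channel and all cross-covariances) so that effect sizes
#' are deterministic given the raw draws; `beta` and the `upsilon` scale are
#' obtained jointly by a fixed-point iteration on `Var(Y)`.
#'
#' @param cfg a [scenario_config()].
#' @param ld_cov p x p true genotype covariance matrix (defaults to the
#'   analytic `2 maf (1 - maf) rho^|j-k|`).
#' @return list with `omega`, `upsilon`, `delta`, `beta`, `invalid_mask`,
#'   `var_x`, `var_y`.
#' @export
draw_effects <- function(cfg, ld_cov = NULL) {
  p <- cfg$p
  if (is.null(ld_cov)) {
    C <- cfg$rho^abs(outer(seq_len(p), seq_len(p), "-"))
    ld_cov <- 2 * cfg$maf * (1 - cfg$maf) * C
  }
  # rejection sampling from N(0, omega_sd^2) truncated to (omega_min, Inf)
  w0 <- numeric(0)
  while (length(w0) < p) {
    cand <- stats::rnorm(2 * p, 0, cfg$omega_sd)
    w0 <- c(w0, cand[cand > cfg$omega_min])
  }
  w0 <- w0[seq_len(p)]

  n_invalid <- round(cfg$prop_invalid * p)
  invalid <- rep(FALSE, p)
  if (n_invalid > 0) invalid[sample.int(p, n_invalid)] <- TRUE

  delta <- rep(0, p)
  if (cfg$scenario == "S3" && n_invalid > 0)
    delta[invalid] <- stats::runif(n_invalid, 0, cfg$delta_max)

  # scale omega: c^2 w0'S w0 = h2_gx * Var(X), with
  # Var(X) = c^2 w0'S w0 + 2 c w0'S delta + delta'S delta + 2
  s0 <- drop(crossprod(w0, ld_cov %*% w0))
  A <- drop(crossprod(w0, ld_cov %*% delta))
  d2 <- drop(crossprod(delta, ld_cov %*% delta))
  h <- cfg$h2_gx
  cc <- (h * A + sqrt(h^2 * A^2 + s0 * (1 - h) * h * (d2 + 2))) /
    (s0 * (1 - h))
  w <- cc * w0

  u <- rep(0, p)
  if (n_invalid > 0) {
    sdev <- function(v) if (cfg$dispersion == "variance") sqrt(v) else v
    u[invalid] <- switch(cfg$scenario,
      S1 = stats::rnorm(n_invalid, 0, sdev(cfg$s1_var)),
      S2 = ,
      S3 = stats::rnorm(n_invalid, 0.1 * sign(w[invalid]), sdev(cfg$s2_var)))
  }

  g <- w + delta
  var_x <- drop(crossprod(g, ld_cov %*% g)) + 2
  a <- drop(crossprod(u, ld_cov %*% u))
  c1 <- drop(crossprod(g, ld_cov %*% u))
  c3 <- drop(crossprod(u, ld_cov %*% delta))
  c2 <- drop(crossprod(g, ld_cov %*% delta))
  h_d <- if (n_invalid > 0 && a > 0) cfg$h2_direct else 0

  # scale upsilon against the non-causal outcome variance
  # V0 = k^2 a + 2 k c3 + d2 + 2 (the variance of Y when beta = 0):
  # k^2 a = h_d * V0, positive root of the implied quadratic
  k <- if (h_d > 0) {
    (h_d * c3 + sqrt(h_d^2 * c3^2 + a * (1 - h_d) * h_d * (d2 + 2))) /
      (a * (1 - h_d))
  } else 0
  V0 <- k^2 * a + 2 * k * c3 + d2 + 2

  # beta solved on the full outcome variance V = beta^2 VX + C1 beta + V0
  beta <- if (cfg$h2_xy > 0) {
    h <- cfg$h2_xy
    C1 <- 2 * k * c1 + 2 * (c2 + 1)
    (h * C1 + sqrt(h^2 * C1^2 + 4 * var_x * (1 - h) * h * V0)) /
      (2 * var_x * (1 - h))
  } else 0
  V <- beta^2 * var_x + (2 * k * c1 + 2 * (c2 + 1)) * beta + V0
  list(omega = w, upsilon = k * u, delta = delta, beta = beta,
       invalid_mask = invalid, var_x = var_x, var_y = V)
}

# ---- two-sample data generation --------------------------------------------

# Marginal (single-SNP, with intercept) regression estimates of y on every
# column of G, without forming centered copies of G.
.marginal_stats <- function(G, y) {
  n <- length(y)
  gbar <- colMeans(G)
  ybar <- mean(y)
  den <- colSums(G * G) - n * gbar^2
  num <- drop(crossprod(G, y)) - n * gbar * ybar
  b <- num / den
  yss <- sum(y^2) - n * ybar^2
  rss <- pmax(yss - b^2 * den, 0)
  se <- sqrt(rss / (n - 2) / den)
  list(beta = b, se = se, freq = gbar / 2)
}

#' Generate one two-sample replicate of marginal summary statistics
#'
#' Draws independent genotype matrices for the exposure sample (`n1`), the
#' outcome sample (`n2`) and, when `rho > 0`, a reference panel (`n_ref`);
#' simulates the confounder, exposure and outcome; and computes per-SNP
#' marginal regression estimates and standard errors in each sample.
#'
#' @param cfg a [scenario_config()].
#' @param effects a [draw_effects()] result.
#' @param copula_root optional precomputed latent root (see
#'   [gen_genotypes()]).
#' @param with_panel emit the reference panel genotype matrix (default: when
#'   `rho > 0`).
#' @return list with `exposure` and `outcome` ([marginal_summary()]
#'   objects) and `panel` (allele-count matrix or `NULL`).
#' @export
simulate_two_sample <- function(cfg, effects, copula_root = NULL,
                                with_panel = cfg$rho > 0) {
  p <- cfg$p
  if (cfg$rho > 0 && is.null(copula_root))
    copula_root <- .copula_root(p, cfg$maf, cfg$rho)
  snp <- paste0("rs", seq_len(p))
  gen <- function(n) gen_genotypes(n, p, cfg$maf, cfg$rho, copula_root)

  G1 <- gen(cfg$n1)
  U1 <- drop(G1 %*% effects$delta) + stats::rnorm(cfg$n1)
  X1 <- drop(G1 %*% effects$omega) + U1 + stats::rnorm(cfg$n1)
  sx <- .marginal_stats(G1, X1)
  exposure <- marginal_summary(snp, rep("A", p), rep("G", p),
                               sx$beta, sx$se, cfg$n1, sx$freq)

  G2 <- gen(cfg$n2)
  U2 <- drop(G2 %*% effects$delta) + stats::rnorm(cfg$n2)
  X2 <- drop(G2 %*% effects$omega) + U2 + stats::rnorm(cfg$n2)
  Y <- effects$beta * X2 + drop(G2 %*% effects$upsilon) + U2 +
    stats::rnorm(cfg$n2)
  sy <- .marginal_stats(G2, Y)
  outcome <- marginal_summary(snp, rep("A", p), rep("G", p),
                              sy$beta, sy$se, cfg$n2, sy$freq)

  panel <- if (with_panel) gen(cfg$n_ref)
  if (!is.null(panel)) colnames(panel) <- snp
  list(exposure = exposure, outcome = outcome, panel = panel)
}

# ---- per-replicate analysis and the experiment harness ---------------------

.sim_methods <- c("cochran_q", "mr_egger", "lda_mr_egger",
                  "tede_sc", "tede_aspu", "tede_sc2", "tede_aspu2")

# Run the requested tests on one replicate's summary statistics; returns a
# named vector of p-values.
.analyze_replicate <- function(dat, cfg, methods) {
  ld <- if (!is.null(dat$panel)) {
    ld_from_panel(dat$panel)
  } else if (cfg$rho > 0) {
    C <- cfg$rho^abs(outer(seq_len(cfg$p), seq_len(cfg$p), "-"))
    ld_reference(C, dat$outcome$snp, rep(cfg$maf, cfg$p))
  } else {
    ld_diag_from_freq(dat$outcome$freq, dat$outcome$snp)
  }
  pair <- harmonize(dat$exposure, dat$outcome, ld)
  pv <- stats::setNames(rep(NA_real_, length(methods)), methods)

  if ("cochran_q" %in% methods)
    pv[["cochran_q"]] <- cochran_q(pair)$p_value
  if ("mr_egger" %in% methods)
    pv[["mr_egger"]] <- mr_egger(pair)$p_value

  tede_methods <- intersect(methods,
                            c("lda_mr_egger", "tede_sc", "tede_aspu",
                              "tede_sc2", "tede_aspu2"))
  if (length(tede_methods) > 0) {
    moments <- sufficient_moments(pair)
    correlated <- !is.null(dat$panel)
    omega <- if (correlated) joint_from_marginal(moments, stage1 = TRUE)$gamma
             else pair$exposure$beta
    if ("lda_mr_egger" %in% methods) {
      j2 <- joint_from_marginal(moments)
      pv[["lda_mr_egger"]] <- lda_mr_egger(j2$gamma, j2$cov_gamma, omega)$p_value
    }
    sys <- build_score_system(moments, omega)
    cfg_spu <- spu_config(B = cfg$B)
    if ("tede_sc" %in% methods) pv[["tede_sc"]] <- tede_sc(sys)$p_value
    if ("tede_aspu" %in% methods)
      pv[["tede_aspu"]] <- tede_aspu(sys, cfg_spu)$p_value
    if (any(c("tede_sc2", "tede_aspu2") %in% methods)) {
      cov_omega <- build_cov_omega(pair, moments = moments)
      sys2 <- apply_sc2_correction(sys, cov_omega)
      if ("tede_sc2" %in% methods)
        pv[["tede_sc2"]] <- tede_sc(sys2)$p_value
      if ("tede_aspu2" %in% methods)
        pv[["tede_aspu2"]] <- tede_aspu(sys2, cfg_spu)$p_value
    }
  }
  pv
}

#' Empirical rejection rates over replicated simulations
#'
#' For each replicate: a fresh effect draw, fresh two-sample (plus panel)
#' data, moment reconstruction (analytic diagonal LD from allele frequencies
#' for independent SNPs; reference-panel LD otherwise), and each requested
#' test at `cfg$alpha_level`. Fully reproducible from `cfg$seed`; each
#' replicate runs under its own child seed so the stream is independent of
#' which methods are requested.
#'
#' @param cfg a [scenario_config()].
#' @param methods subset of `cochran_q`, `mr_egger`, `lda_mr_egger`,
#'   `tede_sc`, `tede_aspu`, `tede_sc2`, `tede_aspu2`.
#' @return data frame with one row per method: rejection proportion,
#'   binomial standard error, replicate count and level.
#' @export
run_rejection_experiment <- function(cfg, methods = c("tede_sc", "tede_aspu")) {
  stopifnot(inherits(cfg, "scenario_config"))
  methods <- match.arg(methods, .sim_methods, several.ok = TRUE)
  if (cfg$rho > 0 && any(c("cochran_q", "mr_egger") %in% methods))
    stop("cochran_q and mr_egger require independent instruments (rho = 0)")
  set.seed(cfg$seed)
  rep_seeds <- sample.int(2147483646L, cfg$n_reps)
  root <- if (cfg$rho > 0) .copula_root(cfg$p, cfg$maf, cfg$rho)
  rej <- stats::setNames(numeric(length(methods)), methods)
  n_err <- 0L
  for (i in seq_len(cfg$n_reps)) {
    set.seed(rep_seeds[i])
    pv <- tryCatch({
      eff <- draw_effects(cfg)
      dat <- simulate_two_sample(cfg, eff, copula_root = root,
                                 with_panel = cfg$rho > 0 &&
                                   cfg$ld_source == "panel")
      .analyze_replicate(dat, cfg, methods)
    }, error = function(e) e)
    if (inherits(pv, "error")) {
      n_err <- n_err + 1L
      if (n_err > max(1L, ceiling(0.01 * cfg$n_reps)))
        stop("more than 1% of replicates failed; last error: ",
             conditionMessage(pv))
      next
    }
    rej <- rej + (pv[methods] < cfg$alpha_level)
  }
  n_ok <- cfg$n_reps - n_err
  rate <- rej / n_ok
  data.frame(method = methods, rate = as.numeric(rate),
             se = sqrt(rate * (1 - rate) / n_ok),
             n_reps = n_ok, alpha = cfg$alpha_level,
             row.names = NULL, stringsAsFactors = FALSE)
}
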