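# Reconstruction of sufficient cross-product statistics from marginal GWAS
# summary statistics plus an LD reference. All tests downstream consume only
# these moments, so with an exact LD reference (the analysis sample itself)
# every summary-level statistic equals its individual-level counterpart.

#' Genotype cross-product matrix G'G implied by an LD reference
#'
#' For centered allele counts, `(G'G)[j,k] = corr[j,k] * sqrt(v_j v_k) *
#' (n - 1)` with `v_j = 2 f_j (1 - f_j)` the Hardy-Weinberg variance of an
#' allele count. With a diagonal (independent-SNP) reference the
#' off-diagonal entries are exactly zero.
#'
#' @param ld an `"ld_reference"`.
#' @param n sample size at which the cross-products are wanted.
#' @return p x p matrix.
#' @export
build_gtg <- function(ld, n) {
  stopifnot(inherits(ld, "ld_reference"), n > 1)
  f <- ld$freq
  if (any(f <= 0 | f >= 1)) stop("allele frequencies must be in (0, 1)")
  v <- 2 * f * (1 - f)
  sdv <- sqrt(v)
  ld$corr * tcrossprod(sdv) * (n - 1)
}

#' Genotype-trait cross-products G'Y from marginal effect estimates
#'
#' Normal equation of the single-SNP centered regression:
#' `G_j'Y = beta*_j * (G'G)[j,j]`.
#'
#' @param marg a [marginal_summary()] for the trait.
#' @param gtg_diag diagonal of the G'G matrix at the trait's sample size.
#' @return length-p vector.
#' @export
build_gty <- function(marg, gtg_diag) {
  stopifnot(inherits(marg, "marginal_summary"),
            length(gtg_diag) == nrow(marg))
  marg$beta * gtg_diag
}

#' Trait sum of squares Y'Y implied by marginal standard errors
#'
#' Inverts the OLS variance formula of the marginal regression with
#' intercept: each SNP implies a total (centered) sum of squares
#' `s_j = se_j^2 (n - 2) (G'G)[j,j] + beta*_j^2 (G'G)[j,j]`; the median over
#' SNPs is returned as a robust aggregate (a few mis-scaled standard errors
#' should not corrupt the reconstruction).
#'
#' @inheritParams build_gty
#' @return scalar Y'Y (centered).
#' @export
build_yty <- function(marg, gtg_diag) {
  stopifnot(inherits(marg, "marginal_summary"))
  n <- marg$n
  if (any(n <= 2)) stop("sample size must exceed 2 to invert the marginal SE")
  stats::median(marg$se^2 * (n - 2) * gtg_diag + marg$beta^2 * gtg_diag)
}

#' Sufficient moments for the LD-aware tests
#'
#' Bundles the outcome-side cross-products (and, when stage-1 information is
#' available, the exposure-side analogues) reconstructed from a harmonized
#' pair. The LD reference supplies the correlation structure; allele
#' frequencies are taken from each trait's own summary statistics when
#' present, falling back to the reference panel.
#'
#' @param pair a [harmonize()]d (and, for Egger-type tests,
#'   [egger_orient()]ed) pair.
#' @param max_condition largest acceptable condition number of G'G before
#'   the reconstruction refuses to proceed; instruments should be pruned
#'   (e.g. r^2 < 0.9) rather than silently regularized.
#' @return Object of class `"sufficient_moments"`: list with `GtG`, `GtY`,
#'   `YtY`, `n` (outcome-side), and `stage1_GtG`, `stage1_GtX`, `XtX`, `n1`
#'   (exposure-side).
#' @export
sufficient_moments <- function(pair, max_condition = 1e10) {
  stopifnot(inherits(pair, "harmonized_pair"))
  out <- pair$outcome
  n2 <- out$n[1]
  f_out <- if (!is.null(out$freq)) out$freq else pair$ld$freq
  ld_out <- ld_reference(pair$ld$corr, pair$ld$snp, f_out, pair$ld$n_ref)
  GtG <- build_gtg(ld_out, n2)
  .check_condition(GtG, max_condition)
  gd <- diag(GtG)
  exp <- pair$exposure
  n1 <- exp$n[1]
  f_exp <- if (!is.null(exp$freq)) exp$freq else pair$ld$freq
  ld_exp <- ld_reference(pair$ld$corr, pair$ld$snp, f_exp, pair$ld$n_ref)
  G1tG1 <- build_gtg(ld_exp, n1)
  structure(list(GtG = GtG, GtY = build_gty(out, gd),
                 YtY = build_yty(out, gd), n = n2,
                 stage1_GtG = G1tG1,
                 stage1_GtX = build_gty(exp, diag(G1tG1)),
                 XtX = build_yty(exp, diag(G1tG1)), n1 = n1),
            class = "sufficient_moments")
}

.check_condition <- function(m, max_condition) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > max_condition)
    stop("G'G is ill-conditioned (condition number > ", max_condition,
         "); prune correlated SNPs before testing")
  invisible(TRUE)
}

#' Joint SNP effects and their covariance from marginal moments
#'
#' Multiple-regression (joint) effect estimates recovered from the
#' reconstructed normal equations: `gamma = (G'G)^{-1} G'Y`, residual
#' variance `sigma2 = (Y'Y - gamma'G'Y) / (n - p - 1)` (floored at a small
#' positive value), `Cov(gamma) = sigma2 (G'G)^{-1}`. On a diagonal LD
#' reference this is the identity map on effect estimates.
#'
#' @param moments a [sufficient_moments()] object (or a list with `GtG`,
#'   `GtY`, `YtY`, `n`).
#' @param stage1 use the exposure-side (stage-1) moments instead, returning
#'   joint SNP-to-exposure weights and their covariance.
#' @return list with `gamma` (joint effects), `cov_gamma`, `sigma2`.
#' @export
joint_from_marginal <- function(moments, stage1 = FALSE) {
  if (stage1) {
    A <- moments$stage1_GtG; b <- moments$stage1_GtX
    yy <- moments$XtX; n <- moments$n1
  } else {
    A <- moments$GtG; b <- moments$GtY
    yy <- moments$YtY; n <- moments$n
  }
  p <- length(b)
  ch <- tryCatch(chol(A), error = function(e)
    stop("G'G is not positive definite; prune correlated SNPs"))
  gamma <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  df <- n - p - 1
  if (df < 1) stop("sample size too small relative to the number of SNPs")
  sigma2 <- max((yy - sum(gamma * b)) / df, 1e-12 * yy / (n - 1))
  Ainv <- chol2inv(ch)
  list(gamma = as.numeric(gamma), cov_gamma = sigma2 * Ainv, sigma2 = sigma2)
}

#' Covariance of the joint stage-1 weights
#'
#' Reconstructs `Cov(omega_hat) = sigma2_X (G1'G1)^{-1}` from the exposure's
#' marginal summary statistics and the LD reference, for use by the
#' variance-corrected TEDE-Sc2/TEDE-aSPU2 tests. When joint weights carry
#' their own standard errors (TWAS weight files), those are used directly:
#' `Cov(omega_hat) = D R^{-1} D` with `D = diag(se)` scaled through the
#' inverse LD correlation, collapsing to `diag(se^2)` for independent SNPs.
#'
#' @param pair a harmonized pair (needs exposure standard errors), or
#'   `NULL` if `weights` with `se_omega` are supplied.
#' @param weights optional [joint_weights()] with `se_omega`.
#' @param moments optional precomputed [sufficient_moments()] for `pair`.
#' @return p x p covariance matrix, or an error of class
#'   `"tede_no_stage1_se"` when no standard errors are available anywhere
#'   (the Sc2/aSPU2 variants are then unavailable).
#' @export
build_cov_omega <- function(pair = NULL, weights = NULL, moments = NULL) {
  if (!is.null(weights) && !is.null(weights$se_omega)) {
    if (is.null(pair)) stop("an LD reference (via `pair`) is required")
    D <- diag(weights$se_omega, nrow = length(weights$se_omega))
    Rinv <- solve(pair$ld$corr)
    return(D %*% Rinv %*% D)
  }
  if (is.null(pair) || is.null(pair$exposure$se) ||
      !all(is.finite(pair$exposure$se))) {
    cond <- simpleError(paste("no stage-1 standard errors available;",
                              "TEDE-Sc2/TEDE-aSPU2 cannot be applied"))
    class(cond) <- c("tede_no_stage1_se", class(cond))
    stop(cond)
  }
  if (is.null(moments)) moments <- sufficient_moments(pair)
  j1 <- joint_from_marginal(moments, stage1 = TRUE)
  j1$cov_gamma
}
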