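# Comparator model-checking tests: Cochran's Q and the MR-Egger intercept
# test for independent instruments, and LDA MR-Egger (generalized
# least-squares Egger regression on joint effects) for correlated ones.

.test_result <- function(method, statistic, df, p_value, estimates = NULL,
                         extras = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, estimates = estimates, extras = extras),
            class = "tede_result")
}

#' @export
print.tede_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4), sep = "")
  if (!is.null(x$df) && is.finite(x$df)) cat(", df =", x$df)
  cat(", p =", format.pval(x$p_value, digits = 3), "\n")
  if (!is.null(x$estimates)) {
    est <- x$estimates
    cat("  ", paste(names(est), format(unlist(est), digits = 4),
                    sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cochran's Q heterogeneity test for independent instruments
#'
#' Tests the consistency of the per-SNP Wald ratios `beta*_j =
#' gamma*_j / omega*_j` around the inverse-variance-weighted mean:
#' `Q = sum w_j (beta*_j - beta*_IVW)^2 ~ chi^2(p - 1)` under the null of
#' no heterogeneity (no pleiotropy).
#'
#' Two weighting conventions are offered. `"first_order"` (default) is the
#' standard first-order inverse variance of the ratio,
#' `w_j = (omega*_j / se(gamma*_j))^2`. `"paper"` uses
#' `w_j = (gamma*_j / se(gamma*_j))^2`, a convention that appears in some of
#' the MR model-checking literature but weights by the outcome rather than
#' the exposure association.
#'
#' @param pair a [harmonize()]d pair of at least 2 independent SNPs; every
#'   marginal exposure effect must be nonzero.
#' @param weight_mode `"first_order"` or `"paper"`.
#' @return A `"tede_result"` with the IVW estimate in `$estimates`.
#' @export
cochran_q <- function(pair, weight_mode = c("first_order", "paper")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(pair, "harmonized_pair"))
  omega <- pair$exposure$beta
  gamma <- pair$outcome$beta
  se_g <- pair$outcome$se
  p <- length(omega)
  if (p < 2) stop("Cochran's Q needs at least 2 instruments")
  if (any(omega == 0))
    stop("zero marginal exposure effect (undefined Wald ratio) for SNP(s): ",
         paste(pair$exposure$snp[omega == 0], collapse = ", "))
  ratio <- gamma / omega
  w <- switch(weight_mode,
              first_order = (omega / se_g)^2,
              paper = (gamma / se_g)^2)
  ivw <- sum(w * ratio) / sum(w)
  Q <- sum(w * (ratio - ivw)^2)
  .test_result("Cochran's Q", Q, p - 1L,
               stats::pchisq(Q, df = p - 1, lower.tail = FALSE),
               estimates = list(beta_ivw = ivw),
               extras = list(weight_mode = weight_mode))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Weighted least-squares regression of the marginal outcome effects on the
#' marginal exposure effects with an intercept,
#' `gamma* = l alpha + omega* beta + eps`, `eps ~ N(0, phi *
#' diag(se(gamma*)^2))`. Following the standard multiplicative
#' random-effects formulation of MR-Egger, the overdispersion `phi` is
#' estimated from the weighted residual mean square and floored at 1, and
#' scales the coefficient standard errors. A nonzero intercept indicates a
#' nonzero average direct effect (directional pleiotropy); the reported
#' p-value is the two-sided normal test of `alpha = 0`. SNP coding is first
#' flipped so that all marginal exposure effects are positive (see
#' [egger_orient()]); this is part of the method and is applied internally
#' (a no-op on already-oriented input).
#'
#' @param pair a [harmonize()]d pair of at least 3 independent SNPs.
#' @return A `"tede_result"` with `alpha`, `beta` and their SEs in
#'   `$estimates`.
#' @export
mr_egger <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  pair <- egger_orient(pair, use_joint = FALSE)
  omega <- pair$exposure$beta
  gamma <- pair$outcome$beta
  w <- 1 / pair$outcome$se^2
  if (length(omega) < 3) stop("MR-Egger needs at least 3 instruments")
  if (stats::sd(omega) == 0)
    stop("all exposure effects identical: Egger design is collinear")
  X <- cbind(intercept = 1, slope = omega)
  XtW <- t(X * w)
  M <- XtW %*% X
  est <- unname(drop(solve(M, XtW %*% gamma)))
  resid <- gamma - drop(X %*% est)
  phi <- max(1, sum(w * resid^2) / (length(gamma) - 2))
  covm <- phi * solve(M)
  se <- unname(sqrt(diag(covm)))
  z <- est[1] / se[1]
  .test_result("MR-Egger", z^2, 1L,
               2 * stats::pnorm(abs(z), lower.tail = FALSE),
               estimates = list(alpha = est[1], se_alpha = se[1],
                                beta = est[2], se_beta = se[2],
                                p_beta = 2 * stats::pnorm(abs(est[2] / se[2]),
                                                          lower.tail = FALSE)))
}

#' LDA MR-Egger: Egger regression on joint effects under LD
#'
#' Generalized least squares fit of the joint outcome effects on the joint
#' exposure effects with an intercept, `gamma = l alpha + omega beta + eps`,
#' `eps ~ N(0, Sigma)` with `Sigma = Cov(gamma)`. The closed-form estimator
#' is `(alpha, beta)' = M^{-1} (l'Sigma^{-1}gamma, omega'Sigma^{-1}gamma)'`
#' with `M` the 2 x 2 Gram matrix of `(l, omega)` under `Sigma^{-1}`, and
#' `Cov(alpha, beta) = M^{-1}`. The intercept z-test probes directional
#' pleiotropy; the slope z-test probes the causal effect.
#'
#' @param gamma length-p joint SNP-to-outcome effects (see
#'   [joint_from_marginal()]).
#' @param cov_gamma p x p covariance of `gamma`.
#' @param omega length-p joint SNP-to-exposure weights; coding should be
#'   oriented so all are positive ([egger_orient()] with `use_joint = TRUE`);
#'   orientation is applied internally when needed.
#' @return A `"tede_result"` for the intercept test, with slope estimates in
#'   `$estimates`.
#' @export
lda_mr_egger <- function(gamma, cov_gamma, omega) {
  p <- length(gamma)
  stopifnot(length(omega) == p, nrow(cov_gamma) == p, ncol(cov_gamma) == p)
  if (p < 3) stop("LDA MR-Egger needs at least 3 instruments")
  s <- ifelse(omega < 0, -1, 1)
  if (any(s < 0)) {           # orient coding so joint exposure effects > 0
    omega <- s * omega
    gamma <- s * gamma
    cov_gamma <- cov_gamma * tcrossprod(s)
  }
  ch <- tryCatch(chol(cov_gamma), error = function(e)
    stop("Cov(gamma) is not positive definite"))
  solveS <- function(v) backsolve(ch, backsolve(ch, v, transpose = TRUE))
  l <- rep(1, p)
  Sl <- solveS(l); Sw <- solveS(omega); Sg <- solveS(gamma)
  M <- matrix(c(sum(l * Sl), sum(l * Sw), sum(omega * Sl), sum(omega * Sw)),
              2, 2, byrow = TRUE)
  if (abs(det(M)) < 1e-12 * max(abs(M))^2)
    stop("intercept and exposure effects are collinear")
  est <- unname(solve(M, c(sum(l * Sg), sum(omega * Sg))))
  covm <- solve(M)
  se <- unname(sqrt(diag(covm)))
  z <- est[1] / se[1]
  .test_result("LDA MR-Egger", z^2, 1L,
               2 * stats::pnorm(abs(z), lower.tail = FALSE),
               estimates = list(alpha = est[1], se_alpha = se[1],
                                beta = est[2], se_beta = se[2],
                                p_beta = 2 * stats::pnorm(abs(est[2] / se[2]),
                                                          lower.tail = FALSE)))
}
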