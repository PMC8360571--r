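#' Run a panel of direct-effect tests on harmonized summary statistics
#'
#' Convenience wrapper for the full summary-statistic pipeline: harmonizes
#' the inputs, reconstructs the sufficient moments, and runs the requested
#' tests. For correlated instruments the stage-1 joint weights are either
#' supplied (`weights`) or reconstructed from the exposure's marginal
#' statistics and the LD reference; for independent instruments the marginal
#' exposure effects serve as the weights.
#'
#' @param exposure,outcome [marginal_summary()] objects.
#' @param ld an `"ld_reference"`; use [ld_diag_from_freq()] for independent
#'   SNPs or [ld_from_panel()] for a genotype panel.
#' @param weights optional [joint_weights()].
#' @param methods subset of `cochran_q`, `mr_egger`, `lda_mr_egger`,
#'   `tede_sc`, `tede_aspu`, `tede_sc2`, `tede_aspu2`. `cochran_q` and
#'   `mr_egger` assume independent instruments.
#' @param B Monte-Carlo sample count for the aSPU tests.
#' @param seed optional seed for the aSPU Monte-Carlo draws.
#' @return named list of `"tede_result"` objects.
#' @export
tede_test <- function(exposure, outcome, ld, weights = NULL,
                      methods = c("tede_sc", "tede_aspu"),
                      B = 1000, seed = NULL) {
  methods <- match.arg(methods, .sim_methods, several.ok = TRUE)
  pair <- harmonize(exposure, outcome, ld, weights)
  out <- list()
  if ("cochran_q" %in% methods) out$cochran_q <- cochran_q(pair)
  if ("mr_egger" %in% methods) out$mr_egger <- mr_egger(pair)

  rest <- setdiff(methods, c("cochran_q", "mr_egger"))
  if (length(rest) > 0) {
    moments <- sufficient_moments(pair)
    diagonal <- all(pair$ld$corr[upper.tri(pair$ld$corr)] == 0)
    omega <- if (!is.null(pair$weights)) pair$weights$omega
             else if (diagonal) pair$exposure$beta
             else joint_from_marginal(moments, stage1 = TRUE)$gamma
    if ("lda_mr_egger" %in% rest) {
      j2 <- joint_from_marginal(moments)
      out$lda_mr_egger <- lda_mr_egger(j2$gamma, j2$cov_gamma, omega)
    }
    sys <- build_score_system(moments, omega)
    cfg <- spu_config(B = B, seed = seed)
    if ("tede_sc" %in% rest) out$tede_sc <- tede_sc(sys)
    if ("tede_aspu" %in% rest) out$tede_aspu <- tede_aspu(sys, cfg)
    if (any(c("tede_sc2", "tede_aspu2") %in% rest)) {
      cov_omega <- build_cov_omega(pair, weights = pair$weights,
                                   moments = moments)
      sys2 <- apply_sc2_correction(sys, cov_omega)
      if ("tede_sc2" %in% rest) out$tede_sc2 <- tede_sc(sys2)
      if ("tede_aspu2" %in% rest) out$tede_aspu2 <- tede_aspu(sys2, cfg)
    }
  }
  out[methods]
}

#' Flatten a list of test results to a data frame
#'
#' @param results a list of `"tede_result"` objects, as returned by
#'   [tede_test()] .
#' @return data frame with method, statistic, df and p-value columns.
#' @export
results_table <- function(results) {
  data.frame(method = vapply(results, `[[`, "", "method"),
             statistic = vapply(results, `[[`, 0, "statistic"),
             df = vapply(results, function(r)
               if (is.null(r$df)) NA_real_ else as.numeric(r$df), 0),
             p_value = vapply(results, `[[`, 0, "p_value"),
             row.names = NULL, stringsAsFactors = FALSE)
}
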