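#' Marginal GWAS summary statistics for one trait
#'
#' Container for per-SNP marginal association estimates (one regression of
#' the trait on each SNP separately, with intercept), as distributed in
#' standard GWAS summary files.
#'
#' @param snp character vector of unique SNP identifiers.
#' @param a1,a2 effect and other allele codes (single characters such as
#'   "A", "C"; any consistent coding is accepted).
#' @param beta per-SNP marginal effect estimates, trait units per copy of
#'   the effect allele.
#' @param se standard errors of `beta`; must be strictly positive.
#' @param n association sample size (scalar or per-SNP vector).
#' @param freq effect-allele frequencies in (0, 1), or `NULL` when the
#'   summary file does not report them (they can then be taken from an LD
#'   reference panel).
#'
#' @return An object of class `"marginal_summary"`: a data frame with
#'   columns `snp`, `a1`, `a2`, `beta`, `se`, `n` and optionally `freq`.
#' @export
marginal_summary <- function(snp, a1, a2, beta, se, n, freq = NULL) {
  snp <- as.character(snp)
  p <- length(snp)
  if (p < 1L) stop("need at least one SNP")
  if (anyDuplicated(snp)) stop("duplicated SNP identifiers: ",
                               paste(unique(snp[duplicated(snp)]), collapse = ", "))
  if (length(n) == 1L) n <- rep(n, p)
  stopifnot(length(a1) == p, length(a2) == p, length(beta) == p,
            length(se) == p, length(n) == p)
  if (any(!is.finite(se)) || any(se <= 0)) {
    bad <- snp[!is.finite(se) | se <= 0]
    stop("non-positive or missing standard errors for SNP(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(freq)) {
    stopifnot(length(freq) == p)
    if (any(freq <= 0 | freq >= 1, na.rm = TRUE))
      stop("allele frequencies must lie strictly in (0, 1)")
  }
  out <- data.frame(snp = snp, a1 = toupper(as.character(a1)),
                    a2 = toupper(as.character(a2)),
                    beta = as.numeric(beta), se = as.numeric(se),
                    n = as.numeric(n), stringsAsFactors = FALSE)
  if (!is.null(freq)) out$freq <- as.numeric(freq)
  class(out) <- c("marginal_summary", "data.frame")
  out
}

#' First-stage joint SNP-to-exposure weights (TWAS weights)
#'
#' @param snp SNP identifiers.
#' @param omega joint (multiple-regression) SNP-to-exposure effects.
#' @param a1,a2 optional allele codes; when present, weights participate in
#'   allele harmonization.
#' @param se_omega optional standard errors of `omega` (strictly positive).
#'   Required by the variance-corrected TEDE-Sc2/TEDE-aSPU2 tests.
#' @param n1 optional stage-1 sample size.
#' @return Object of class `"joint_weights"`.
#' @export
joint_weights <- function(snp, omega, a1 = NULL, a2 = NULL,
                          se_omega = NULL, n1 = NULL) {
  snp <- as.character(snp)
  p <- length(snp)
  stopifnot(length(omega) == p)
  if (anyDuplicated(snp)) stop("duplicated SNP identifiers in weights")
  if (!is.null(se_omega)) {
    stopifnot(length(se_omega) == p)
    if (any(se_omega <= 0)) stop("se_omega must be strictly positive")
  }
  out <- list(snp = snp, omega = as.numeric(omega),
              a1 = if (!is.null(a1)) toupper(as.character(a1)),
              a2 = if (!is.null(a2)) toupper(as.character(a2)),
              se_omega = if (!is.null(se_omega)) as.numeric(se_omega),
              n1 = n1)
  class(out) <- "joint_weights"
  out
}

#' LD reference: SNP correlation structure plus allele frequencies
#'
#' @param corr p x p SNP allele-count correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite within tolerance). Use
#'   [ld_diag_from_freq()] for the independent-SNP (MR) case.
#' @param snp SNP identifiers matching the rows/columns of `corr`.
#' @param freq allele frequencies in (0, 1), one per SNP.
#' @param n_ref reference-panel sample size, or `NA` when the matrix is the
#'   analytic diagonal built from frequencies alone.
#' @return Object of class `"ld_reference"`.
#' @export
ld_reference <- function(corr, snp, freq, n_ref = NA_real_) {
  corr <- as.matrix(corr)
  p <- length(snp)
  stopifnot(nrow(corr) == p, ncol(corr) == p, length(freq) == p)
  if (max(abs(corr - t(corr))) > 1e-8) stop("LD matrix must be symmetric")
  corr <- (corr + t(corr)) / 2
  if (max(abs(diag(corr) - 1)) > 1e-6) stop("LD matrix must have unit diagonal")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("LD matrix is not positive semi-definite within tolerance")
  if (any(freq <= 0 | freq >= 1))
    stop("allele frequencies must lie strictly in (0, 1)")
  dimnames(corr) <- list(snp, snp)
  structure(list(snp = as.character(snp), corr = corr,
                 freq = as.numeric(freq), n_ref = n_ref),
            class = "ld_reference")
}

#' Diagonal LD reference from allele frequencies (independent SNPs)
#'
#' For MR with independent instruments no panel is needed: the genotype
#' variance of each SNP is 2f(1-f) under Hardy-Weinberg equilibrium, so the
#' LD correlation matrix is the identity.
#'
#' @inheritParams ld_reference
#' @return An `"ld_reference"` with identity correlation.
#' @export
ld_diag_from_freq <- function(freq, snp = paste0("snp", seq_along(freq))) {
  ld_reference(diag(length(freq)), snp = snp, freq = freq, n_ref = NA_real_)
}

#' LD reference estimated from a genotype reference panel
#'
#' @param geno samples x SNPs matrix of allele counts (values in \[0, 2\]).
#' @param snp SNP identifiers (defaults to the column names of `geno`).
#' @return An `"ld_reference"` with panel-estimated correlation and
#'   frequencies, `n_ref` set to the panel size.
#' @export
ld_from_panel <- function(geno, snp = colnames(geno)) {
  geno <- as.matrix(geno)
  if (is.null(snp)) snp <- paste0("snp", seq_len(ncol(geno)))
  if (any(geno < 0 | geno > 2, na.rm = TRUE))
    stop("panel genotypes must be allele counts in [0, 2]")
  freq <- colMeans(geno) / 2
  if (any(freq <= 0 | freq >= 1))
    stop("monomorphic SNP(s) in reference panel: ",
         paste(snp[freq <= 0 | freq >= 1], collapse = ", "))
  ld_reference(stats::cor(geno), snp = snp, freq = freq, n_ref = nrow(geno))
}

# ---- file input/output -----------------------------------------------------

.sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

.default_map <- c(snp = "SNP", a1 = "A1", a2 = "A2", beta = "BETA",
                  se = "SE", n = "N", freq = "FREQ")

#' Read marginal GWAS summary statistics from a delimited text file
#'
#' The delimiter is sniffed from tab, comma and whitespace. Column names are
#' remapped through `column_map`, whose entries name the file columns holding
#' each canonical field (`snp`, `a1`, `a2`, `beta`, `se`, `n`, `freq`).
#' Rows with missing `beta` or `se` are dropped with a message giving the
#' count.
#'
#' @param path file path.
#' @param column_map named character vector overriding any of the default
#'   column names `SNP, A1, A2, BETA, SE, N, FREQ`.
#' @return A [marginal_summary()] object.
#' @export
read_marginal_summary <- function(path, column_map = character()) {
  map <- .default_map
  map[names(column_map)] <- column_map
  tab <- utils::read.table(path, header = TRUE, sep = .sniff_delim(path),
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("snp", "a1", "a2", "beta", "se", "n")
  for (f in required)
    if (!map[[f]] %in% names(tab))
      stop("required column '", map[[f]], "' (", f, ") not found in ", path)
  keep <- is.finite(suppressWarnings(as.numeric(tab[[map[["beta"]]]]))) &
    is.finite(suppressWarnings(as.numeric(tab[[map[["se"]]]])))
  if (any(!keep))
    message("dropped ", sum(!keep), " row(s) with missing beta or se")
  tab <- tab[keep, , drop = FALSE]
  freq <- if (map[["freq"]] %in% names(tab)) as.numeric(tab[[map[["freq"]]]])
  marginal_summary(snp = tab[[map[["snp"]]]], a1 = tab[[map[["a1"]]]],
                   a2 = tab[[map[["a2"]]]],
                   beta = as.numeric(tab[[map[["beta"]]]]),
                   se = as.numeric(tab[[map[["se"]]]]),
                   n = as.numeric(tab[[map[["n"]]]]), freq = freq)
}

#' Write marginal summary statistics to a tab-delimited file
#'
#' Full numeric precision is preserved so that a read/write round trip is
#' exact.
#'
#' @param x a [marginal_summary()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marginal_summary <- function(x, path) {
  stopifnot(inherits(x, "marginal_summary"))
  out <- data.frame(SNP = x$snp, A1 = x$a1, A2 = x$a2,
                    BETA = format(x$beta, digits = 17),
                    SE = format(x$se, digits = 17), N = format(x$n, digits = 17))
  if (!is.null(x$freq)) out$FREQ <- format(x$freq, digits = 17)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read TWAS weights (joint SNP-to-exposure effects) from delimited text
#'
#' Expected columns `SNP, A1, A2, WEIGHT` and optionally `SE_WEIGHT`.
#'
#' @param path file path.
#' @return A [joint_weights()] object.
#' @export
read_joint_weights <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = .sniff_delim(path),
                           stringsAsFactors = FALSE)
  for (f in c("SNP", "WEIGHT"))
    if (!f %in% names(tab)) stop("required column '", f, "' not found in ", path)
  joint_weights(snp = tab$SNP, omega = tab$WEIGHT,
                a1 = if ("A1" %in% names(tab)) tab$A1,
                a2 = if ("A2" %in% names(tab)) tab$A2,
                se_omega = if ("SE_WEIGHT" %in% names(tab)) tab$SE_WEIGHT)
}

#' Read an LD correlation matrix with a SNP-id sidecar
#'
#' @param path square delimited numeric matrix (no header).
#' @param snp_path text file with one SNP id per line, in matrix order.
#' @param freq allele frequencies for the SNPs (the matrix file carries
#'   none).
#' @param n_ref panel size behind the matrix, if known.
#' @return An `"ld_reference"`.
#' @export
read_ld_matrix <- function(path, snp_path, freq, n_ref = NA_real_) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  snp <- readLines(snp_path)
  snp <- snp[nzchar(snp)]
  ld_reference(m, snp = snp, freq = freq, n_ref = n_ref)
}

# ---- harmonization ---------------------------------------------------------

.is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

# Align `other` (marginal_summary or joint_weights) to the reference alleles.
# Returns list(obj, keep, flipped) on the common index set `idx`.
.align_alleles <- function(ref_a1, ref_a2, a1, a2) {
  same <- a1 == ref_a1 & a2 == ref_a2
  swap <- a1 == ref_a2 & a2 == ref_a1
  list(keep = same | swap, flip = swap & !same)
}

#' Harmonize exposure, outcome, weights and LD reference to one SNP set
#'
#' Restricts all inputs to their common SNPs, ordered as in the LD
#' reference, and aligns effect alleles to the exposure's coding: where the
#' outcome (or weights) reports the swapped allele pair, its effect sign is
#' negated and its frequency replaced by `1 - f`. Allele pairs matching
#' neither orientation, and strand-ambiguous (A/T, C/G) SNPs whose
#' orientations conflict, are dropped with a warning; no strand inference is
#' attempted.
#'
#' @param exposure,outcome [marginal_summary()] objects.
#' @param ld an `"ld_reference"`; its SNP order is canonical.
#' @param weights optional [joint_weights()].
#' @return Object of class `"harmonized_pair"`: list with elements
#'   `exposure`, `outcome`, `weights`, `ld` and `flip_mask` (logical record
#'   of sign flips applied by [egger_orient()], initialized to `FALSE`).
#' @export
harmonize <- function(exposure, outcome, ld, weights = NULL) {
  stopifnot(inherits(exposure, "marginal_summary"),
            inherits(outcome, "marginal_summary"),
            inherits(ld, "ld_reference"))
  common <- ld$snp[ld$snp %in% exposure$snp & ld$snp %in% outcome$snp]
  if (!is.null(weights)) common <- common[common %in% weights$snp]
  if (length(common) == 0L) stop("no SNPs shared by all inputs")

  ei <- match(common, exposure$snp)
  oi <- match(common, outcome$snp)
  li <- match(common, ld$snp)
  exp <- exposure[ei, , drop = FALSE]
  out <- outcome[oi, , drop = FALSE]

  al <- .align_alleles(exp$a1, exp$a2, out$a1, out$a2)
  keep <- al$keep
  # strand-ambiguous SNPs with conflicting orientation cannot be resolved
  ambig <- .is_palindromic(exp$a1, exp$a2) & al$flip
  keep <- keep & !ambig
  if (any(!keep))
    warning("dropped ", sum(!keep),
            " SNP(s) with unresolvable allele orientation: ",
            paste(common[!keep], collapse = ", "))

  wflip <- rep(FALSE, length(common))
  if (!is.null(weights)) {
    wi <- match(common, weights$snp)
    if (!is.null(weights$a1)) {
      wal <- .align_alleles(exp$a1, exp$a2, weights$a1[wi], weights$a2[wi])
      wkeep <- wal$keep & !(.is_palindromic(exp$a1, exp$a2) & wal$flip)
      keep <- keep & wkeep
      wflip <- wal$flip
    }
  }
  if (!any(keep)) stop("no SNPs left after allele harmonization")

  common <- common[keep]
  exp <- exp[keep, , drop = FALSE]
  out <- out[keep, , drop = FALSE]
  flip <- al$flip[keep]
  out$beta[flip] <- -out$beta[flip]
  if (!is.null(out$freq)) out$freq[flip] <- 1 - out$freq[flip]
  tmp <- out$a1[flip]; out$a1[flip] <- out$a2[flip]; out$a2[flip] <- tmp

  w <- NULL
  if (!is.null(weights)) {
    wi <- match(common, weights$snp)
    w <- joint_weights(snp = common,
                       omega = ifelse(wflip[keep], -1, 1) * weights$omega[wi],
                       a1 = exp$a1, a2 = exp$a2,
                       se_omega = if (!is.null(weights$se_omega))
                         weights$se_omega[wi],
                       n1 = weights$n1)
  }
  li <- match(common, ld$snp)
  ld2 <- ld_reference(ld$corr[li, li, drop = FALSE], snp = common,
                      freq = ld$freq[li], n_ref = ld$n_ref)
  structure(list(exposure = exp, outcome = out, weights = w, ld = ld2,
                 flip_mask = rep(FALSE, length(common))),
            class = "harmonized_pair")
}

#' Orient SNP coding so all exposure effects are positive
#'
#' Egger-type tests require all SNP-to-exposure effects to be positive; any
#' SNP with a negative exposure effect has its coding flipped (allele count
#' G mapped to 2 - G). The flip negates that SNP's exposure and outcome
#' effects, its joint weight, and the sign of its LD correlation with every
#' other SNP, and replaces its allele frequency by `1 - f`. SNPs with an
#' exposure effect of exactly zero are left unflipped with a warning (the
#' sign is undefined and either choice leaves the design unchanged in the
#' limit).
#'
#' @param pair a [harmonize()]d pair.
#' @param use_joint flip on the sign of the joint weights (TWAS/LDA path)
#'   instead of the marginal exposure effects (MR path).
#' @return The re-oriented `"harmonized_pair"`, with `flip_mask` updated
#'   (applying the function twice returns the original pair).
#' @export
egger_orient <- function(pair, use_joint = FALSE) {
  stopifnot(inherits(pair, "harmonized_pair"))
  eff <- if (use_joint) {
    if (is.null(pair$weights)) stop("use_joint = TRUE requires joint weights")
    pair$weights$omega
  } else pair$exposure$beta
  if (any(eff == 0))
    warning("exposure effect exactly zero for SNP(s) ",
            paste(pair$exposure$snp[eff == 0], collapse = ", "),
            "; left unflipped")
  flip <- eff < 0
  if (!any(flip)) return(pair)
  s <- ifelse(flip, -1, 1)
  pair$exposure$beta <- s * pair$exposure$beta
  pair$outcome$beta <- s * pair$outcome$beta
  if (!is.null(pair$exposure$freq))
    pair$exposure$freq[flip] <- 1 - pair$exposure$freq[flip]
  if (!is.null(pair$outcome$freq))
    pair$outcome$freq[flip] <- 1 - pair$outcome$freq[flip]
  if (!is.null(pair$weights)) pair$weights$omega <- s * pair$weights$omega
  # coding flip G -> 2 - G conjugates the correlation by diag(s)
  pair$ld$corr <- pair$ld$corr * tcrossprod(s)
  pair$ld$freq[flip] <- 1 - pair$ld$freq[flip]
  pair$flip_mask <- xor(pair$flip_mask, flip)
  pair
}
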