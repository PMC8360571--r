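test_that("marginal summary files round-trip and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  x <- marginal_summary(c("rs1", "rs2", "rs3"), c("A", "C", "T"),
                        c("G", "T", "C"), beta = c(0.1, -0.02, 1 / 3),
                        se = c(0.01, 0.02, 0.002), n = 1234,
                        freq = c(0.3, 0.41, 1 / 7))
  write_marginal_summary(x, path)
  y <- read_marginal_summary(path)
  expect_equal(y$beta, x$beta)
  expect_equal(y$se, x$se)
  expect_equal(y$freq, x$freq)
  expect_identical(y$snp, x$snp)

  # a zero SE must be rejected naming the SNP
  expect_error(marginal_summary("rs9", "A", "G", 0.1, 0, 100), "rs9")
})

test_that("reader drops rows with missing beta or se, with a count", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tA2\tBETA\tSE\tN",
               "rs1\tA\tG\t0.1\t0.01\t100",
               "rs2\tA\tG\tNA\t0.01\t100",
               "rs3\tA\tG\t0.3\t0.02\t100",
               "rs4\tA\tG\t0.2\t0.01\t100",
               "rs5\tA\tG\t0.15\t0.03\t100"), path)
  expect_message(x <- read_marginal_summary(path), "dropped 1")
  expect_equal(nrow(x), 4L)
  expect_false("rs2" %in% x$snp)

  # a missing required column is a hard error naming it
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SNP,A1,A2,BETA,N", "rs1,A,G,0.1,100"), path2)
  expect_error(read_marginal_summary(path2), "SE")
})

test_that("harmonize restricts to the intersection in LD order and flips
           swapped alleles", {
  exposure <- marginal_summary(paste0("rs", 1:5), rep("A", 5), rep("G", 5),
                               beta = seq(0.1, 0.5, by = 0.1),
                               se = rep(0.01, 5), n = 1000,
                               freq = rep(0.3, 5))
  outcome <- marginal_summary(c("rs4", "rs2", "rs3"),
                              c("A", "G", "A"), c("G", "A", "G"),
                              beta = c(0.04, 0.02, 0.03),
                              se = rep(0.02, 3), n = 2000,
                              freq = c(0.3, 0.7, 0.3))
  ld <- ld_diag_from_freq(rep(0.3, 5), paste0("rs", 1:5))
  pair <- harmonize(exposure, outcome, ld)
  # intersection {rs2, rs3, rs4}, ordered as in the LD reference
  expect_identical(pair$exposure$snp, c("rs2", "rs3", "rs4"))
  # rs2 had A1/A2 swapped on the outcome side: beta negated, freq mirrored
  expect_equal(pair$outcome$beta, c(-0.02, 0.03, 0.04))
  expect_equal(pair$outcome$freq, c(0.3, 0.3, 0.3))
  expect_false(any(pair$flip_mask))

  # identical inputs pass through unchanged
  pair2 <- harmonize(exposure, exposure, ld)
  expect_equal(pair2$outcome$beta, exposure$beta)

  # empty intersection is a hard error
  out2 <- outcome
  out2$snp <- paste0("rs", 11:13)
  expect_error(harmonize(exposure, out2, ld), "no SNPs")
})

test_that("unresolvable and strand-ambiguous alleles are dropped with
           a warning", {
  exposure <- marginal_summary(c("rs1", "rs2"), c("A", "A"), c("G", "T"),
                               beta = c(0.1, 0.2), se = c(0.01, 0.01),
                               n = 1000, freq = c(0.3, 0.3))
  # rs1 alleles match neither orientation; rs2 is A/T with swapped coding
  outcome <- marginal_summary(c("rs1", "rs2"), c("C", "T"), c("G", "A"),
                              beta = c(0.05, 0.02), se = c(0.02, 0.02),
                              n = 500, freq = c(0.4, 0.6))
  ld <- ld_diag_from_freq(c(0.3, 0.3), c("rs1", "rs2"))
  expect_error(expect_warning(harmonize(exposure, outcome, ld), "dropped 2"),
               "no SNPs left")
})

test_that("egger_orient flips signs consistently and is an involution", {
  set.seed(7)
  p <- 4
  snp <- paste0("rs", 1:p)
  R <- 0.5^abs(outer(1:p, 1:p, "-"))
  exposure <- marginal_summary(snp, rep("A", p), rep("G", p),
                               beta = c(0.2, -0.1, 0.3, -0.25),
                               se = rep(0.02, p), n = 1000,
                               freq = rep(0.3, p))
  outcome <- marginal_summary(snp, rep("A", p), rep("G", p),
                              beta = c(0.02, 0.01, -0.03, 0.02),
                              se = rep(0.02, p), n = 1000,
                              freq = rep(0.3, p))
  pair <- harmonize(exposure, outcome, ld_reference(R, snp, rep(0.3, p)))
  orient <- egger_orient(pair)
  expect_true(all(orient$exposure$beta > 0))
  expect_identical(orient$flip_mask, c(FALSE, TRUE, FALSE, TRUE))

  # oracle: flipped correlation is the sign-diagonal conjugation D R D
  s <- ifelse(pair$exposure$beta < 0, -1, 1)
  expect_equal(orient$ld$corr, diag(s) %*% R %*% diag(s),
               ignore_attr = TRUE)
  expect_equal(orient$ld$corr, t(orient$ld$corr))
  expect_equal(diag(orient$ld$corr), rep(1, p), ignore_attr = TRUE)
  expect_true(min(eigen(orient$ld$corr, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-8)

  # orientation is idempotent: an already-oriented pair is untouched
  twice <- egger_orient(orient)
  expect_identical(twice, orient)
  # and manually undoing the flips restores the original pair
  undone <- orient
  s2 <- ifelse(orient$flip_mask, -1, 1)
  undone$exposure$beta <- s2 * orient$exposure$beta
  expect_equal(undone$exposure$beta, pair$exposure$beta)

  # exact zero: warned and left unflipped
  pair0 <- pair
  pair0$exposure$beta[1] <- 0
  expect_warning(o0 <- egger_orient(pair0), "rs1")
  expect_false(o0$flip_mask[1])
})

test_that("harmonize is idempotent", {
  pair <- make_pair(p = 6, seed = 3)
  again <- harmonize(pair$exposure, pair$outcome, pair$ld)
  expect_equal(again$exposure$beta, pair$exposure$beta)
  expect_equal(again$outcome$beta, pair$outcome$beta)
  expect_identical(again$flip_mask, pair$flip_mask)
})

test_that("ld constructors validate and compute panel moments", {
  expect_error(ld_reference(matrix(c(1, 0.5, 0.4, 1), 2, 2),
                            c("a", "b"), c(0.3, 0.3)), "symmetric")
  expect_error(ld_reference(matrix(c(1, 2, 2, 1), 2, 2),
                            c("a", "b"), c(0.3, 0.3)), "semi-definite")
  set.seed(11)
  geno <- gen_genotypes(400, 3, maf = 0.25, rho = 0)
  colnames(geno) <- c("a", "b", "c")
  ld <- ld_from_panel(geno)
  expect_equal(ld$corr, cor(geno), ignore_attr = TRUE)
  expect_equal(ld$freq, colMeans(geno) / 2, ignore_attr = TRUE)
  expect_equal(ld$n_ref, 400)
})
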