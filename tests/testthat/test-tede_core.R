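# Score-system construction, the score test, and the adaptive SPU test.

exact_moments <- function(G, Y) {
  Gc <- scale(G, scale = FALSE)
  Yc <- Y - mean(Y)
  structure(list(GtG = crossprod(Gc), GtY = drop(crossprod(Gc, Yc)),
                 YtY = sum(Yc^2), n = length(Y)),
            class = "sufficient_moments")
}

test_that("score system reproduces the single-instrument Wald ratio and
           construction identities", {
  pair <- make_pair(p = 4, seed = 71)
  mom <- sufficient_moments(pair)
  # weights concentrated on SNP 1, diagonal G'G: beta_hat is gamma*_1
  sys <- build_score_system(mom, c(1, 0, 0, 0))
  expect_equal(sys$beta_hat, pair$outcome$beta[1], tolerance = 1e-12)
  # last score entry is exactly zero by construction
  expect_identical(sys$U[length(sys$U)], 0)
  expect_true(isSymmetric(sys$I))
  expect_error(build_score_system(mom, rep(0, 4)), "X'X")
})

test_that("summary-level score and information equal individual-level
           likelihood derivatives under exact moments", {
  d <- make_individual(n = 1200, p = 5, rho = 0.4, beta = 0.3, seed = 81)
  omega_hat <- unname(coef(lm(d$X ~ d$G))[-1])
  mom <- exact_moments(d$G, d$Y)
  sys <- build_score_system(mom, omega_hat)

  # direct individual-level computation of the same quantities
  Gc <- scale(d$G, scale = FALSE)
  Yc <- d$Y - mean(d$Y)
  Xhat <- drop(Gc %*% omega_hat)
  beta_hat <- sum(Xhat * Yc) / sum(Xhat^2)
  r <- Yc - beta_hat * Xhat
  sigma2 <- sum(r^2) / (length(Yc) - 1)
  U <- c(drop(crossprod(Gc, r)) / sigma2, 0)
  I <- rbind(cbind(crossprod(Gc), crossprod(Gc, Xhat)),
             c(crossprod(Xhat, Gc), sum(Xhat^2))) / sigma2
  expect_equal(sys$beta_hat, beta_hat, tolerance = 1e-10)
  expect_equal(sys$U, U, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sys$I, I, tolerance = 1e-8, ignore_attr = TRUE)

  # and the score statistic agrees with the explicit projection form
  st <- tede_sc(sys)
  A <- crossprod(Gc)
  stat_direct <- drop(crossprod(crossprod(Gc, r), solve(A, crossprod(Gc, r)))) /
    sigma2
  expect_equal(st$statistic, stat_direct, tolerance = 1e-8)
  expect_identical(st$df, 5L)   # X lies in span(G): one dimension removed
})

test_that("tede_sc handles the zero score and labels corrected systems", {
  pair <- make_pair(p = 4, seed = 91)
  mom <- sufficient_moments(pair)
  sys <- build_score_system(mom, pair$exposure$beta)
  sys0 <- sys
  sys0$U[] <- 0
  r0 <- tede_sc(sys0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_identical(tede_sc(sys)$method, "TEDE-Sc")
  sys2 <- apply_sc2_correction(sys, diag(0.01, 4))
  expect_identical(tede_sc(sys2)$method, "TEDE-Sc2")
})

test_that("the Sc2 correction modifies exactly the direct-effect block", {
  pair <- make_pair(p = 2, seed = 101)
  mom <- sufficient_moments(pair)
  sys <- build_score_system(mom, pair$exposure$beta)
  p <- 2

  # zero covariance: identity transformation
  same <- apply_sc2_correction(sys, matrix(0, p, p))
  expect_equal(same$I, sys$I)

  # beta_hat = 0: the correction vanishes
  sys0 <- sys
  sys0$beta_hat <- 0
  expect_equal(apply_sc2_correction(sys0, diag(0.01, p))$I, sys$I)

  # generic case: matrix arithmetic oracle on the p x p block
  co <- diag(0.01, p)
  got <- apply_sc2_correction(sys, co)
  GtG <- mom$GtG
  want <- GtG / sys$sigma2 +
    sys$beta_hat^2 * (GtG %*% co %*% GtG) / sys$sigma2^2
  expect_equal(got$I[1:p, 1:p], want, ignore_attr = TRUE)
  expect_equal(got$I[p + 1, ], sys$I[p + 1, ])
  expect_true(got$corrected)
  expect_error(apply_sc2_correction(sys, diag(3)), "dimension")
})

test_that("Sc2 statistic never exceeds Sc when beta_hat is nonzero", {
  for (seed in 1:20) {
    d <- make_individual(n = 400, p = 4, rho = 0.3, beta = 0.5, seed = seed)
    omega_hat <- unname(coef(lm(d$X ~ d$G))[-1])
    sys <- build_score_system(exact_moments(d$G, d$Y), omega_hat)
    set.seed(seed)
    A <- matrix(rnorm(16, sd = 0.05), 4, 4)
    co <- crossprod(A)
    sys2 <- apply_sc2_correction(sys, co)
    expect_lte(tede_sc(sys2)$statistic, tede_sc(sys)$statistic + 1e-10)
  }
})

test_that("standardized scores reproduce the score statistic exactly", {
  # the quadratic form identity Z' Sigma^+ Z = U' I^+ U holds on random PSD
  # systems whose score lies in the attainable space (the causal-effect
  # normal equation makes the score orthogonal to the weight direction)
  for (seed in 1:100) {
    set.seed(seed)
    p <- sample(2:6, 1)
    G <- matrix(rnorm(50 * p), 50, p)
    omega <- runif(p, 0.5, 1.5)
    A <- crossprod(G)
    v <- rnorm(p)
    w <- v - omega * sum(omega * (A %*% v)) / sum(omega * (A %*% omega))
    u <- drop(A %*% w)               # satisfies omega' u = 0
    sys <- structure(list(
      U = c(u, 0),
      I = rbind(cbind(A, A %*% omega),
                c(crossprod(omega, A), crossprod(omega, A %*% omega))),
      beta_hat = 0.2, sigma2 = 1, n = 50, corrected = FALSE),
      class = "score_system")
    std <- standardize_scores(sys)
    q1 <- drop(crossprod(std$Z, MASS::ginv(std$Sigma) %*% std$Z))
    q2 <- tede_sc(sys)$statistic
    expect_equal(q1, q2, tolerance = 1e-8)
  }
})

test_that("standardization normalizes the diagonal", {
  pair <- make_pair(p = 5, seed = 111)
  sys <- build_score_system(sufficient_moments(pair), pair$exposure$beta)
  std <- standardize_scores(sys)
  expect_equal(diag(std$Sigma), rep(1, 6), ignore_attr = TRUE)
  # diagonal information: Sigma is the identity on the direct-effect block
  expect_true(all(abs(std$Sigma[1:5, 1:5] - diag(5)) < 1e-12))
  expect_equal(std$Z[1:5], sys$U[1:5] / sqrt(diag(sys$I)[1:5]),
               ignore_attr = TRUE)
})

test_that("SPU statistics follow their definition", {
  expect_equal(spu_statistic(c(1, -1), 1), 0)
  expect_equal(spu_statistic(c(1, -1), 2), 2)
  expect_equal(spu_statistic(c(3, -4), Inf), 4)
  expect_equal(spu_statistic(c(0.5, 2, -1.5), 3), 0.5^3 + 8 - 1.5^3)
})

test_that("spu_config validates its inputs", {
  expect_error(spu_config(B = 10), "B >= 100")
  expect_error(spu_config(gammas = c(1, Inf, 2)), "final")
  cfg <- spu_config()
  expect_identical(cfg$gammas, c(1:8, Inf))
  expect_identical(cfg$B, 1000L)
})

test_that("aSPU returns p ~ 1 for a null score and respects the p-value
           floor", {
  pair <- make_pair(p = 4, seed = 121)
  sys <- build_score_system(sufficient_moments(pair), pair$exposure$beta)
  sys$U[] <- 0
  r <- tede_aspu(sys, spu_config(B = 200, seed = 1))
  expect_true(all(r$extras$p_spu > 0.9))
  expect_gte(r$p_value, 0.9)

  # a huge score hits the floor: 0 without correction, 1/(B+1) with it
  sys$U[1] <- 1e4
  r2 <- tede_aspu(sys, spu_config(B = 200, seed = 1))
  expect_equal(r2$p_value, 0)
  r3 <- tede_aspu(sys, spu_config(B = 200, seed = 1,
                                  p_floor_correction = TRUE))
  expect_equal(r3$p_value, 1 / 201)
})

test_that("aSPU is reproducible from its seed and B only sharpens
           resolution", {
  pair <- make_pair(p = 5, seed = 131)
  sys <- build_score_system(sufficient_moments(pair), pair$exposure$beta)
  a <- tede_aspu(sys, spu_config(B = 300, seed = 9))
  b <- tede_aspu(sys, spu_config(B = 300, seed = 9))
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$extras$p_spu, b$extras$p_spu)
  # the observed SPU statistics do not depend on B
  expect_identical(a$statistic >= 0, TRUE)
})

test_that("single-score SPU(2) p-value matches the chi-squared oracle", {
  # p = 1: the standardized score is a single z; SPU(2) = z^2 (plus the
  # structurally zero causal coordinate), so its Monte-Carlo p-value must
  # match the chi-squared(1) tail within Monte-Carlo error
  pair <- make_pair(p = 1, seed = 141)
  mom <- sufficient_moments(pair)
  sys <- build_score_system(mom, 1)
  # with p = 1 the score is fully absorbed by beta_hat; set a synthetic
  # system instead: one free score with unit information
  sys$U <- c(1.7, 0)
  sys$I <- diag(c(1, 1))
  r <- tede_aspu(sys, spu_config(B = 1e5, seed = 3),
                 null_cov = "information")
  p_spu2 <- r$extras$p_spu[["SPU(2)"]]
  # draws have two free coordinates here; SPU(2) null is chi-squared(2)
  expect_equal(p_spu2, pchisq(1.7^2, df = 2, lower.tail = FALSE),
               tolerance = 0.02)
})

test_that("null draws from the projected score covariance calibrate the
           test where information draws are conservative", {
  # under LD the projected (Schur-complement) covariance is the true null
  # law of the score; empirical rejection at 0.05 should be near nominal
  set.seed(151)
  p <- 8
  R <- 0.5^abs(outer(1:p, 1:p, "-"))
  ch <- chol(R)
  omega <- runif(p, 0.5, 1.5)
  n <- 300
  rej_score <- 0
  nrep <- 200
  for (i in seq_len(nrep)) {
    G <- matrix(rnorm(n * p), n, p) %*% ch
    Y <- rnorm(n)
    sys <- build_score_system(exact_moments(G, Y), omega)
    rej_score <- rej_score +
      (tede_aspu(sys, spu_config(B = 300))$p_value < 0.05)
  }
  rate <- rej_score / nrep
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})
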