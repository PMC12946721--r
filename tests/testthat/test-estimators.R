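# Univariable estimators and sensitivity statistics.

test_that("wald_ratio: point estimate, delta SEs, null case", {
  w <- wald_ratio(0.10, 0.02, 0.02, 0.01)
  expect_equal(w$beta, 0.2)
  expect_equal(w$se, 0.1)
  null <- wald_ratio(0.10, 0.02, 0, 0.01)
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)
  expect_error(wald_ratio(0, 0.02, 0.1, 0.01),
               class = "mrm_degenerate_instrument_error")
  # second-order SE exceeds first-order by exactly the documented term
  w1 <- wald_ratio(0.1, 0.05, 0.02, 0.01)
  w2 <- wald_ratio(0.1, 0.05, 0.02, 0.01, second_order = TRUE)
  expect_equal(w2$se^2 - w1$se^2, 0.02^2 * 0.05^2 / 0.1^4)
})

test_that("ivw reduces to the Wald ratio for one SNP and averages ratios", {
  hs1 <- make_hset(0.1, 0.01, 0.05, 0.01)
  expect_equal(mr_ivw(hs1)$beta, wald_ratio(0.1, 0.01, 0.05, 0.01)$beta)
  expect_identical(mr_ivw(hs1)$method, "wald_ratio")
  # equal exposure betas and outcome SEs -> equal weights -> mean of ratios
  hs3 <- make_hset(rep(0.1, 3), rep(0.01, 3),
                   c(0.01, 0.02, 0.03), rep(0.01, 3))
  expect_equal(mr_ivw(hs3)$beta, 0.2)
})

test_that("ivw matches the weighted-least-squares oracle on unequal weights", {
  hs <- make_hset(beta_exp = c(0.08, 0.12, 0.05, 0.20, 0.10),
                  se_exp = c(0.01, 0.02, 0.01, 0.03, 0.01),
                  beta_out = c(0.015, 0.030, 0.008, 0.045, 0.022),
                  se_out = c(0.004, 0.010, 0.003, 0.012, 0.006))
  fit <- lm_wls(hs$data$beta_out, hs$data$beta_exp, 1 / hs$data$se_out^2)
  est <- mr_ivw(hs, mode = "fixed")
  expect_equal(est$beta, unname(coef(fit)[1]), tolerance = 1e-12)
  # fixed-effect SE from the normal equations
  expect_equal(est$se, sqrt(1 / sum(hs$data$beta_exp^2 / hs$data$se_out^2)),
               tolerance = 1e-12)
})

test_that("ivw fixed beta is scale-invariant in se_out; SE scales linearly", {
  hs <- make_hset(beta_exp = c(0.1, 0.2, 0.15), se_exp = rep(0.01, 3),
                  beta_out = c(0.02, 0.05, 0.03), se_out = c(0.01, 0.02, 0.01))
  a <- mr_ivw(hs, mode = "fixed")
  hs2 <- hs
  hs2$data$se_out <- hs$data$se_out * 3
  b <- mr_ivw(hs2, mode = "fixed")
  expect_equal(b$beta, a$beta, tolerance = 1e-14)
  expect_equal(b$se, 3 * a$se, tolerance = 1e-14)
})

test_that("every estimator reports a log-symmetric OR interval", {
  hs <- make_hset(beta_exp = c(0.1, 0.2, 0.15, 0.08), se_exp = rep(0.01, 4),
                  beta_out = c(0.02, 0.05, 0.03, 0.01),
                  se_out = c(0.01, 0.02, 0.01, 0.01))
  for (est in list(mr_ivw(hs), mr_egger(hs),
                   wald_ratio(0.1, 0.01, 0.03, 0.01))) {
    expect_identical(est$or, exp(est$beta))
    expect_identical(est$or_low, exp(est$ci_low))
    expect_equal(est$or, sqrt(est$or_low * est$or_high), tolerance = 1e-12)
    expect_true(est$ci_low <= est$beta && est$beta <= est$ci_high)
  }
})

test_that("egger matches the with-intercept WLS oracle and detects pleiotropy", {
  set.seed(9)
  bx <- seq(0.04, 0.30, length.out = 20)  # wide spread identifies the intercept
  se_out <- runif(20, 0.002, 0.004)
  by <- 0.05 + 0.2 * bx + rnorm(20) * se_out  # directional pleiotropy 0.05
  hs <- make_hset(bx, rep(0.005, 20), by, se_out)
  est <- mr_egger(hs)
  fit <- lm_wls(by, bx, 1 / se_out^2, intercept = TRUE)
  expect_equal(est$beta, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(est$egger_intercept, unname(coef(fit)[1]), tolerance = 1e-12)
  expect_equal(est$egger_intercept, 0.05, tolerance = 0.02)
  expect_lt(est$egger_intercept_p, 0.05)
  # slope recovered despite pleiotropy the plain IVW absorbs
  expect_equal(est$beta, 0.2, tolerance = 0.05)
})

test_that("egger interpolates 3 collinear points exactly and equals ivw at zero intercept", {
  bx <- c(0.05, 0.10, 0.20)
  by <- 0.25 * bx  # exact line through the origin
  hs <- make_hset(bx, rep(0.01, 3), by, rep(0.01, 3))
  egg <- mr_egger(hs)
  expect_equal(egg$beta, 0.25, tolerance = 1e-12)
  expect_equal(egg$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(egg$q, 0, tolerance = 1e-20)
  expect_equal(mr_ivw(hs)$beta, egg$beta, tolerance = 1e-12)
  expect_error(mr_egger(make_hset(c(0.1, 0.2), c(0.01, 0.01),
                                  c(0.02, 0.04), c(0.01, 0.01))),
               class = "mrm_insufficient_instruments_error")
  # sign orientation: flipping an exposure sign leaves the fit unchanged
  hs_flip <- make_hset(c(-0.05, 0.10, 0.20), rep(0.01, 3),
                       c(-0.0125, 0.025, 0.05), rep(0.01, 3))
  expect_equal(mr_egger(hs_flip)$beta, 0.25, tolerance = 1e-12)
})

test_that("cochran_q: hand value, zero-heterogeneity and order invariance", {
  # ratios 0.1 and 0.3, ratio-scale SE 0.1 each, beta_hat = 0.2 -> Q = 2
  hs <- make_hset(c(1, 1), c(0.01, 0.01), c(0.1, 0.3), c(0.1, 0.1))
  beta_hat <- mr_ivw(hs, mode = "fixed")$beta
  expect_equal(beta_hat, 0.2)
  qr <- cochran_q(hs, beta_hat)
  expect_equal(qr$q, 2)
  expect_identical(qr$df, 1L)
  # identical ratios -> Q = 0, p = 1
  hs0 <- make_hset(c(0.1, 0.2), c(0.01, 0.01), c(0.02, 0.04), c(0.01, 0.01))
  q0 <- cochran_q(hs0, 0.2)
  expect_equal(q0$q, 0)
  expect_equal(q0$p, 1)
  # permutation invariance
  hs4 <- make_hset(c(0.1, 0.2, 0.15, 0.3), rep(0.01, 4),
                   c(0.02, 0.05, 0.03, 0.05), rep(0.01, 4))
  q_a <- cochran_q(hs4, 0.2)$q
  perm <- mrmediate:::hset_subset(hs4, c(3, 1, 4, 2))
  expect_equal(cochran_q(perm, 0.2)$q, q_a)
})

test_that("steiger_test orientation and boundary behaviour", {
  hs <- make_hset(c(0.1, 0.12), c(0.01, 0.01), c(0.01, 0.012),
                  c(0.01, 0.01), n_exp = 50000, n_out = 50000)
  st <- steiger_test(hs)
  expect_true(st$direction_ok)
  expect_lt(st$steiger_p, 0.05)
  # equal aggregate r2 -> not ok, p = 1
  hs_eq <- make_hset(c(0.1, 0.12), c(0.01, 0.01), c(0.1, 0.12),
                     c(0.01, 0.01), n_exp = 50000, n_out = 50000)
  st_eq <- steiger_test(hs_eq)
  expect_false(st_eq$direction_ok)
  expect_equal(st_eq$steiger_p, 1)
})

test_that("ivw null calibration over replicates (reduced-n sanity check)", {
  # full 1000-replicate version lives in the acceptance suite
  rej <- vapply(1:150, function(i) {
    tri <- simulate_triplet(sim_config(n_snps = 30, n_snps_med = 0,
                                       theta_direct = 0, alpha = 0, b_med = 0,
                                       seed = 9000 + i))
    mr_ivw(harmonise(tri$exposure, tri$outcome))$pval < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.12)
})

test_that("sensitivity_report aggregates Q, Egger, Steiger and PRESSO", {
  tri <- simulate_triplet(sim_config(n_snps = 15, n_snps_med = 0, seed = 31))
  hs <- harmonise(tri$exposure, tri$outcome)
  rep <- sensitivity_report(hs, presso_global_p = 0.4)
  expect_identical(rep$q_df, n_snp(hs) - 1L)
  expect_true(rep$steiger_direction_ok)
  expect_identical(rep$presso_global_p, 0.4)
  expect_true(all(c("egger_intercept", "egger_intercept_p") %in% names(rep)))
})
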