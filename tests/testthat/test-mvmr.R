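# Multivariable MR: input assembly and weighted least squares.

test_that("build_mvmr_input takes the union, audits missing SNPs, survives flips", {
  tri <- simulate_triplet(sim_config(n_snps = 10, n_snps_med = 10, seed = 55))
  exp_ids <- tri$exposure$data$snp_id[1:10]
  med_ids <- tri$mediator$data$snp_id[11:20]
  inp <- build_mvmr_input(list(tri$exposure, tri$mediator), tri$outcome,
                          instruments = list(exp_ids, med_ids))
  expect_identical(length(inp$snp_ids), 20L)
  expect_identical(dim(inp$beta_X), c(20L, 2L))

  # drop a union SNP from the outcome panel -> removed with audit
  out2 <- tri$outcome
  out2$data <- out2$data[out2$data$snp_id != exp_ids[1], ]
  inp2 <- build_mvmr_input(list(tri$exposure, tri$mediator), out2,
                           instruments = list(exp_ids, med_ids))
  expect_identical(length(inp2$snp_ids), 19L)
  expect_true(exp_ids[1] %in% inp2$audit$snp_id)

  # orientation flips in the mediator panel leave the input unchanged
  med_flip <- tri$mediator
  med_flip$data <- transform(med_flip$data,
    effect_allele = other_allele, other_allele = effect_allele,
    beta = -beta, eaf = 1 - eaf)
  inp3 <- build_mvmr_input(list(tri$exposure, med_flip), tri$outcome,
                           instruments = list(exp_ids, med_ids))
  expect_equal(inp3$beta_X, inp$beta_X)
  expect_equal(inp3$beta_Y, inp$beta_Y)

  expect_error(build_mvmr_input(list(tri$exposure), tri$outcome,
                                instruments = list(exp_ids)),
               class = "mrm_config_error")
})

test_that("mvmr_ivw matches the normal-equations oracle on a 6-SNP fixture", {
  bX <- cbind(c(0.10, 0.08, 0.12, 0.05, 0.15, 0.09),
              c(0.02, 0.11, 0.04, 0.09, 0.01, 0.12))
  se_Y <- c(0.004, 0.006, 0.005, 0.008, 0.004, 0.007)
  bY <- c(0.021, 0.030, 0.026, 0.023, 0.020, 0.034)
  inp <- structure(list(snp_ids = sprintf("s%d", 1:6),
                        beta_X = `colnames<-`(bX, c("e1", "e2")),
                        se_X = bX * 0 + 0.005,
                        beta_Y = bY, se_Y = se_Y,
                        exposure_ids = c("e1", "e2"), outcome_id = "out",
                        audit = NULL), class = "mvmr_input")
  est <- mvmr_ivw(inp)
  fit <- lm_wls(bY, bX, 1 / se_Y^2)
  expect_equal(est$estimates$beta, unname(coef(fit)), tolerance = 1e-10)
  expect_identical(est$estimates$exposure_id, c("e1", "e2"))
  # log-symmetric OR intervals per exposure
  expect_equal(est$estimates$or,
               sqrt(est$estimates$or_low * est$estimates$or_high))
})

test_that("collinear exposures raise an identification error naming them", {
  bX <- cbind(c(0.1, 0.2, 0.05, 0.15), 0.5 * c(0.1, 0.2, 0.05, 0.15))
  inp <- structure(list(snp_ids = sprintf("s%d", 1:4),
                        beta_X = `colnames<-`(bX, c("microbe", "metab")),
                        se_X = bX * 0 + 0.005,
                        beta_Y = c(0.02, 0.04, 0.01, 0.03),
                        se_Y = rep(0.005, 4),
                        exposure_ids = c("microbe", "metab"),
                        outcome_id = "out", audit = NULL),
                   class = "mvmr_input")
  expect_error(mvmr_ivw(inp), "microbe.*metab",
               class = "mrm_identification_error")
})

test_that("with an orthogonal second exposure the first equals univariable IVW", {
  # construct beta_X2 exactly W-orthogonal to beta_X1 and to beta_Y's signal
  bx1 <- c(0.1, 0.2, 0.15, 0.05, 0.25, 0.12)
  se_Y <- rep(0.005, 6)
  w <- 1 / se_Y^2
  raw <- c(1, -1, 2, -2, 1.5, -0.5)
  bx2 <- raw - bx1 * sum(w * raw * bx1) / sum(w * bx1^2)  # orthogonalise
  bY <- 0.3 * bx1
  inp <- structure(list(snp_ids = sprintf("s%d", 1:6),
                        beta_X = cbind(e1 = bx1, e2 = bx2),
                        se_X = cbind(rep(0.005, 6), rep(0.005, 6)),
                        beta_Y = bY, se_Y = se_Y,
                        exposure_ids = c("e1", "e2"), outcome_id = "out",
                        audit = NULL), class = "mvmr_input")
  est <- mvmr_ivw(inp)
  uni <- sum(w * bx1 * bY) / sum(w * bx1^2)
  expect_equal(est$estimates$beta[1], uni, tolerance = 1e-12)
  expect_equal(est$estimates$beta[2], 0, tolerance = 1e-12)
  # column order invariance up to reordering of outputs
  inp_sw <- inp
  inp_sw$beta_X <- inp$beta_X[, 2:1]
  inp_sw$se_X <- inp$se_X[, 2:1]
  inp_sw$exposure_ids <- c("e2", "e1")
  est_sw <- mvmr_ivw(inp_sw)
  expect_equal(est_sw$estimates$beta[match(c("e1", "e2"),
                                           est_sw$estimates$exposure_id)],
               est$estimates$beta, tolerance = 1e-12)
})

test_that("mvmr recovers the generative direct and mediator effects", {
  tri <- simulate_triplet(sim_config(n_snps = 40, n_snps_med = 40,
                                     theta_direct = 0.1, alpha = 0.5,
                                     b_med = 0.2, n_exp = 2e5, n_med = 2e5,
                                     n_out = 2e5, seed = 66))
  ids <- tri$exposure$data$snp_id
  inp <- build_mvmr_input(list(tri$exposure, tri$mediator), tri$outcome,
                          instruments = list(ids[1:40], ids[41:80]))
  est <- mvmr_ivw(inp)$estimates
  expect_lt(abs(est$beta[est$exposure_id == "exposure"] - 0.1), 0.03)
  expect_lt(abs(est$beta[est$exposure_id == "mediator"] - 0.2), 0.03)
})
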