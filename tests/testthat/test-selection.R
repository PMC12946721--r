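# Instrument selection: thresholding, clumping, filters, full pipeline.

test_that("threshold_instruments applies the genome-wide / fallback rule", {
  p <- make_panel(beta = rep(0.1, 12), se = rep(0.01, 12),
                  pval = c(rep(1e-9, 6), rep(0.5, 6)))
  th <- threshold_instruments(p, selection_params())
  expect_identical(nrow(th$data), 6L)
  expect_identical(attr(th, "threshold_used"), 5e-8)

  # 3 below 5e-8 but 12 below 5e-5 -> fallback branch
  p2 <- make_panel(beta = rep(0.1, 14), se = rep(0.01, 14),
                   pval = c(rep(1e-9, 3), rep(1e-6, 9), rep(0.5, 2)))
  th2 <- threshold_instruments(p2, selection_params())
  expect_identical(nrow(th2$data), 12L)
  expect_identical(attr(th2, "threshold_used"), 5e-5)

  p3 <- make_panel(beta = rep(0.1, 3), se = rep(0.01, 3), pval = rep(0.5, 3))
  expect_error(threshold_instruments(p3), class = "mrm_no_instrument_error")
})

test_that("clump keeps the best SNP per correlated window (greedy oracle)", {
  # two SNPs 100 kb apart, r2 = 0.5: only the smaller p survives
  p <- make_panel(beta = c(0.1, 0.1), se = c(0.01, 0.01),
                  pos = c(100000L, 200000L), pval = c(1e-10, 1e-9))
  ld <- block_ld_matrix(p$data$snp_id, block_size = 2, r2 = 0.5)
  cl <- clump(p, ld, window_kb = 500, r2_max = 0.01)
  expect_identical(cl$data$snp_id, "snp001")
  # independent SNPs: all retained; r2_max = 1 never exceeded
  ld0 <- block_ld_matrix(p$data$snp_id, block_size = 1, r2 = 0)
  expect_identical(nrow(clump(p, ld0, 500, 0.01)$data), 2L)
  expect_identical(nrow(clump(p, ld, 500, 1.0)$data), 2L)
  # missing LD entry errors
  p_extra <- make_panel(beta = c(0.1, 0.1, 0.1), se = rep(0.01, 3))
  expect_error(clump(p_extra, ld, 500, 0.01), class = "mrm_missing_ld_error")
})

test_that("clump matches a brute-force oracle and ignores input row order", {
  set.seed(42)
  m <- 24
  tri <- simulate_triplet(sim_config(n_snps = m, n_snps_med = 0,
                                     ld_block_size = 4, ld_r2 = 0.6,
                                     seed = 808))
  panel <- tri$exposure
  greedy_oracle <- function(d, R, window, r2max) {
    ord <- order(d$pval, d$snp_id)
    alive <- rep(TRUE, nrow(d)); keep <- character(0)
    for (i in ord) {
      if (!alive[i]) next
      keep <- c(keep, d$snp_id[i]); alive[i] <- FALSE
      for (j in which(alive)) {
        if (d$chrom[j] == d$chrom[i] &&
            abs(d$pos[j] - d$pos[i]) <= window * 1000 &&
            R[d$snp_id[i], d$snp_id[j]] > r2max) alive[j] <- FALSE
      }
    }
    keep
  }
  expected <- greedy_oracle(panel$data, tri$ld$r2, 500, 0.01)
  got <- clump(panel, tri$ld, 500, 0.01)$data$snp_id
  expect_setequal(got, expected)
  # shuffled rows give the same retained set, in original panel order
  shuffled <- panel
  shuffled$data <- panel$data[sample(m), ]
  rownames(shuffled$data) <- NULL
  got2 <- clump(shuffled, tri$ld, 500, 0.01)$data$snp_id
  expect_setequal(got2, got)
  # one SNP per block at most when within-block r2 exceeds the ceiling
  block <- ceiling(match(got, panel$data$snp_id) / 4)
  expect_identical(anyDuplicated(block), 0L)
})

test_that("outcome-association filter removes p <= 0.05, keeps missing SNPs", {
  cand <- make_panel(beta = rep(0.1, 3), se = rep(0.01, 3))
  outc <- make_panel("out", "binary", beta = c(0.05, 0.001),
                     se = c(0.019, 0.02),
                     snp_id = c("snp001", "snp002"))
  # snp001 outcome p ~ 0.0085 -> removed; snp002 p ~ 0.96 -> kept;
  # snp003 absent -> kept (deferred drop)
  kept <- filter_outcome_association(cand, outc, 0.05)$data$snp_id
  expect_identical(kept, c("snp002", "snp003"))
  expect_identical(nrow(filter_outcome_association(cand, outc, 0)$data), 3L)
})

test_that("f_statistic and snp_r2 follow their closed forms", {
  expect_equal(f_statistic(0.10, 0.02), 25)
  expect_equal(f_statistic(0, 0.3), 0)
  expect_equal(snp_r2(0.1, 0.02, 10000), 25 / (25 + 9998))
  expect_equal(snp_r2(0, 0.02, 100), 0)
  # strictly below 1 for any finite t
  expect_true(all(snp_r2(c(5, 50, 500), 0.01, 50) < 1))
  # F = 9 sits below the conventional cutoff of 10
  expect_lt(f_statistic(0.03, 0.01), 10)
})

test_that("steiger_filter removes only strictly reversed SNPs", {
  hs <- make_hset(beta_exp = c(0.10, 0.02, 0.05),
                  se_exp = c(0.01, 0.01, 0.01),
                  beta_out = c(0.01, 0.10, 0.05),
                  se_out = c(0.01, 0.01, 0.01))
  st <- steiger_filter(hs)
  # snp2: outcome r2 exceeds exposure r2 -> removed; snp3 tie -> retained
  expect_identical(st$removed, "snp002")
  expect_setequal(st$hset$data$snp_id, c("snp001", "snp003"))
})

test_that("select_instruments composes the pipeline with a complete audit", {
  tri <- simulate_triplet(sim_config(n_snps = 40, n_snps_med = 0, seed = 4242))
  iset <- select_instruments(tri$exposure, tri$outcome, tri$ld,
                             selection_profile("mediation"),
                             presso_nsim = 500, seed = 1)
  hs <- iset$harmonised
  # accounting identity: input = retained + audited
  expect_identical(iset$n_input, n_snp(hs) + nrow(iset$audit))
  expect_identical(anyDuplicated(iset$audit$snp_id), 0L)
  expect_true(all(hs$data$f_stat > 10))
  # clean triplet: no PRESSO removals
  expect_false(any(iset$audit$stage_removed == "presso"))
  # an injected large pleiotropic outlier is pruned by the PRESSO stage
  out2 <- tri$outcome
  victim <- hs$data$snp_id[1]
  k <- match(victim, out2$data$snp_id)
  out2$data$beta[k] <- out2$data$beta[k] + 1.0
  out2$data$pval[k] <- 2 * pnorm(-abs(out2$data$beta[k] / out2$data$se[k]))
  out2$data$pval[k] <- max(out2$data$pval[k], .Machine$double.xmin)
  iset2 <- select_instruments(tri$exposure, out2, tri$ld,
                              selection_profile("mediation"),
                              presso_nsim = 1000, seed = 2)
  aud <- iset2$audit
  expect_true(any(aud$snp_id == victim &
                    aud$stage_removed %in% c("presso", "steiger")))
})

test_that("steiger_filter flag off still reports r2 columns", {
  tri <- simulate_triplet(sim_config(n_snps = 20, n_snps_med = 0, seed = 11))
  iset <- select_instruments(tri$exposure, tri$outcome, tri$ld,
                             selection_profile("mediation",
                                               steiger_filter = FALSE),
                             presso_nsim = 0)
  expect_true(all(c("r2_exp", "r2_out") %in% names(iset$harmonised$data)))
  expect_false(any(iset$audit$stage_removed == "steiger"))
})

test_that("named profiles carry the documented presets", {
  bc <- selection_profile("bloodcell")
  expect_identical(bc$clump_window_kb, 10000L)
  expect_identical(bc$clump_r2, 0.001)
  rv <- selection_profile("reverse_mr")
  expect_identical(rv$p_primary, 1e-8)
  expect_identical(rv$clump_window_kb, 10000L)
  expect_identical(rv$clump_r2, 0.001)
  expect_identical(rv$f_min, 10)
  md <- selection_profile("mediation")
  expect_identical(md$p_outcome_min, 0)
  expect_error(selection_params(p_primary = 1e-4, p_fallback = 1e-8),
               class = "mrm_config_error")
})
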