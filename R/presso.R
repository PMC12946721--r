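#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Parametric-resampling detection of horizontal pleiotropy.  The observed
#' residual sum of squares uses leave-one-out IVW fits: for SNP j the
#' expected outcome effect is `beta_loo_j * beta_exp_j` where `beta_loo_j` is
#' the IVW slope fitted without SNP j, and
#' `RSS_obs = sum_j (beta_out_j - beta_loo_j * beta_exp_j)^2 / se_out_j^2`.
#' Each of `n_sim` replicates draws `beta_exp* ~ N(beta_exp, se_exp^2)` and
#' `beta_out*_j ~ N(beta_loo_j * beta_exp_j, se_out_j^2)` and recomputes the
#' statistic identically (including its own leave-one-out fits).  The global
#' p-value uses the add-one correction `(1 + #{RSS* >= RSS_obs})/(n_sim+1)`,
#' so it is never exactly zero and has resolution `1/(n_sim+1)`.  Per-SNP
#' outlier p-values compare each observed residual term with its simulated
#' distribution and are Bonferroni-multiplied by the number of SNPs
#' (`outlier_bonferroni = FALSE` switches to Benjamini-Hochberg).  When
#' outliers are flagged, the distortion test compares the change in the IVW
#' estimate after removing them against removal of random SNP subsets of the
#' same size.
#'
#' @param hset A `harmonised_set` with at least 4 SNPs.
#' @param n_sim Number of parametric resamples (>= 1000 recommended).
#' @param outlier_alpha Significance level for adjusted outlier p-values.
#' @param seed Integer seed; results are deterministic given it.
#' @param outlier_bonferroni Bonferroni-adjust outlier p-values (default);
#'   otherwise BH.
#' @return A `presso_result`: `global_rss`, `global_p`, `n_sim`, `outlier_p`
#'   (adjusted, named by SNP), `outliers`, `distortion_p`, `beta_raw`,
#'   `beta_corrected` (IVW on the pruned set, present iff outliers were
#'   found), `seed`.
#' @export
mr_presso <- function(hset, n_sim = 5000L, outlier_alpha = 0.05,
                      seed = NULL, outlier_bonferroni = TRUE) {
  d <- hset$data
  n <- nrow(d)
  if (n < 4L)
    stop_mrm("mrm_insufficient_instruments_error",
             "MR-PRESSO needs at least 4 instruments")
  n_sim <- as.integer(n_sim)
  bx <- d$beta_exp; sx <- d$se_exp
  by <- d$beta_out; sy <- d$se_out
  w <- 1 / sy^2

  loo_terms <- function(bx, by) {
    # rows = replicates (matrices) or a single vector
    if (is.matrix(bx)) {
      sxx <- (bx^2) %*% w
      sxy <- (bx * by) %*% w
      beta_loo <- (sweep(bx * by, 2L, w, "*") * -1 + c(sxy)) /
        (sweep(bx^2, 2L, w, "*") * -1 + c(sxx))
      sweep((by - beta_loo * bx)^2, 2L, w, "*")
    } else {
      sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
      beta_loo <- (sxy - w * bx * by) / (sxx - w * bx^2)
      w * (by - beta_loo * bx)^2
    }
  }

  obs_term <- loo_terms(bx, by)
  rss_obs <- sum(obs_term)
  sxx <- sum(w * bx^2)
  beta_loo <- (sum(w * bx * by) - w * bx * by) / (sxx - w * bx^2)
  mu_y <- beta_loo * bx

  with_seed(seed, {
    BX <- matrix(stats::rnorm(n_sim * n), n_sim, n)
    BX <- sweep(sweep(BX, 2L, sx, "*"), 2L, bx, "+")
    BY <- matrix(stats::rnorm(n_sim * n), n_sim, n)
    BY <- sweep(sweep(BY, 2L, sy, "*"), 2L, mu_y, "+")
    sim_term <- loo_terms(BX, BY)
    rss_sim <- rowSums(sim_term)

    global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    outlier_raw <- (1 + colSums(sim_term >= rep(obs_term, each = n_sim))) /
      (n_sim + 1)
    outlier_p <- if (outlier_bonferroni) pmin(1, outlier_raw * n)
    else stats::p.adjust(outlier_raw, method = "BH")
    names(outlier_p) <- d$snp_id
    outliers <- d$snp_id[outlier_p < outlier_alpha]

    ivw_beta <- function(keep) {
      sum(w[keep] * bx[keep] * by[keep]) / sum(w[keep] * bx[keep]^2)
    }
    beta_raw <- ivw_beta(seq_len(n))
    beta_corrected <- NULL
    distortion_p <- NA_real_
    if (length(outliers) > 0L && length(outliers) < n) {
      keep <- !(d$snp_id %in% outliers)
      beta_corrected <- mr_ivw(hset_subset(hset, keep))$beta
      d_obs <- beta_raw - beta_corrected
      k_rem <- sum(!keep)
      n_draw <- min(n_sim, 1000L)
      d_rand <- replicate(n_draw, {
        drop <- sample.int(n, k_rem)
        beta_raw - ivw_beta(setdiff(seq_len(n), drop))
      })
      distortion_p <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (n_draw + 1)
    }

    structure(list(global_rss = rss_obs, global_p = global_p, n_sim = n_sim,
                   outlier_p = outlier_p, outliers = outliers,
                   distortion_p = distortion_p, beta_raw = beta_raw,
                   beta_corrected = beta_corrected, seed = seed),
              class = "presso_result")
  })
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> RSS = %.4g, global p = %.4g (%d sims), %d outlier(s)\n",
              x$global_rss, x$global_p, x$n_sim, length(x$outliers)))
  if (length(x$outliers))
    cat("  outliers:", paste(x$outliers, collapse = ", "),
        sprintf("; distortion p = %.3g\n", x$distortion_p))
  invisible(x)
}
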