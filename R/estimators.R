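#' Construct an MR estimate
#'
#' Internal constructor shared by all estimators.  Confidence intervals use
#' the fixed normal quantile 1.959964 (weights treated as known), odds ratios
#' are `exp(beta)`, and the reported OR is therefore exactly the geometric
#' mean of its CI bounds (log-symmetric interval).
#' @noRd
mr_estimate <- function(method, beta, se, n_snp, q = NA_real_,
                        q_df = NA_integer_, q_pval = NA_real_,
                        egger_intercept = NA_real_,
                        egger_intercept_se = NA_real_,
                        egger_intercept_p = NA_real_) {
  z975 <- 1.959964
  ci_low <- beta - z975 * se
  ci_high <- beta + z975 * se
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high,
    or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
    pval = z_to_p(beta / se), n_snp = as.integer(n_snp),
    q = q, q_df = q_df, q_pval = q_pval,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = egger_intercept_p
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta = %.4g (se %.4g), OR = %.4g [%.4g, %.4g], p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$se, x$or, x$or_low, x$or_high, x$pval, x$n_snp))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  intercept = %.4g (p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_p))
  invisible(x)
}

#' Wald ratio for a single instrument
#'
#' Causal estimate `beta_out / beta_exp`.  The default standard error is the
#' first-order delta approximation `se_out / |beta_exp|`; `second_order =
#' TRUE` adds the exposure-uncertainty term
#' `sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`.
#'
#' @param beta_exp,se_exp Exposure effect and its SE.
#' @param beta_out,se_out Outcome effect and its SE.
#' @param second_order Use the second-order delta SE.
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       second_order = FALSE) {
  if (beta_exp == 0)
    stop_mrm("mrm_degenerate_instrument_error",
             "wald_ratio undefined for beta_exp = 0")
  beta <- beta_out / beta_exp
  se <- if (second_order)
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  else se_out / abs(beta_exp)
  mr_estimate("wald_ratio", beta, se, 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_out^2`; equivalently the inverse-variance
#' weighted meta-analysis of per-SNP Wald ratios.  `mode = "fixed"` reports
#' the fixed-effect SE; `"mre"` (multiplicative random effects) scales it by
#' `max(1, sqrt(Q/(n-1)))`; `"auto"` applies the same scaling only when
#' `Q/(n-1) > 1`, which is numerically identical to `"mre"` and is the
#' default.  A single SNP delegates to [wald_ratio()].
#'
#' @param hset A `harmonised_set` (see [harmonise()]).
#' @param mode `"auto"`, `"fixed"` or `"mre"`.
#' @return An `mr_estimate` carrying Cochran's Q, its df and p-value.
#' @export
mr_ivw <- function(hset, mode = c("auto", "fixed", "mre")) {
  mode <- match.arg(mode)
  d <- hset$data
  n <- nrow(d)
  if (n == 0L) stop_mrm("mrm_no_instrument_error", "no instruments")
  if (n == 1L)
    return(wald_ratio(d$beta_exp, d$se_exp, d$beta_out, d$se_out))
  w <- 1 / d$se_out^2
  sxx <- sum(w * d$beta_exp^2)
  beta <- sum(w * d$beta_exp * d$beta_out) / sxx
  se_fixed <- sqrt(1 / sxx)
  qres <- cochran_q(hset, beta)
  phi <- switch(mode,
                fixed = 1,
                mre = max(1, sqrt(qres$q / qres$df)),
                auto = if (qres$q / qres$df > 1) sqrt(qres$q / qres$df) else 1)
  mr_estimate(paste0("ivw_", if (mode == "auto") "mre" else mode),
              beta, se_fixed * phi, n,
              q = qres$q, q_df = qres$df, q_pval = qres$p)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an intercept
#' (weights `1/se_out^2`).  Exposure effects are sign-oriented to be
#' non-negative before fitting (InSIDE convention).  The slope is the causal
#' estimate; a non-zero intercept indicates directional pleiotropy.  SEs are
#' scaled by the multiplicative overdispersion factor
#' `max(1, sqrt(Q_egger/(n-2)))`.
#'
#' @param hset A `harmonised_set`; needs at least 3 SNPs.
#' @return An `mr_estimate` with method `"egger"`, including the intercept,
#'   its SE and p-value.
#' @export
mr_egger <- function(hset) {
  d <- hset$data
  n <- nrow(d)
  if (n < 3L)
    stop_mrm("mrm_insufficient_instruments_error",
             "MR-Egger needs at least 3 instruments")
  s <- ifelse(d$beta_exp < 0, -1, 1)
  bx <- s * d$beta_exp
  by <- s * d$beta_out
  w <- 1 / d$se_out^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, X * w)
  coefs <- solve(XtWX, crossprod(X, by * w))
  resid <- by - X %*% coefs
  q_e <- sum(w * resid^2)
  phi <- max(1, sqrt(q_e / (n - 2)))
  covb <- solve(XtWX) * phi^2
  slope <- coefs[2L]; slope_se <- sqrt(covb[2L, 2L])
  int <- coefs[1L]; int_se <- sqrt(covb[1L, 1L])
  mr_estimate("egger", slope, slope_se, n,
              q = q_e, q_df = n - 2L,
              q_pval = stats::pchisq(q_e, n - 2L, lower.tail = FALSE),
              egger_intercept = int, egger_intercept_se = int_se,
              egger_intercept_p = z_to_p(int / int_se))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (ratio_j - beta_hat)^2` with ratio-scale weights
#' `w_j = (se_out_j / beta_exp_j)^-2`; identical to the weighted residual sum
#' of squares of the origin regression.
#'
#' @param hset A `harmonised_set`.
#' @param beta_hat Pooled causal estimate the ratios are compared against.
#' @return List with `q`, `df = n - 1` and the chi-square upper-tail `p`.
#' @export
cochran_q <- function(hset, beta_hat) {
  d <- hset$data
  n <- nrow(d)
  if (n < 2L) stop_mrm("mrm_insufficient_instruments_error",
                       "Cochran's Q needs at least 2 instruments")
  w <- (d$beta_exp / d$se_out)^2
  ratio <- d$beta_out / d$beta_exp
  q <- sum(w * (ratio - beta_hat)^2)
  df <- n - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Per-SNP variance explained
#'
#' Scale-free form `t^2 / (t^2 + n - 2)` with `t = beta/se`; strictly below 1
#' for finite t.
#'
#' @param beta,se,n Effect, standard error, sample size (vectors).
#' @return Proportion of trait variance explained per SNP.
#' @export
snp_r2 <- function(beta, se, n) {
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Per-SNP instrument-strength F statistic
#'
#' Single-SNP approximation `F = (beta/se)^2` (the squared Wald z); F > 10 is
#' the conventional weak-instrument cutoff.
#'
#' @param beta,se Effect and standard error (vectors).
#' @return F statistics.
#' @export
f_statistic <- function(beta, se) (beta / se)^2

#' Steiger directionality test for an instrument set
#'
#' Compares the aggregate variance explained in the exposure versus the
#' outcome.  `direction_ok` is `TRUE` when the instruments explain strictly
#' more exposure than outcome variance; the p-value compares the Fisher
#' z-transformed aggregate correlations `sqrt(sum r2)` with effective sample
#' sizes (two-sided), so equal sums give p = 1.
#'
#' @param hset A `harmonised_set`.
#' @return List with `direction_ok`, `steiger_p`, `r2_exp_sum`, `r2_out_sum`.
#' @export
steiger_test <- function(hset) {
  d <- hset$data
  r2e <- sum(snp_r2(d$beta_exp, d$se_exp, d$n_exp))
  r2o <- sum(snp_r2(d$beta_out, d$se_out, d$n_out))
  r_e <- sqrt(min(r2e, 1 - 1e-12))
  r_o <- sqrt(min(r2o, 1 - 1e-12))
  ne <- mean(d$n_exp); no <- mean(d$n_out)
  z <- (atanh(r_e) - atanh(r_o)) / sqrt(1 / (ne - 3) + 1 / (no - 3))
  list(direction_ok = r2e > r2o, steiger_p = z_to_p(z),
       r2_exp_sum = r2e, r2_out_sum = r2o)
}

#' Assemble the sensitivity report for an instrument set
#'
#' Cochran's Q at the IVW estimate, the MR-Egger intercept test, the Steiger
#' directionality test and (optionally) the MR-PRESSO global p-value.
#'
#' @param hset A `harmonised_set`.
#' @param presso_global_p Optional MR-PRESSO global p (see [mr_presso()]).
#' @return List of sensitivity statistics.
#' @export
sensitivity_report <- function(hset, presso_global_p = NA_real_) {
  n <- n_snp(hset)
  ivw <- if (n >= 2L) mr_ivw(hset) else NULL
  qres <- if (n >= 2L) cochran_q(hset, ivw$beta) else list(q = NA_real_, df = NA_integer_, p = NA_real_)
  egg <- if (n >= 3L) mr_egger(hset) else NULL
  st <- steiger_test(hset)
  list(cochran_q = qres$q, q_df = qres$df, q_pval = qres$p,
       egger_intercept = if (is.null(egg)) NA_real_ else egg$egger_intercept,
       egger_intercept_p = if (is.null(egg)) NA_real_ else egg$egger_intercept_p,
       steiger_direction_ok = st$direction_ok, steiger_p = st$steiger_p,
       presso_global_p = presso_global_p)
}
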