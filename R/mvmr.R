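#' Assemble the input for multivariable MR
#'
#' Builds the joint per-SNP effect matrix for two or more exposures against
#' one outcome.  The SNP set is the union of the per-exposure instrument
#' sets, optionally re-clumped jointly (greedy, ordered by the minimum
#' p-value across exposures).  Every SNP is harmonised to the orientation of
#' the first exposure panel; SNPs missing from any panel, or dropped during
#' pairwise harmonisation, are removed and audited.
#'
#' @param exposure_panels Named list of [gwas_panel()]s (>= 2), first panel
#'   defines the reference orientation.
#' @param outcome_panel Outcome [gwas_panel()].
#' @param instruments List of character vectors of instrument SNP ids, one
#'   per exposure (e.g. from [select_instruments()]).
#' @param ld Optional `ld_matrix` for joint re-clumping.
#' @param clump_window_kb,clump_r2 Joint clumping settings (used when `ld`
#'   is supplied).
#' @return An `mvmr_input`: `snp_ids`, `beta_X` / `se_X` (n_snp x n_exposure
#'   matrices), `beta_Y` / `se_Y`, `exposure_ids`, `outcome_id`, `audit`.
#' @export
build_mvmr_input <- function(exposure_panels, outcome_panel, instruments,
                             ld = NULL, clump_window_kb = 500L,
                             clump_r2 = 0.01) {
  k <- length(exposure_panels)
  if (k < 2L)
    stop_mrm("mrm_config_error", "multivariable MR needs at least 2 exposures")
  stopifnot(length(instruments) == k)
  exposure_ids <- vapply(exposure_panels, `[[`, character(1), "trait_id")

  union_ids <- unique(unlist(instruments))
  ref <- exposure_panels[[1L]]
  audit <- data.frame(snp_id = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  note <- function(ids, reason) {
    if (length(ids))
      audit <<- rbind(audit, data.frame(snp_id = ids, reason = reason,
                                        stringsAsFactors = FALSE))
  }

  present <- Reduce(intersect, c(lapply(exposure_panels,
                                        function(p) p$data$snp_id),
                                 list(outcome_panel$data$snp_id)))
  missing <- setdiff(union_ids, present)
  note(missing, "missing_in_some_panel")
  ids <- intersect(union_ids, present)
  if (length(ids) <= k)
    stop_mrm("mrm_identification_error", paste0(
      "only ", length(ids), " usable SNP(s) for ", k, " exposures"))

  # Joint re-clump on the union, ranked by the best p-value across exposures.
  if (!is.null(ld)) {
    ref_rows <- ref$data[match(ids, ref$data$snp_id), , drop = FALSE]
    minp <- do.call(pmin, lapply(exposure_panels, function(p)
      p$data$pval[match(ids, p$data$snp_id)]))
    pseudo <- ref
    pseudo$data <- transform(ref_rows, pval = minp)
    rownames(pseudo$data) <- NULL
    clumped <- clump(pseudo, ld, clump_window_kb, clump_r2)
    note(setdiff(ids, clumped$data$snp_id), "joint_clump")
    ids <- clumped$data$snp_id
    if (length(ids) <= k)
      stop_mrm("mrm_identification_error",
               "joint clumping left too few SNPs for identification")
  }

  ref_sub <- subset_panel(ref, ids)
  align <- function(panel) {
    hs <- harmonise(ref_sub, subset_panel(panel, ids))
    list(ids = hs$data$snp_id,
         beta = stats::setNames(hs$data$beta_out, hs$data$snp_id),
         se = stats::setNames(hs$data$se_out, hs$data$snp_id),
         dropped = hs$dropped)
  }
  aligned <- lapply(c(exposure_panels[-1L], list(outcome_panel)), align)
  for (a in aligned) note(a$dropped$snp_id, a$dropped$reason)
  keep <- Reduce(intersect, c(list(ids), lapply(aligned, `[[`, "ids")))
  if (length(keep) <= k)
    stop_mrm("mrm_identification_error",
             "harmonisation left too few SNPs for identification")

  ref_rows <- ref_sub$data[match(keep, ref_sub$data$snp_id), , drop = FALSE]
  beta_X <- cbind(ref_rows$beta,
                  do.call(cbind, lapply(aligned[-length(aligned)],
                                        function(a) unname(a$beta[keep]))))
  se_X <- cbind(ref_rows$se,
                do.call(cbind, lapply(aligned[-length(aligned)],
                                      function(a) unname(a$se[keep]))))
  colnames(beta_X) <- colnames(se_X) <- exposure_ids
  outc <- aligned[[length(aligned)]]
  structure(list(snp_ids = keep, beta_X = beta_X, se_X = se_X,
                 beta_Y = unname(outc$beta[keep]),
                 se_Y = unname(outc$se[keep]),
                 exposure_ids = unname(exposure_ids),
                 outcome_id = outcome_panel$trait_id,
                 audit = audit),
            class = "mvmr_input")
}

#' Multivariable IVW estimate
#'
#' Weighted least squares of the outcome effects on the exposure-effect
#' matrix without intercept, weights `1/se_Y^2`.  Standard errors come from
#' the weighted normal-equations covariance scaled by the multiplicative
#' overdispersion factor `max(1, sqrt(Q_resid/(n_snp - n_exposures)))`.
#' Confidence intervals use the normal quantile 1.959964.
#'
#' @param input An `mvmr_input`.
#' @return An `mvmr_estimate`: data frame `estimates` (one row per exposure:
#'   `exposure_id`, `beta`, `se`, `ci_low`, `ci_high`, `or`, `or_low`,
#'   `or_high`, `pval`) plus `q_resid`, `q_df`, `n_snp`.
#' @export
mvmr_ivw <- function(input) {
  X <- input$beta_X
  y <- input$beta_Y
  w <- 1 / input$se_Y^2
  n <- nrow(X); k <- ncol(X)
  if (n <= k)
    stop_mrm("mrm_identification_error", "need more SNPs than exposures")
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < k) {
    cols <- paste(input$exposure_ids, collapse = ", ")
    stop_mrm("mrm_identification_error", paste0(
      "exposure effect matrix is rank deficient (collinear exposures among: ",
      cols, ")"))
  }
  XtWX <- crossprod(X, X * w)
  coefs <- drop(solve(XtWX, crossprod(X, y * w)))
  resid <- y - drop(X %*% coefs)
  q_resid <- sum(w * resid^2)
  phi <- max(1, sqrt(q_resid / (n - k)))
  covb <- solve(XtWX) * phi^2
  se <- sqrt(diag(covb))
  z975 <- 1.959964
  est <- data.frame(
    exposure_id = input$exposure_ids,
    beta = coefs, se = se,
    ci_low = coefs - z975 * se, ci_high = coefs + z975 * se,
    or = exp(coefs), or_low = exp(coefs - z975 * se),
    or_high = exp(coefs + z975 * se),
    pval = z_to_p(coefs / se),
    row.names = NULL, stringsAsFactors = FALSE)
  if (n < 3L * k)
    warning("fewer than 3 SNPs per exposure; multivariable estimates may be unstable")
  structure(list(estimates = est, q_resid = q_resid, q_df = n - k,
                 n_snp = n), class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("<mvmr_estimate> %d SNPs, Q_resid = %.4g (df %d)\n",
              x$n_snp, x$q_resid, x$q_df))
  print(x$estimates)
  invisible(x)
}
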