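#' Two-step MR mediation decomposition
#'
#' Combines the total effect of the exposure on the outcome, the univariable
#' exposure-to-mediator effect `beta_a`, and the mediator-on-outcome effect
#' adjusted for the exposure `beta_b` (from multivariable MR) into the
#' product-of-coefficients decomposition:
#' indirect = `beta_a * beta_b`; direct = total - indirect;
#' mediated proportion = indirect / total.  The indirect-effect standard
#' error is the first-order delta (Sobel) form
#' `sqrt(beta_a^2 se_b^2 + beta_b^2 se_a^2)` (`second_order = TRUE` adds the
#' `se_a^2 se_b^2` term); its 95% CI uses the normal quantile 1.959964 and
#' the p-value is two-sided normal.
#'
#' Classification at level `alpha`: `none` when the indirect effect is not
#' significant; otherwise `inconsistent` when the indirect and total effects
#' have opposite signs, `complete` when the direct effect is not significant,
#' and `partial` when both are.  The direct-effect SE is approximated as
#' `sqrt(se_total^2 + se_indirect^2)` (independence approximation across the
#' two samples).
#'
#' @param total [wald_ratio()] / [mr_ivw()] estimate of the exposure-outcome
#'   total effect.
#' @param a Univariable estimate of the exposure-mediator effect.
#' @param b The mediator's row from [mvmr_ivw()] (or any list with `beta`
#'   and `se`).
#' @param alpha Two-sided significance level for classification
#'   (default 0.1).
#' @param second_order Include the second-order delta variance term.
#' @param exposure_id,mediator_id,outcome_id Optional trait labels.
#' @return A `mediation_result` list: effects, delta-method CI, p-value,
#'   signed `proportion` (and `proportion_abs`), and `classification`.
#' @export
mediate <- function(total, a, b, alpha = 0.1, second_order = FALSE,
                    exposure_id = NULL, mediator_id = NULL,
                    outcome_id = NULL) {
  grab <- function(x) list(beta = x$beta, se = x$se)
  tt <- grab(total); aa <- grab(a); bb <- grab(b)
  indirect <- aa$beta * bb$beta
  v <- aa$beta^2 * bb$se^2 + bb$beta^2 * aa$se^2
  if (second_order) v <- v + aa$se^2 * bb$se^2
  se_indirect <- sqrt(v)
  z975 <- 1.959964
  direct <- tt$beta - indirect
  se_direct <- sqrt(tt$se^2 + se_indirect^2)
  pval <- if (se_indirect > 0) z_to_p(indirect / se_indirect) else
    as.numeric(indirect == 0)
  p_direct <- z_to_p(direct / se_direct)
  proportion <- if (tt$beta != 0) indirect / tt$beta else NA_real_
  classification <-
    if (pval >= alpha) "none"
    else if (sign(indirect) != sign(tt$beta)) "inconsistent"
    else if (p_direct >= alpha) "complete"
    else "partial"
  structure(list(
    exposure_id = exposure_id, mediator_id = mediator_id,
    outcome_id = outcome_id,
    total = tt$beta, se_total = tt$se,
    beta_a = aa$beta, se_a = aa$se,
    beta_b = bb$beta, se_b = bb$se,
    indirect = indirect, se_indirect = se_indirect,
    ci_low = indirect - z975 * se_indirect,
    ci_high = indirect + z975 * se_indirect,
    direct = direct, se_direct = se_direct,
    proportion = proportion,
    proportion_abs = if (is.na(proportion)) NA_real_ else abs(proportion),
    proportion_defined = tt$beta != 0,
    pval = pval, p_direct = p_direct, alpha = alpha,
    classification = classification
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s\n",
              x$exposure_id %||% "exposure", x$mediator_id %||% "mediator",
              x$outcome_id %||% "outcome"))
  cat(sprintf("  total %.4g, direct %.4g, indirect %.4g [%.4g, %.4g], p = %.3g\n",
              x$total, x$direct, x$indirect, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  mediated proportion %.2f%%, classification: %s\n",
              100 * x$proportion, x$classification))
  invisible(x)
}

#' Mediation scan over exposure-mediator pairs
#'
#' For every exposure-mediator pair whose exposure-to-mediator effect is
#' significant at `alpha`, computes: the total effect (univariable IVW of
#' the exposure on the outcome, on the exposure's selected instruments),
#' `beta_a` (univariable IVW of the exposure on the mediator, same
#' instruments), `beta_b` (the mediator coefficient from pairwise
#' multivariable MR of exposure + mediator on the outcome, on the jointly
#' clumped union of both instrument sets) and the [mediate()] decomposition.
#'
#' Instrument selection uses the `"mediation"` profile by default, which
#' disables the outcome-association filter: with an established causal
#' effect, that filter preferentially removes valid instruments and biases
#' the total effect toward the null (see the methods vignette).
#'
#' @param exposure_panels Named list of exposure [gwas_panel()]s.
#' @param mediator_panels Named list of mediator [gwas_panel()]s.
#' @param outcome Outcome [gwas_panel()].
#' @param ld An `ld_matrix` covering all SNPs.
#' @param params A [selection_params()]; default `selection_profile("mediation")`.
#' @param alpha Significance level for the beta(A) gate and the
#'   classification (default 0.1).
#' @param presso_nsim MR-PRESSO resamples inside instrument selection
#'   (0 disables).
#' @param seed Seed for resampling stages.
#' @return List of `mediation_result`s (one per evaluated pair); pairs that
#'   fail (no instruments, identification error) or are gated out are
#'   recorded in the `"skipped"` attribute with the reason.
#' @export
mediation_scan <- function(exposure_panels, mediator_panels, outcome, ld,
                           params = selection_profile("mediation"),
                           alpha = 0.1, presso_nsim = 1000L, seed = NULL) {
  results <- list()
  skipped <- list()
  skip <- function(exp_id, med_id, why)
    skipped[[length(skipped) + 1L]] <<- data.frame(
      exposure_id = exp_id, mediator_id = med_id, reason = why,
      stringsAsFactors = FALSE)

  for (ei in seq_along(exposure_panels)) {
    expo <- exposure_panels[[ei]]
    iset <- tryCatch(
      select_instruments(expo, outcome, ld, params,
                         presso_nsim = presso_nsim, seed = seed),
      mrm_error = function(e) e)
    if (inherits(iset, "error")) {
      for (med in mediator_panels)
        skip(expo$trait_id, med$trait_id, conditionMessage(iset))
      next
    }
    total <- mr_ivw(iset$harmonised)
    inst_ids <- iset$harmonised$data$snp_id

    for (mi in seq_along(mediator_panels)) {
      med <- mediator_panels[[mi]]
      res <- tryCatch({
        hs_a <- harmonise(subset_panel(expo, inst_ids), med)
        a <- mr_ivw(hs_a)
        if (a$pval >= alpha) {
          skip(expo$trait_id, med$trait_id, "beta_a_not_significant")
          NULL
        } else {
          med_iset <- tryCatch(
            select_instruments(med, outcome, ld, params,
                               presso_nsim = presso_nsim, seed = seed),
            mrm_error = function(e) NULL)
          med_ids <- if (is.null(med_iset)) character(0)
                     else med_iset$harmonised$data$snp_id
          mv_in <- build_mvmr_input(
            list(expo, med), outcome,
            instruments = list(inst_ids, med_ids),
            ld = ld, clump_window_kb = params$clump_window_kb,
            clump_r2 = params$clump_r2)
          mv <- mvmr_ivw(mv_in)
          b <- mv$estimates[mv$estimates$exposure_id == med$trait_id, ]
          mediate(total, a, b, alpha = alpha,
                  exposure_id = expo$trait_id, mediator_id = med$trait_id,
                  outcome_id = outcome$trait_id)
        }
      }, mrm_error = function(e) {
        skip(expo$trait_id, med$trait_id, conditionMessage(e))
        NULL
      })
      if (!is.null(res)) results[[length(results) + 1L]] <- res
    }
  }
  attr(results, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
    else data.frame(exposure_id = character(0), mediator_id = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  results
}

#' Tabulate mediation results
#'
#' One row per result, mirroring the standard mediation-table columns:
#' exposure, mediator, outcome, total, direct, mediation effect with CI,
#' p-value and mediated proportion (signed and absolute).
#'
#' @param results List of `mediation_result`s (e.g. from [mediation_scan()]).
#' @return A data frame.
#' @export
mediation_table <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    exposure_id = r$exposure_id %||% NA_character_,
    mediator_id = r$mediator_id %||% NA_character_,
    outcome_id = r$outcome_id %||% NA_character_,
    total = r$total, direct = r$direct,
    indirect = r$indirect, ci_low = r$ci_low, ci_high = r$ci_high,
    pval = r$pval, proportion = r$proportion,
    proportion_abs = r$proportion_abs,
    classification = r$classification,
    stringsAsFactors = FALSE)))
}
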