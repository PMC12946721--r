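#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted values: with p-values sorted ascending,
#' `q_(i) = min_{k >= i} p_(k) * m / k`, capped at 1, returned in input
#' order.  Thin validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param pvals Non-empty numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L)
    stop_mrm("mrm_validation_error", "empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop_mrm("mrm_validation_error", "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

screen_row_names <- function() {
  c("exposure_id", "outcome_id", "direction", "status", "method", "n_snp",
    "threshold_used", "beta", "se", "ci_low", "ci_high", "or", "or_low",
    "or_high", "pval", "q", "q_df", "q_pval", "egger_intercept",
    "egger_intercept_p", "steiger_ok", "steiger_p", "presso_global_p",
    "fdr_q", "raw_significant", "fdr_significant", "significant",
    "classification")
}

empty_screen_row <- function(exposure_id, outcome_id, direction, status) {
  row <- data.frame(
    exposure_id = exposure_id, outcome_id = outcome_id,
    direction = direction, status = status,
    method = NA_character_, n_snp = NA_integer_, threshold_used = NA_real_,
    beta = NA_real_, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    or = NA_real_, or_low = NA_real_, or_high = NA_real_, pval = NA_real_,
    q = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
    egger_intercept = NA_real_, egger_intercept_p = NA_real_,
    steiger_ok = NA, steiger_p = NA_real_, presso_global_p = NA_real_,
    fdr_q = NA_real_, raw_significant = NA, fdr_significant = NA,
    significant = NA, classification = "none",
    stringsAsFactors = FALSE)
  row[, screen_row_names()]
}

#' Screen exposures against one outcome
#'
#' For each exposure panel: select instruments, estimate the causal effect
#' (IVW with at least two instruments, otherwise the Wald ratio) and attach
#' the full sensitivity report.  Benjamini-Hochberg adjustment is applied
#' across the family of this one screen invocation; `significant` means
#' `fdr_q < fdr_threshold`, `raw_significant` means `pval < 0.05` (both are
#' reported because headline results are often quoted at raw p < 0.05 while
#' the declared criterion is FDR-based).  Significant rows are classified
#' `Risk` (OR > 1) or `Protect` (OR < 1).  Per-trait failures become status
#' rows, never errors.
#'
#' @param exposures Named list of exposure [gwas_panel()]s.
#' @param outcome Outcome [gwas_panel()].
#' @param ld An `ld_matrix`.
#' @param params A [selection_params()].
#' @param fdr_threshold FDR significance threshold (default 0.1).
#' @param direction Label stored in the rows (`"forward"` or `"reverse"`).
#' @param presso_nsim MR-PRESSO resamples inside selection (0 disables).
#' @param seed Seed for resampling stages.
#' @return Data frame with one row per exposure (class `screen_result`).
#' @export
mr_screen <- function(exposures, outcome, ld, params = selection_params(),
                      fdr_threshold = 0.1, direction = "forward",
                      presso_nsim = 1000L, seed = NULL) {
  rows <- lapply(exposures, function(expo) {
    out <- tryCatch({
      iset <- select_instruments(expo, outcome, ld, params,
                                 presso_nsim = presso_nsim, seed = seed)
      hs <- iset$harmonised
      est <- if (n_snp(hs) >= 2L) mr_ivw(hs) else
        wald_ratio(hs$data$beta_exp, hs$data$se_exp,
                   hs$data$beta_out, hs$data$se_out)
      sens <- sensitivity_report(hs,
        presso_global_p = if (is.null(iset$presso)) NA_real_
                          else iset$presso$global_p)
      row <- empty_screen_row(expo$trait_id, outcome$trait_id, direction, "ok")
      row$method <- est$method; row$n_snp <- est$n_snp
      row$threshold_used <- iset$threshold_used
      for (f in c("beta", "se", "ci_low", "ci_high", "or", "or_low",
                  "or_high", "pval"))
        row[[f]] <- est[[f]]
      row$q <- sens$cochran_q; row$q_df <- sens$q_df; row$q_pval <- sens$q_pval
      row$egger_intercept <- sens$egger_intercept
      row$egger_intercept_p <- sens$egger_intercept_p
      row$steiger_ok <- sens$steiger_direction_ok
      row$steiger_p <- sens$steiger_p
      row$presso_global_p <- sens$presso_global_p
      row
    }, mrm_error = function(e)
      empty_screen_row(expo$trait_id, outcome$trait_id, direction,
                       conditionMessage(e)))
    out
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ok <- res$status == "ok"
  if (any(ok)) {
    res$fdr_q[ok] <- bh_adjust(res$pval[ok])
    res$raw_significant[ok] <- res$pval[ok] < 0.05
    res$fdr_significant[ok] <- res$fdr_q[ok] < fdr_threshold
    res$significant <- res$fdr_significant
    res$classification[ok] <- ifelse(
      res$significant[ok] & res$or[ok] > 1, "Risk",
      ifelse(res$significant[ok] & res$or[ok] < 1, "Protect", "none"))
  }
  class(res) <- c("screen_result", class(res))
  res
}

#' Reverse-direction screen
#'
#' Runs the identical machinery with the roles swapped: the (disease)
#' outcome trait becomes the exposure and each target trait becomes an
#' outcome.  Uses the `"reverse_mr"` selection profile (p < 1e-8, 10,000 kb
#' window, r2 < 0.001, F > 10) unless overridden.
#'
#' @param outcome_as_exposure The disease [gwas_panel()], now the exposure.
#' @param targets Named list of target [gwas_panel()]s, each screened as an
#'   outcome.
#' @param ld An `ld_matrix`.
#' @param params A [selection_params()]; default
#'   `selection_profile("reverse_mr")`.
#' @param ... Passed to [mr_screen()] internals (`fdr_threshold`,
#'   `presso_nsim`, `seed`).
#' @return Data frame with one row per target, `direction = "reverse"`.
#' @export
reverse_screen <- function(outcome_as_exposure, targets, ld,
                           params = selection_profile("reverse_mr"), ...) {
  dots <- list(...)
  fdr_threshold <- dots$fdr_threshold %||% 0.1
  presso_nsim <- dots$presso_nsim %||% 1000L
  seed <- dots$seed
  rows <- lapply(targets, function(target) {
    single <- mr_screen(list(outcome_as_exposure), target, ld, params,
                        fdr_threshold = fdr_threshold, direction = "reverse",
                        presso_nsim = presso_nsim, seed = seed)
    single
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ok <- res$status == "ok"
  # re-adjust across the whole reverse family, not per target
  res$fdr_q <- NA_real_
  if (any(ok)) {
    res$fdr_q[ok] <- bh_adjust(res$pval[ok])
    res$fdr_significant[ok] <- res$fdr_q[ok] < fdr_threshold
    res$significant <- res$fdr_significant
    res$classification[ok] <- ifelse(
      res$significant[ok] & res$or[ok] > 1, "Risk",
      ifelse(res$significant[ok] & res$or[ok] < 1, "Protect", "none"))
  }
  res
}

#' Write screen results as TSV
#' @param rows A screen result data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
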