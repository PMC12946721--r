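#' Instrument-selection parameters
#'
#' Bundles the six-step instrument-selection settings: the genome-wide
#' significance threshold with its relaxed fallback, LD-clumping window and
#' r-squared ceiling, the outcome-association filter, the weak-instrument F
#' cutoff and the Steiger directionality filter.  Named profiles mirror the
#' conventional presets: `"default"` (500 kb, r2 < 0.01), `"bloodcell"`
#' (10,000 kb, r2 < 0.001) and `"reverse_mr"` (p < 1e-8, 10,000 kb,
#' r2 < 0.001, no relaxed fallback).
#'
#' @param p_primary Primary significance threshold (default 5e-8).
#' @param p_fallback Relaxed threshold used when fewer than
#'   `min_snps_for_primary` SNPs pass `p_primary` (default 5e-5).
#' @param min_snps_for_primary Minimum SNP count for the primary threshold.
#' @param clump_window_kb Clumping window in kilobases.
#' @param clump_r2 Maximum permitted r-squared between retained instruments.
#' @param p_outcome_min Candidates with outcome p-value at or below this are
#'   removed ("unrelated to the outcome" filter); 0 disables the filter.
#' @param f_min Weak-instrument cutoff; SNPs with `F <= f_min` are removed.
#' @param steiger_filter Apply the per-SNP Steiger directionality filter.
#' @return A `selection_params` list.
#' @export
selection_params <- function(p_primary = 5e-8, p_fallback = 5e-5,
                             min_snps_for_primary = 5L,
                             clump_window_kb = 500L, clump_r2 = 0.01,
                             p_outcome_min = 0.05, f_min = 10,
                             steiger_filter = TRUE) {
  if (p_fallback < p_primary)
    stop_mrm("mrm_config_error", "p_fallback must be >= p_primary")
  if (clump_r2 <= 0 || clump_r2 > 1)
    stop_mrm("mrm_config_error", "clump_r2 must lie in (0,1]")
  structure(list(p_primary = p_primary, p_fallback = p_fallback,
                 min_snps_for_primary = as.integer(min_snps_for_primary),
                 clump_window_kb = as.integer(clump_window_kb),
                 clump_r2 = clump_r2, p_outcome_min = p_outcome_min,
                 f_min = f_min, steiger_filter = isTRUE(steiger_filter)),
            class = "selection_params")
}

#' @rdname selection_params
#' @param profile One of `"default"`, `"bloodcell"`, `"reverse_mr"`,
#'   `"mediation"`.
#' @param ... Overrides passed to [selection_params()].
#' @export
selection_profile <- function(profile = c("default", "bloodcell",
                                          "reverse_mr", "mediation"), ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    default = list(),
    bloodcell = list(clump_window_kb = 10000L, clump_r2 = 0.001),
    reverse_mr = list(p_primary = 1e-8, p_fallback = 1e-8,
                      min_snps_for_primary = 1L,
                      clump_window_kb = 10000L, clump_r2 = 0.001),
    # In the mediation stage the exposure-outcome effect is established, so
    # the "unrelated to the outcome" filter would preferentially discard
    # valid instruments; pleiotropy exclusion is delegated to PRESSO/Steiger.
    mediation = list(p_outcome_min = 0))
  do.call(selection_params, utils::modifyList(base, list(...)))
}

#' Threshold instruments with genome-wide fallback
#'
#' Retains SNPs with `pval < p_primary`; if fewer than
#' `min_snps_for_primary` survive, the relaxed `p_fallback` threshold is used
#' instead.  The threshold actually applied is reported in the
#' `"threshold_used"` attribute of the result.
#'
#' @param exposure A [gwas_panel()].
#' @param params A [selection_params()].
#' @return The filtered panel (attribute `threshold_used`).
#' @export
threshold_instruments <- function(exposure, params = selection_params()) {
  p <- exposure$data$pval
  keep <- p < params$p_primary
  used <- params$p_primary
  if (sum(keep) < params$min_snps_for_primary) {
    keep <- p < params$p_fallback
    used <- params$p_fallback
  }
  if (!any(keep))
    stop_mrm("mrm_no_instrument_error", paste0(
      "no SNPs pass p < ", format(params$p_primary), " or p < ",
      format(params$p_fallback), " for trait '", exposure$trait_id, "'"))
  out <- exposure
  out$data <- exposure$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  attr(out, "threshold_used") <- used
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining SNP with the smallest p-value (ties broken
#' by lexicographic `snp_id`) and discards every remaining SNP on the same
#' chromosome within `window_kb` kilobases whose r-squared with it exceeds
#' `r2_max`.  Retained SNPs are returned in their original panel order, so
#' the result is independent of input row order.
#'
#' @param panel A [gwas_panel()]; all SNPs must be present in `ld`.
#' @param ld An `ld_matrix`.
#' @param window_kb Clump window in kilobases.
#' @param r2_max Maximum permitted r-squared.
#' @return The clumped panel.
#' @export
clump <- function(panel, ld, window_kb = 500L, r2_max = 0.01) {
  d <- panel$data
  missing <- setdiff(d$snp_id, ld$snp_ids)
  if (length(missing))
    stop_mrm("mrm_missing_ld_error", paste0(
      "SNP(s) absent from LD matrix: ",
      paste(utils::head(missing, 5L), collapse = ", ")))
  ord <- order(d$pval, d$snp_id)
  alive <- rep(TRUE, nrow(d))
  keep <- logical(nrow(d))
  R <- ld$r2
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- alive & d$chrom == d$chrom[i] &
      abs(d$pos - d$pos[i]) <= window_kb * 1000
    if (any(near)) {
      r2 <- R[d$snp_id[i], d$snp_id[near]]
      alive[which(near)[r2 > r2_max]] <- FALSE
    }
  }
  out <- panel
  out$data <- d[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  attr(out, "threshold_used") <- attr(panel, "threshold_used")
  out
}

#' Outcome-association filter
#'
#' Removes candidate instruments whose outcome-panel p-value is at or below
#' `p_min` ("SNPs not related to the outcome" criterion).  Candidates absent
#' from the outcome panel are retained here and dropped later at
#' harmonisation with reason `missing_in_outcome`.
#'
#' @param candidates Candidate-instrument [gwas_panel()].
#' @param outcome Outcome [gwas_panel()].
#' @param p_min Removal threshold; 0 disables the filter.
#' @return The filtered candidate panel.
#' @export
filter_outcome_association <- function(candidates, outcome, p_min = 0.05) {
  if (p_min <= 0) return(candidates)
  p_out <- outcome$data$pval[match(candidates$data$snp_id,
                                   outcome$data$snp_id)]
  keep <- is.na(p_out) | p_out > p_min
  out <- candidates
  out$data <- candidates$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  attr(out, "threshold_used") <- attr(candidates, "threshold_used")
  out
}

#' Steiger directionality filter
#'
#' Removes SNPs whose variance explained in the outcome strictly exceeds
#' that in the exposure (`t^2/(t^2+n-2)` form); ties are retained.
#'
#' @param hset A `harmonised_set`.
#' @return List with the filtered `hset` and the `removed` SNP ids.
#' @export
steiger_filter <- function(hset) {
  d <- hset$data
  r2e <- snp_r2(d$beta_exp, d$se_exp, d$n_exp)
  r2o <- snp_r2(d$beta_out, d$se_out, d$n_out)
  bad <- r2o > r2e
  list(hset = hset_subset(hset, !bad), removed = d$snp_id[bad])
}

#' Select instruments for one exposure-outcome pair
#'
#' Composes the selection pipeline: significance thresholding (with
#' fallback), greedy LD clumping, the outcome-association filter,
#' harmonisation, the F > `f_min` weak-instrument filter, the per-SNP Steiger
#' filter and iterative MR-PRESSO outlier pruning (repeat until the global
#' test exceeds 0.05 or fewer than 4 SNPs remain).  Every removed SNP appears
#' exactly once in the audit trail with the stage and reason.
#'
#' @param exposure,outcome [gwas_panel()]s.
#' @param ld An `ld_matrix` covering the exposure SNPs.
#' @param params A [selection_params()].
#' @param presso_nsim MR-PRESSO resamples; 0 skips PRESSO pruning.
#' @param seed Seed for the PRESSO resampling.
#' @return An `instrument_set`: `harmonised` (with per-SNP `f_stat`,
#'   `r2_exp`, `r2_out` columns), `audit` data frame
#'   (`snp_id`, `stage_removed`, `reason`), `threshold_used`, `params`,
#'   `presso` (final `presso_result` or NULL) and `n_input`.
#' @export
select_instruments <- function(exposure, outcome, ld,
                               params = selection_params(),
                               presso_nsim = 5000L, seed = NULL) {
  audit <- data.frame(snp_id = character(0), stage_removed = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  note <- function(ids, stage, reason) {
    if (length(ids))
      audit <<- rbind(audit, data.frame(snp_id = ids, stage_removed = stage,
                                        reason = reason,
                                        stringsAsFactors = FALSE))
  }
  fail <- function(stage) stop_mrm("mrm_no_instrument_error",
    paste0("no instruments remain after stage '", stage, "' for '",
           exposure$trait_id, "' -> '", outcome$trait_id, "'"))

  th <- threshold_instruments(exposure, params)
  note(setdiff(exposure$data$snp_id, th$data$snp_id),
       "threshold", "pval_above_threshold")

  cl <- clump(th, ld, params$clump_window_kb, params$clump_r2)
  note(setdiff(th$data$snp_id, cl$data$snp_id), "clump", "ld_with_retained_snp")
  if (nrow(cl$data) == 0L) fail("clump")

  oc <- filter_outcome_association(cl, outcome, params$p_outcome_min)
  note(setdiff(cl$data$snp_id, oc$data$snp_id),
       "outcome_filter", "associated_with_outcome")
  if (nrow(oc$data) == 0L) fail("outcome_filter")

  hs <- harmonise(oc, outcome)
  if (nrow(hs$dropped))
    note(hs$dropped$snp_id, "harmonise", hs$dropped$reason)

  f <- f_statistic(hs$data$beta_exp, hs$data$se_exp)
  weak <- f <= params$f_min
  note(hs$data$snp_id[weak], "f_filter", "weak_instrument")
  hs <- hset_subset(hs, !weak)
  if (n_snp(hs) == 0L) fail("f_filter")

  if (params$steiger_filter) {
    st <- steiger_filter(hs)
    note(st$removed, "steiger", "steiger_reversed")
    hs <- st$hset
    if (n_snp(hs) == 0L) fail("steiger")
  }

  presso <- NULL
  if (presso_nsim > 0) {
    round <- 0L
    while (n_snp(hs) >= 4L) {
      presso <- mr_presso(hs, n_sim = presso_nsim,
                          seed = if (is.null(seed)) NULL else seed + round)
      if (presso$global_p > 0.05 || length(presso$outliers) == 0L) break
      note(presso$outliers, "presso", "presso_outlier")
      hs <- hset_subset(hs, !(hs$data$snp_id %in% presso$outliers))
      round <- round + 1L
    }
  }

  hs$data$f_stat <- f_statistic(hs$data$beta_exp, hs$data$se_exp)
  hs$data$r2_exp <- snp_r2(hs$data$beta_exp, hs$data$se_exp, hs$data$n_exp)
  hs$data$r2_out <- snp_r2(hs$data$beta_out, hs$data$se_out, hs$data$n_out)

  structure(list(harmonised = hs, audit = audit,
                 threshold_used = attr(th, "threshold_used"),
                 params = params, presso = presso,
                 n_input = nrow(exposure$data)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s -> %s: %d instruments (threshold %g), %d removed\n",
              x$harmonised$exposure_id, x$harmonised$outcome_id,
              n_snp(x$harmonised), x$threshold_used, nrow(x$audit)))
  invisible(x)
}

#' Write an instrument-selection audit trail
#'
#' @param iset An `instrument_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(iset, path) {
  utils::write.table(iset$audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
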