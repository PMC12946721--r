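#' Harmonise exposure and outcome panels to a shared effect allele
#'
#' Aligns every SNP shared by the two panels to the exposure panel's effect
#' allele.  Outcome records whose alleles are swapped relative to the exposure
#' have their effect sign flipped and frequency complemented; records on the
#' opposite strand are complemented first.  Palindromic SNPs (A/T or C/G)
#' carry no strand information in their allele labels, so they are retained
#' only when both panels' effect-allele frequencies fall on the same side of
#' 0.5 and both lie outside `0.5 +/- palindrome_eaf_window`; otherwise they
#' are dropped with reason `palindromic_ambiguous`.  A missing frequency on
#' either side also drops a palindromic SNP (fail-safe).  Irreconcilable
#' allele pairs are dropped with reason `allele_mismatch`.
#'
#' @param exposure,outcome [gwas_panel()] objects.
#' @param palindrome_eaf_window Half-width of the ambiguity band around an
#'   allele frequency of 0.5; must lie in `[0, 0.5)`.  Default 0.08.
#' @return A `harmonised_set`: list with elements `exposure_id`, `outcome_id`,
#'   `data` (per-SNP aligned effects: `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta_exp`, `se_exp`, `pval_exp`,
#'   `n_exp`, `eaf_out`, `beta_out`, `se_out`, `pval_out`, `n_out`) and
#'   `dropped` (`snp_id`, `reason`).
#' @export
harmonise <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "gwas_panel"), inherits(outcome, "gwas_panel"))
  w <- palindrome_eaf_window
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w >= 0.5)
    stop_mrm("mrm_config_error", "palindrome_eaf_window must lie in [0, 0.5)")

  e <- exposure$data
  o <- outcome$data[match(e$snp_id, outcome$data$snp_id), , drop = FALSE]
  shared <- !is.na(o$snp_id)
  if (!any(shared))
    stop_mrm("mrm_empty_overlap_error",
             "no SNPs shared between exposure and outcome panels")
  e <- e[shared, , drop = FALSE]
  o <- o[shared, , drop = FALSE]

  n <- nrow(e)
  keep <- rep(TRUE, n)
  flip <- rep(FALSE, n)
  reason <- rep(NA_character_, n)

  pal <- is_palindromic(e$effect_allele, e$other_allele)

  # Non-palindromic: try as-written, swapped, complemented, complement-swapped.
  as_written <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swapped    <- o$effect_allele == e$other_allele  & o$other_allele == e$effect_allele
  c_ea <- revcomp(o$effect_allele); c_oa <- revcomp(o$other_allele)
  comp_match <- c_ea == e$effect_allele & c_oa == e$other_allele
  comp_swap  <- c_ea == e$other_allele  & c_oa == e$effect_allele

  npl <- !pal
  flip[npl & !as_written & (swapped | comp_swap)] <- TRUE
  mismatch <- npl & !(as_written | swapped | comp_match | comp_swap)
  keep[mismatch] <- FALSE
  reason[mismatch] <- "allele_mismatch"

  # Palindromic: complement is indistinguishable from identity/swap, so align
  # by the written labels, then demand frequency concordance.
  if (any(pal)) {
    pal_mismatch <- pal & !(as_written | swapped)
    keep[pal_mismatch] <- FALSE
    reason[pal_mismatch] <- "allele_mismatch"
    flip[pal & swapped] <- TRUE
    idx <- which(pal & (as_written | swapped))
    if (length(idx)) {
      eaf_o <- ifelse(flip[idx], 1 - o$eaf[idx], o$eaf[idx])
      eaf_e <- e$eaf[idx]
      ok <- !is.na(eaf_e) & !is.na(eaf_o) &
        sign(eaf_e - 0.5) == sign(eaf_o - 0.5) &
        abs(eaf_e - 0.5) > w & abs(eaf_o - 0.5) > w
      keep[idx[!ok]] <- FALSE
      reason[idx[!ok]] <- "palindromic_ambiguous"
    }
  }

  beta_out <- ifelse(flip, -o$beta, o$beta)
  eaf_out <- ifelse(flip, 1 - o$eaf, o$eaf)

  dropped <- data.frame(snp_id = e$snp_id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  missing_ids <- exposure$data$snp_id[!exposure$data$snp_id %in% outcome$data$snp_id]
  if (length(missing_ids))
    dropped <- rbind(data.frame(snp_id = missing_ids,
                                reason = "missing_in_outcome",
                                stringsAsFactors = FALSE), dropped)

  data <- data.frame(
    snp_id = e$snp_id, chrom = e$chrom, pos = e$pos,
    effect_allele = e$effect_allele, other_allele = e$other_allele,
    eaf = e$eaf,
    beta_exp = e$beta, se_exp = e$se, pval_exp = e$pval, n_exp = e$n,
    eaf_out = eaf_out, beta_out = beta_out, se_out = o$se,
    pval_out = o$pval, n_out = o$n,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(data) <- NULL
  if (nrow(data) == 0L)
    stop_mrm("mrm_empty_overlap_error",
             "all shared SNPs were dropped during harmonisation")
  structure(list(exposure_id = exposure$trait_id,
                 outcome_id = outcome$trait_id,
                 data = data, dropped = dropped),
            class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("<harmonised_set> %s -> %s: %d SNPs retained, %d dropped\n",
              x$exposure_id, x$outcome_id, nrow(x$data), nrow(x$dropped)))
  invisible(x)
}

n_snp <- function(hset) nrow(hset$data)

hset_subset <- function(hset, keep) {
  hset$data <- hset$data[keep, , drop = FALSE]
  rownames(hset$data) <- NULL
  hset
}

# Re-express a harmonised set as a pair of panels (used for the idempotence
# property and by multivariable assembly).
hset_to_panels <- function(hset, n_exp = NULL, n_out = NULL,
                           exposure_type = "continuous",
                           outcome_type = "binary") {
  d <- hset$data
  base <- d[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele")]
  exp_d <- cbind(base, data.frame(eaf = d$eaf, beta = d$beta_exp, se = d$se_exp,
                                  pval = d$pval_exp, n = d$n_exp))
  out_d <- cbind(base, data.frame(eaf = d$eaf_out, beta = d$beta_out,
                                  se = d$se_out, pval = d$pval_out, n = d$n_out))
  list(exposure = gwas_panel(hset$exposure_id, exposure_type, exp_d,
                             sample_size = n_exp %||% max(d$n_exp)),
       outcome = gwas_panel(hset$outcome_id, outcome_type, out_d,
                            sample_size = n_out %||% max(d$n_out)))
}
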