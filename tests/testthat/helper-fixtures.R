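# Small in-code fixtures shared across the suite.

# Build a panel from per-SNP vectors; pval derived from beta/se unless given.
make_panel <- function(trait_id = "exp", trait_type = "continuous",
                       beta, se, eaf = NULL, n = 10000L,
                       effect_allele = NULL, other_allele = NULL,
                       snp_id = NULL, chrom = "1", pos = NULL, pval = NULL) {
  m <- length(beta)
  pairs <- matrix(c("A","C", "A","G", "C","T", "G","T"), ncol = 2, byrow = TRUE)
  idx <- rep_len(seq_len(nrow(pairs)), m)
  gwas_panel(trait_id, trait_type, data.frame(
    snp_id = snp_id %||% sprintf("snp%03d", seq_len(m)),
    chrom = rep_len(chrom, m),
    pos = pos %||% (seq_len(m) * 100000L),
    effect_allele = effect_allele %||% pairs[idx, 1],
    other_allele = other_allele %||% pairs[idx, 2],
    eaf = eaf %||% rep(0.3, m),
    beta = beta, se = se,
    pval = pval %||% pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = rep_len(n, m), stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Harmonised set straight from aligned effect vectors (identical alleles).
make_hset <- function(beta_exp, se_exp, beta_out, se_out,
                      n_exp = 10000L, n_out = 10000L, eaf = 0.3) {
  e <- make_panel("exp", beta = beta_exp, se = se_exp, n = n_exp, eaf = rep_len(eaf, length(beta_exp)))
  o <- make_panel("out", "binary", beta = beta_out, se = se_out, n = n_out,
                  eaf = rep_len(eaf, length(beta_out)))
  harmonise(e, o)
}

# Independent weighted-least-squares oracle (stats::lm route).
lm_wls <- function(y, X, w, intercept = FALSE) {
  if (intercept) stats::lm(y ~ X, weights = w) else stats::lm(y ~ 0 + X, weights = w)
}
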