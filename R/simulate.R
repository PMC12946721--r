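#' Configuration for the synthetic GWAS triplet generator
#'
#' Describes the generative model for an exposure / mediator / binary-outcome
#' summary-statistics triplet with known causal structure
#' (exposure -> mediator -> outcome plus a direct exposure -> outcome path):
#' for exposure-instrument SNP j, the true exposure effect is
#' `gamma_j ~ N(0, exposure_effect_sd^2)`, the true mediator effect is
#' `alpha * gamma_j`, and the true outcome (log-odds) effect is
#' `(theta_direct + alpha * b_med) * gamma_j + u_j`, where `u_j` is a
#' horizontal-pleiotropy offset drawn for a `pleio_frac` subset.  A further
#' `n_snps_med` mediator-specific SNPs carry `delta_k ~ N(0, med_effect_sd^2)`
#' on the mediator (outcome effect `b_med * delta_k`, no exposure effect);
#' without them the exposure and mediator effect vectors would be exactly
#' collinear and multivariable MR would be unidentified.
#'
#' Observed effects add noise with per-trait standard error
#' `1 / sqrt(2 * eaf * (1 - eaf) * n)` (standardised-genotype approximation);
#' p-values are two-sided normal.
#'
#' @param n_snps Number of exposure-instrument SNPs.
#' @param n_snps_med Number of mediator-specific SNPs.
#' @param n_exp,n_med,n_out GWAS sample sizes for the three traits.
#' @param theta_direct Exposure -> outcome effect not through the mediator.
#' @param alpha Exposure -> mediator effect (the true beta(A)).
#' @param b_med Mediator -> outcome effect (the true beta(B)).
#' @param pleio_frac Fraction of exposure SNPs with a direct outcome effect.
#' @param pleio_sd SD of the pleiotropy offsets.
#' @param pleio_directional If `TRUE` the offsets have mean `pleio_sd`
#'   (directional pleiotropy), else mean 0 (balanced).
#' @param eaf_range Interval within (0,1) from which allele frequencies are
#'   drawn uniformly.
#' @param exposure_effect_sd SD of the true per-allele exposure effects.
#' @param med_effect_sd SD of mediator-specific effects.
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param ld_r2 Off-diagonal r-squared within an LD block.
#' @param allele_noise Fraction of outcome records emitted with swapped and/or
#'   strand-complemented alleles (and beta/eaf adjusted accordingly), to
#'   exercise harmonisation.
#' @param snp_spacing_kb Physical spacing of consecutive SNPs.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 30L, n_snps_med = 30L,
                       n_exp = 50000L, n_med = 50000L, n_out = 50000L,
                       theta_direct = 0.1, alpha = 0.5, b_med = 0.2,
                       pleio_frac = 0, pleio_sd = 0.05,
                       pleio_directional = FALSE,
                       eaf_range = c(0.1, 0.9),
                       exposure_effect_sd = 0.08, med_effect_sd = 0.08,
                       ld_block_size = 1L, ld_r2 = 0,
                       allele_noise = 0, snp_spacing_kb = 100L,
                       seed = NULL) {
  cfg <- list(n_snps = as.integer(n_snps), n_snps_med = as.integer(n_snps_med),
              n_exp = as.integer(n_exp), n_med = as.integer(n_med),
              n_out = as.integer(n_out),
              theta_direct = theta_direct, alpha = alpha, b_med = b_med,
              pleio_frac = pleio_frac, pleio_sd = pleio_sd,
              pleio_directional = isTRUE(pleio_directional),
              eaf_range = as.numeric(eaf_range),
              exposure_effect_sd = exposure_effect_sd,
              med_effect_sd = med_effect_sd,
              ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
              allele_noise = allele_noise,
              snp_spacing_kb = as.integer(snp_spacing_kb),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) stop_mrm("mrm_config_error", msg)
  if (cfg$n_snps < 1L) bad("n_snps must be positive")
  if (cfg$n_snps_med < 0L) bad("n_snps_med must be non-negative")
  if (any(c(cfg$n_exp, cfg$n_med, cfg$n_out) < 1L)) bad("sample sizes must be positive")
  for (f in c("pleio_frac", "ld_r2", "allele_noise"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(paste(f, "must lie in [0,1]"))
  r <- cfg$eaf_range
  if (length(r) != 2L || r[1] >= r[2] || r[1] <= 0 || r[2] >= 1)
    bad("eaf_range must be a non-empty sub-interval of (0,1)")
  if (cfg$exposure_effect_sd <= 0) bad("exposure_effect_sd must be positive")
  if (cfg$pleio_sd < 0) bad("pleio_sd must be non-negative")
  if (cfg$ld_block_size < 1L) bad("ld_block_size must be positive")
  invisible(cfg)
}

# Non-palindromic ordered allele pairs.
.allele_pairs <- matrix(c("A","C", "A","G", "C","A", "C","T",
                          "G","A", "G","T", "T","C", "T","G"),
                        ncol = 2L, byrow = TRUE)

#' Simulate an exposure/mediator/outcome summary-statistics triplet
#'
#' Draws one realisation of the generative model described in [sim_config()]
#' and returns the three panels, a block-diagonal LD matrix and the ground
#' truth.  All emitted variants are non-palindromic so that harmonisation is
#' always unambiguous; palindromic handling is exercised by dedicated
#' fixtures, not by the generator.
#'
#' @param config A [sim_config()].
#' @param exposure_id,mediator_id,outcome_id Trait identifiers.
#' @return List with elements `exposure`, `mediator`, `outcome`
#'   ([gwas_panel()]s), `ld` (an `ld_matrix`) and `truth` (generative record:
#'   `gamma`, `delta`, `u`, `pleio_idx`, `theta_total`, `config`).
#' @export
simulate_triplet <- function(config = sim_config(),
                             exposure_id = "exposure",
                             mediator_id = "mediator",
                             outcome_id = "outcome") {
  validate_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    m <- cfg$n_snps + cfg$n_snps_med
    snp_id <- sprintf("rs%06d", seq_len(m))
    pos <- as.integer(seq_len(m)) * cfg$snp_spacing_kb * 1000L
    pair <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                          drop = FALSE]
    eaf <- stats::runif(m, cfg$eaf_range[1], cfg$eaf_range[2])

    gamma <- c(stats::rnorm(cfg$n_snps, 0, cfg$exposure_effect_sd),
               rep(0, cfg$n_snps_med))
    delta <- c(rep(0, cfg$n_snps),
               if (cfg$n_snps_med > 0)
                 stats::rnorm(cfg$n_snps_med, 0, cfg$med_effect_sd) else numeric(0))
    u <- rep(0, m)
    n_pleio <- round(cfg$pleio_frac * cfg$n_snps)
    pleio_idx <- if (n_pleio > 0) sort(sample.int(cfg$n_snps, n_pleio)) else integer(0)
    if (n_pleio > 0) {
      mu_p <- if (cfg$pleio_directional) cfg$pleio_sd else 0
      u[pleio_idx] <- stats::rnorm(n_pleio, mu_p, cfg$pleio_sd)
    }
    theta_total <- cfg$theta_direct + cfg$alpha * cfg$b_med

    true_exp <- gamma
    true_med <- cfg$alpha * gamma + delta
    true_out <- theta_total * gamma + cfg$b_med * delta + u

    make <- function(true_beta, n, trait_id, trait_type) {
      se <- 1 / sqrt(2 * eaf * (1 - eaf) * n)
      beta <- true_beta + stats::rnorm(m) * se
      gwas_panel(trait_id, trait_type, data.frame(
        snp_id = snp_id, chrom = "1", pos = pos,
        effect_allele = pair[, 1], other_allele = pair[, 2],
        eaf = eaf, beta = beta, se = se,
        # floor at the smallest positive double: panels require pval in (0,1]
        pval = pmax(z_to_p(beta / se), .Machine$double.xmin),
        n = n, stringsAsFactors = FALSE), sample_size = n)
    }
    exposure <- make(true_exp, cfg$n_exp, exposure_id, "continuous")
    mediator <- make(true_med, cfg$n_med, mediator_id, "continuous")
    outcome <- make(true_out, cfg$n_out, outcome_id, "binary")

    if (cfg$allele_noise > 0) {
      k <- round(cfg$allele_noise * m)
      if (k > 0) {
        idx <- sort(sample.int(m, k))
        mode <- sample(c("swap", "comp", "comp_swap"), k, replace = TRUE)
        d <- outcome$data
        sw <- idx[mode != "comp"]
        d[sw, c("effect_allele", "other_allele")] <-
          d[sw, c("other_allele", "effect_allele")]
        d$beta[sw] <- -d$beta[sw]
        d$eaf[sw] <- 1 - d$eaf[sw]
        cp <- idx[mode != "swap"]
        d$effect_allele[cp] <- revcomp(d$effect_allele[cp])
        d$other_allele[cp] <- revcomp(d$other_allele[cp])
        outcome$data <- d
      }
    }

    ld <- block_ld_matrix(snp_id, cfg$ld_block_size, cfg$ld_r2)
    list(exposure = exposure, mediator = mediator, outcome = outcome, ld = ld,
         truth = list(gamma = gamma, delta = delta, u = u,
                      pleio_idx = pleio_idx, eaf = eaf,
                      theta_total = theta_total, config = cfg,
                      seed = cfg$seed))
  })
}

#' Block-diagonal LD matrix
#'
#' @param snp_ids SNP identifiers (defines matrix order).
#' @param block_size SNPs per block.
#' @param r2 Off-diagonal r-squared within a block.
#' @return An `ld_matrix`: list with `snp_ids` and the symmetric `r2` matrix
#'   (unit diagonal).
#' @export
block_ld_matrix <- function(snp_ids, block_size = 1L, r2 = 0) {
  m <- length(snp_ids)
  block <- ceiling(seq_len(m) / block_size)
  R <- outer(block, block, function(a, b) ifelse(a == b, r2, 0))
  diag(R) <- 1
  dimnames(R) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = R), class = "ld_matrix")
}

#' Simulate a set of exposure panels against one shared outcome
#'
#' Each config contributes an exposure panel on its own disjoint SNP segment;
#' with `shared_outcome = TRUE` the per-config outcome records are
#' concatenated into a single outcome panel over the union of SNPs (segments
#' are disjoint, so the combined panel is a valid joint GWAS).  Used as a
#' multi-trait screening fixture.
#'
#' @param configs List of [sim_config()]s, one per exposure; trait ids are
#'   `exposure_ids[i]`.
#' @param shared_outcome Emit a single combined outcome panel.
#' @param exposure_ids Trait identifiers (must be unique).
#' @param outcome_id Identifier for the shared outcome.
#' @return List with `exposures` (list of panels), `outcome` (panel or NULL),
#'   `ld` (combined `ld_matrix`) and `truths`.
#' @export
simulate_panel_set <- function(configs, shared_outcome = TRUE,
                               exposure_ids = sprintf("exposure_%02d",
                                                      seq_along(configs)),
                               outcome_id = "outcome") {
  if (length(configs) == 0L)
    stop_mrm("mrm_config_error", "need at least one config")
  if (anyDuplicated(exposure_ids))
    stop_mrm("mrm_config_error", "duplicate exposure trait ids")
  exposures <- vector("list", length(configs))
  out_rows <- list(); truths <- list(); ids <- character(0)
  offset <- 0L
  for (i in seq_along(configs)) {
    tri <- simulate_triplet(configs[[i]], exposure_id = exposure_ids[i],
                            outcome_id = outcome_id)
    relabel <- function(panel) {
      k <- nrow(panel$data)
      panel$data$snp_id <- sprintf("rs%06d", offset + seq_len(k))
      panel$data$pos <- panel$data$pos + offset * 1000000L
      panel
    }
    exposures[[i]] <- relabel(tri$exposure)
    out <- relabel(tri$outcome)
    out_rows[[i]] <- out$data
    truths[[i]] <- tri$truth
    ids <- c(ids, exposures[[i]]$data$snp_id)
    offset <- offset + nrow(tri$exposure$data)
  }
  names(exposures) <- exposure_ids
  outcome <- NULL
  if (shared_outcome) {
    d <- do.call(rbind, out_rows)
    outcome <- gwas_panel(outcome_id, "binary", d,
                          sample_size = max(d$n))
  }
  ld <- block_ld_matrix(ids,
                        block_size = configs[[1]]$ld_block_size,
                        r2 = configs[[1]]$ld_r2)
  list(exposures = exposures, outcome = outcome, ld = ld, truths = truths)
}

#' Write / read an LD matrix as TSV
#'
#' Square tab-separated layout: header row of SNP ids, then one row per SNP
#' with its id in the first column.
#' @param ld An `ld_matrix`.
#' @param path File path.
#' @return `path` (write) or an `ld_matrix` (read).
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  out <- cbind(data.frame(snp_id = ld$snp_ids, stringsAsFactors = FALSE),
               as.data.frame(ld$r2))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(d$snp_id)
  R <- as.matrix(d[, -1, drop = FALSE])
  dimnames(R) <- list(ids, ids)
  structure(list(snp_ids = ids, r2 = R), class = "ld_matrix")
}
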