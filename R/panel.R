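#' GWAS summary-statistics panels
#'
#' A `gwas_panel` holds one trait's per-variant summary associations in the
#' package's canonical 10-column dialect: `snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' Effects for binary traits are on the log-odds scale.
#'
#' @param trait_id Character scalar identifying the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param data Data frame with the ten canonical columns (any order).
#' @param sample_size GWAS sample size; defaults to the maximum per-record
#'   `n` (per-record `n` may vary).
#' @param strict If `TRUE` (default), any invalid record is an error naming
#'   the offending rows; if `FALSE`, invalid records are dropped and reported
#'   via the `"diagnostics"` attribute.
#' @return An object of class `gwas_panel`.
#' @export
gwas_panel <- function(trait_id, trait_type = c("continuous", "binary"),
                       data, sample_size = NULL, strict = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  missing_cols <- setdiff(sumstats_columns(), names(data))
  if (length(missing_cols) > 0L)
    stop_mrm("mrm_format_error", paste0(
      "panel '", trait_id, "' is missing required column(s): ",
      paste(missing_cols, collapse = ", ")))
  data <- as.data.frame(data)[, sumstats_columns()]
  data$snp_id <- as.character(data$snp_id)
  data$chrom <- as.character(data$chrom)
  data$pos <- as.integer(data$pos)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) data[[col]] <- as.numeric(data[[col]])
  data$n <- as.integer(data$n)

  bad <- validate_records(data)
  if (length(bad$rows) > 0L) {
    msg <- paste0("panel '", trait_id, "': ", length(bad$rows),
                  " invalid record(s): ",
                  paste(utils::head(bad$detail, 5L), collapse = "; "),
                  if (length(bad$detail) > 5L) " ...")
    if (strict) stop_mrm("mrm_validation_error", msg)
    data <- data[-bad$rows, , drop = FALSE]
  }
  if (nrow(data) == 0L)
    stop_mrm("mrm_validation_error",
             paste0("panel '", trait_id, "' has no valid records"))
  if (anyDuplicated(data$snp_id))
    stop_mrm("mrm_validation_error",
             paste0("panel '", trait_id, "' has duplicated snp_id"))
  rownames(data) <- NULL
  structure(list(
    trait_id = trait_id,
    trait_type = trait_type,
    sample_size = as.integer(sample_size %||% max(data$n)),
    data = data
  ), class = "gwas_panel",
  diagnostics = if (length(bad$rows)) bad$detail else character(0))
}

sumstats_columns <- function() {
  c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pval", "n")
}

# Row-level invariant checks; returns offending row indices plus messages.
validate_records <- function(d) {
  checks <- list(
    "pos must be a positive integer"    = is.na(d$pos) | d$pos < 1L,
    "alleles must be over {A,C,G,T}"    = !grepl("^[ACGT]+$", d$effect_allele) |
                                          !grepl("^[ACGT]+$", d$other_allele),
    "effect_allele must differ from other_allele" =
                                          d$effect_allele == d$other_allele,
    "eaf must lie in (0,1)"             = !is.na(d$eaf) & (d$eaf <= 0 | d$eaf >= 1),
    "beta must be finite"               = !is.finite(d$beta),
    "se must be > 0"                    = is.na(d$se) | d$se <= 0,
    "pval must lie in (0,1]"            = is.na(d$pval) | d$pval <= 0 | d$pval > 1,
    "n must be a positive integer"      = is.na(d$n) | d$n < 1L
  )
  rows <- integer(0); detail <- character(0)
  for (what in names(checks)) {
    idx <- which(checks[[what]])
    if (length(idx)) {
      rows <- union(rows, idx)
      detail <- c(detail, paste0("row ", idx, ": ", what))
    }
  }
  list(rows = sort(rows), detail = detail)
}

#' @export
print.gwas_panel <- function(x, ...) {
  cat(sprintf("<gwas_panel> %s (%s), %d variants, n = %d\n",
              x$trait_id, x$trait_type, nrow(x$data), x$sample_size))
  print(utils::head(x$data, 4L))
  if (nrow(x$data) > 4L) cat("  ...\n")
  invisible(x)
}

subset_panel <- function(panel, snp_ids) {
  keep <- panel$data$snp_id %in% snp_ids
  panel$data <- panel$data[keep, , drop = FALSE]
  rownames(panel$data) <- NULL
  panel
}

#' Read a summary-statistics table
#'
#' Reads a tab-separated file in the canonical dialect (ten required columns
#' in any header order, UTF-8, `.` decimal separator) into a [gwas_panel()].
#'
#' @inheritParams gwas_panel
#' @param path Path to a TSV file.
#' @return A `gwas_panel`.
#' @export
read_sumstats <- function(path, trait_id, trait_type = c("continuous", "binary"),
                          sample_size = NULL, strict = TRUE) {
  if (!file.exists(path))
    stop_mrm("mrm_format_error", paste0("file not found: ", path))
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  gwas_panel(trait_id, trait_type, d, sample_size = sample_size, strict = strict)
}

#' Write a summary-statistics table
#'
#' Writes a panel in the canonical column order with full numeric precision
#' (17 significant digits), so `read_sumstats(write_sumstats(p))` round-trips
#' exactly at double precision.
#'
#' @param panel A [gwas_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(panel, path) {
  stopifnot(inherits(panel, "gwas_panel"))
  if (nrow(panel$data) == 0L)
    stop_mrm("mrm_validation_error", "refusing to write an empty panel")
  d <- panel$data
  out <- data.frame(
    snp_id = d$snp_id, chrom = d$chrom, pos = d$pos,
    effect_allele = d$effect_allele, other_allele = d$other_allele,
    eaf = fmt_num(d$eaf), beta = fmt_num(d$beta), se = fmt_num(d$se),
    pval = fmt_num(d$pval), n = d$n,
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_mrm("mrm_io_error", paste0("cannot write ", path, ": ",
                                    conditionMessage(ok)))
  invisible(path)
}
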