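# Internal helpers: condition constructors, RNG scoping, allele arithmetic.

stop_mrm <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mrm_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @noRd
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` evaluates in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Reverse complement of allele strings (vectorised); alleles over {A,C,G,T}.
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", toupper(x))
  one <- nchar(comp) == 1L
  if (all(one)) return(comp)
  comp[!one] <- vapply(strsplit(comp[!one], ""), function(s)
    paste(rev(s), collapse = ""), character(1))
  comp
}

is_palindromic <- function(ea, oa) toupper(oa) == revcomp(ea)

# Full-precision numeric formatting for round-trip-safe TSV output.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.17g", v)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
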