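#' Run a configured end-to-end analysis
#'
#' Executes, per the JSON config: optional simulation of a synthetic panel
#' set, the forward screen, the reverse screen and the mediation scan, and
#' writes results TSVs, audit TSVs, a log file recording the seed,
#' parameters and per-stage counts, and a machine-readable JSON run summary.
#' Unknown config keys are an error (strict parsing, to catch typos).
#'
#' Recognised top-level keys: `seed`, `out_dir`, `simulate` (either
#' [sim_config()] fields plus `n_exposures`, or `panels` with file paths
#' `exposures`, `mediators`, `outcome`, `ld`), `selection` (`profile` plus
#' [selection_params()] overrides), `fdr_threshold`, `mediation`
#' (`run`, `alpha`), `presso` (`n_sim`), `reverse` (`run`).
#'
#' @param config_path Path to a JSON configuration file.
#' @return The run directory path, invisibly; outputs are written there.
#' @export
run_config <- function(config_path) {
  if (!file.exists(config_path))
    stop_mrm("mrm_config_error", paste0("config not found: ", config_path))
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  known <- c("seed", "out_dir", "simulate", "selection", "fdr_threshold",
             "mediation", "presso", "reverse")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_mrm("mrm_config_error", paste0("unknown config key(s): ",
                                        paste(unknown, collapse = ", ")))
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- cfg$out_dir %||% "mrmediate_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("mrmediate %s | seed %d | %s",
          as.character(utils::packageVersion("mrmediate")), seed,
          format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  # --- selection parameters -------------------------------------------------
  sel_cfg <- as.list(cfg$selection %||% list())
  profile <- sel_cfg$profile %||% "default"
  sel_cfg$profile <- NULL
  sel_known <- names(formals(selection_params))
  unknown <- setdiff(names(sel_cfg), sel_known)
  if (length(unknown))
    stop_mrm("mrm_config_error", paste0("unknown selection key(s): ",
                                        paste(unknown, collapse = ", ")))
  params <- do.call(selection_profile, c(list(profile = profile), sel_cfg))
  fdr_threshold <- cfg$fdr_threshold %||% 0.1
  presso_nsim <- as.integer((cfg$presso %||% list())$n_sim %||% 1000L)
  logline("selection profile: %s; fdr_threshold: %g; presso n_sim: %d",
          profile, fdr_threshold, presso_nsim)

  # --- inputs ---------------------------------------------------------------
  sim_cfg <- as.list(cfg$simulate %||% list())
  if (!is.null(sim_cfg$panels)) {
    paths <- sim_cfg$panels
    exposures <- lapply(paths$exposures, function(p)
      read_sumstats(p, trait_id = sub("[.][^.]*$", "", basename(p))))
    names(exposures) <- vapply(exposures, `[[`, character(1), "trait_id")
    mediators <- lapply(paths$mediators %||% character(0), function(p)
      read_sumstats(p, trait_id = sub("[.][^.]*$", "", basename(p))))
    names(mediators) <- vapply(mediators, `[[`, character(1), "trait_id")
    outcome <- read_sumstats(paths$outcome, trait_id = "outcome",
                             trait_type = "binary")
    ld <- read_ld_matrix(paths$ld)
  } else {
    n_exposures <- as.integer(sim_cfg$n_exposures %||% 3L)
    sim_cfg$n_exposures <- NULL
    sim_known <- names(formals(sim_config))
    unknown <- setdiff(names(sim_cfg), sim_known)
    if (length(unknown))
      stop_mrm("mrm_config_error", paste0("unknown simulate key(s): ",
                                          paste(unknown, collapse = ", ")))
    tris <- lapply(seq_len(n_exposures), function(i) {
      simulate_triplet(do.call(sim_config, utils::modifyList(
        sim_cfg, list(seed = seed + i))),
        exposure_id = sprintf("exposure_%02d", i),
        mediator_id = sprintf("mediator_%02d", i),
        outcome_id = "outcome")
    })
    # disjoint SNP segments per triplet; shared outcome = concatenation
    offset <- 0L
    relabel <- function(panel, offset) {
      panel$data$snp_id <- sprintf("rs%06d",
                                   offset + seq_len(nrow(panel$data)))
      panel$data$pos <- panel$data$pos + offset * 1000000L
      panel
    }
    exposures <- list(); mediators <- list(); out_rows <- list()
    for (i in seq_along(tris)) {
      k <- nrow(tris[[i]]$exposure$data)
      exposures[[i]] <- relabel(tris[[i]]$exposure, offset)
      mediators[[i]] <- relabel(tris[[i]]$mediator, offset)
      out_rows[[i]] <- relabel(tris[[i]]$outcome, offset)$data
      offset <- offset + k
    }
    names(exposures) <- vapply(exposures, `[[`, character(1), "trait_id")
    names(mediators) <- vapply(mediators, `[[`, character(1), "trait_id")
    d <- do.call(rbind, out_rows)
    outcome <- gwas_panel("outcome", "binary", d)
    ld <- block_ld_matrix(d$snp_id,
                          block_size = tris[[1]]$truth$config$ld_block_size,
                          r2 = tris[[1]]$truth$config$ld_r2)
    for (i in seq_along(exposures)) {
      write_sumstats(exposures[[i]], file.path(
        out_dir, paste0(exposures[[i]]$trait_id, ".tsv")))
      write_sumstats(mediators[[i]], file.path(
        out_dir, paste0(mediators[[i]]$trait_id, ".tsv")))
    }
    write_sumstats(outcome, file.path(out_dir, "outcome.tsv"))
    write_ld_matrix(ld, file.path(out_dir, "ld.tsv"))
    logline("simulated %d exposure triplet(s), %d SNPs total",
            n_exposures, nrow(d))
  }

  # --- forward screen -------------------------------------------------------
  fwd <- mr_screen(exposures, outcome, ld, params,
                   fdr_threshold = fdr_threshold,
                   presso_nsim = presso_nsim, seed = seed)
  write_screen(fwd, file.path(out_dir, "screen_forward.tsv"))
  logline("forward screen: %d trait(s), %d significant",
          nrow(fwd), sum(fwd$significant, na.rm = TRUE))

  # --- reverse screen -------------------------------------------------------
  rev_rows <- NULL
  if (isTRUE((cfg$reverse %||% list(run = TRUE))$run %||% TRUE)) {
    rev_rows <- reverse_screen(outcome, exposures, ld,
                               fdr_threshold = fdr_threshold,
                               presso_nsim = presso_nsim, seed = seed)
    write_screen(rev_rows, file.path(out_dir, "screen_reverse.tsv"))
    logline("reverse screen: %d trait(s), %d significant",
            nrow(rev_rows), sum(rev_rows$significant, na.rm = TRUE))
  }

  # --- mediation scan -------------------------------------------------------
  med_cfg <- as.list(cfg$mediation %||% list())
  med_tab <- NULL
  if (isTRUE(med_cfg$run %||% TRUE) && length(mediators) > 0) {
    med_params <- selection_profile("mediation",
      clump_window_kb = params$clump_window_kb, clump_r2 = params$clump_r2)
    med <- mediation_scan(exposures, mediators, outcome, ld,
                          params = med_params,
                          alpha = med_cfg$alpha %||% 0.1,
                          presso_nsim = presso_nsim, seed = seed)
    med_tab <- mediation_table(med)
    if (!is.null(med_tab))
      utils::write.table(med_tab, file.path(out_dir, "mediation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(attr(med, "skipped"),
                       file.path(out_dir, "mediation_skipped.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logline("mediation scan: %d result(s), %d pair(s) skipped",
            length(med), nrow(attr(med, "skipped")))
  }

  summary <- list(
    seed = seed, selection_profile = profile,
    fdr_threshold = fdr_threshold, presso_n_sim = presso_nsim,
    n_exposures = length(exposures),
    forward_significant = sum(fwd$significant, na.rm = TRUE),
    reverse_significant = if (is.null(rev_rows)) NA_integer_
                          else sum(rev_rows$significant, na.rm = TRUE),
    mediation_results = if (is.null(med_tab)) 0L else nrow(med_tab))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `inst/cli/mrmediate` script:
#' `simulate`, `screen`, `run` (config-driven; see [run_config()]).
#' Arguments are `--key value` pairs.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
mr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mrmediate <command> [--key value ...]",
    "  run      --config <path.json>",
    "  simulate --out <dir> [--seed <int>] [--n-snps <int>]",
    "  screen   --config <path.json>   (alias of run)",
    sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]
  rest <- args[-1L]
  opts <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[[i]])
    opts[[gsub("-", "_", key)]] <- if (i + 1L <= length(rest)) rest[[i + 1L]] else ""
    i <- i + 2L
  }
  switch(cmd,
    run = , screen = {
      run_config(opts$config %||% stop_mrm("mrm_config_error",
                                           "--config is required"))
      invisible(0L)
    },
    simulate = {
      out <- opts$out %||% "mrmediate_sim"
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      tri <- simulate_triplet(sim_config(
        n_snps = as.integer(opts$n_snps %||% 30L),
        seed = as.integer(opts$seed %||% 1L)))
      write_sumstats(tri$exposure, file.path(out, "exposure.tsv"))
      write_sumstats(tri$mediator, file.path(out, "mediator.tsv"))
      write_sumstats(tri$outcome, file.path(out, "outcome.tsv"))
      write_ld_matrix(tri$ld, file.path(out, "ld.tsv"))
      jsonlite::write_json(tri$truth[c("theta_total", "seed")],
                           file.path(out, "truth.json"), auto_unbox = TRUE,
                           digits = NA)
      invisible(0L)
    },
    { message("unknown command: ", cmd, "\n", usage); invisible(1L) })
}
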