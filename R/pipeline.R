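#' @title Pipeline front-end and reproduction recipes
#' @description Ties the stages together behind a validated run
#'   configuration, including the two built-in recipes that recompute the
#'   packaged reference-table summaries, and writes a manifest sufficient
#'   to reproduce outputs bit for bit. A thin command-line wrapper over
#'   these functions ships in `inst/scripts/venomont-cli.R`.
#' @name cli
NULL

#' Reproduce the consensus ontogeny calls from the packaged flag tables
#'
#' Applies the majority-consensus rule to the packaged per-population
#' outlier flags and confirms the calls against the packaged DESeq and
#' DESeq2 detections.
#'
#' @param min_outlier,min_same_direction Consensus rule parameters
#'   (defaults 3 and 3).
#' @param fdr_threshold FDR cutoff for the detection tables (default 0.1).
#' @return A list: `calls` (the `consensus_calls` data frame with
#'   `confirmed` filled), `n_up`, `n_down`, `n_confirmed`,
#'   `n_detected_deseq`, `n_detected_deseq2`.
#' @export
repro_table5 <- function(min_outlier = 3L, min_same_direction = 3L,
                         fdr_threshold = 0.1) {
  flags <- load_fixture("table5_outliers")
  deseq <- load_fixture("table5_deseq", fdr_threshold = fdr_threshold)
  deseq2 <- load_fixture("table5_deseq2", fdr_threshold = fdr_threshold)
  calls <- consensus_call(flags, min_outlier, min_same_direction)
  calls <- intersect_detections(calls, list(deseq, deseq2))
  list(calls = calls,
       n_up = sum(calls$call == "up"),
       n_down = sum(calls$call == "down"),
       n_confirmed = sum(calls$confirmed),
       n_detected_deseq = sum(deseq$detected),
       n_detected_deseq2 = sum(deseq2$detected))
}

#' Reproduce the presence/absence summaries from the packaged matrices
#'
#' @return A list with `full` and `subsampled` [summarize_absence()]
#'   results for the all-reads and 9.5M-read matrices.
#' @export
repro_table4 <- function() {
  meta <- canonical_sample_meta(
    colnames(load_fixture("table4_full")$present))
  list(full = summarize_absence(load_fixture("table4_full"), meta),
       subsampled = summarize_absence(load_fixture("table4_sub"), meta))
}

run_config_defaults <- function() {
  list(stage = NULL, out_dir = ".", seed = 1L, verbosity = 1L,
       overlap = 120L, min_reads = 200L,
       cluster_threshold = 0.01, linkage = "single",
       min_depth = 5L, max_low_fraction = 0.10, max_mismatches = 2L,
       subsample_n = NULL,
       percentile = 99, min_outlier = 3L, min_same_direction = 3L,
       fdr_threshold = 0.1,
       trim = 0, isotonic = FALSE,
       input = NULL, inputs = list())
}

#' Validate a pipeline run configuration
#'
#' Unknown keys are rejected and every parameter is checked against its
#' documented domain before any stage runs.
#'
#' @param ... Configuration values overriding the defaults; `stage` is
#'   required and must be one of "repro-table4", "repro-table5", "ld50".
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  stages <- c("repro-table4", "repro-table5", "ld50")
  if (is.null(cfg$stage) || !(cfg$stage %in% stages))
    stop("stage must be one of: ", paste(stages, collapse = ", "))
  stopifnot(cfg$overlap >= 1, cfg$min_reads >= 0,
            cfg$cluster_threshold > 0, cfg$cluster_threshold < 0.5,
            cfg$min_depth >= 1,
            cfg$max_low_fraction > 0, cfg$max_low_fraction < 1,
            cfg$max_mismatches >= 0,
            cfg$min_outlier >= 1, cfg$min_same_direction >= 1,
            cfg$fdr_threshold > 0, cfg$fdr_threshold < 1,
            cfg$trim >= 0, cfg$trim <= 0.1)
  if (cfg$percentile <= 0 || cfg$percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  class(cfg) <- "run_config"
  cfg
}

#' Execute a configured pipeline stage
#'
#' Runs the requested stage, writes its result files under
#' `config$out_dir`, and writes `manifest.json` recording parameters,
#' seeds, input digests and the package version, sufficient to reproduce
#' the outputs bit for bit.
#'
#' @param config A [run_config()].
#' @return Invisibly, the stage result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  result <- switch(config$stage,
    "repro-table5" = {
      res <- repro_table5(config$min_outlier, config$min_same_direction,
                          config$fdr_threshold)
      write_results(res$calls, file.path(config$out_dir, "consensus.tsv"),
                    "tsv")
      res
    },
    "repro-table4" = {
      res <- repro_table4()
      write_results(data.frame(
        half = c("full", "subsampled"),
        n_variable = c(res$full$n_variable_transcripts,
                       res$subsampled$n_variable_transcripts),
        mean_missing = c(res$full$overall_mean_missing,
                         res$subsampled$overall_mean_missing),
        adult_mean = c(res$full$adult_mean, res$subsampled$adult_mean),
        juvenile_mean = c(res$full$juvenile_mean,
                          res$subsampled$juvenile_mean),
        welch_p = c(res$full$welch_p, res$subsampled$welch_p)),
        file.path(config$out_dir, "absence_summary.tsv"), "tsv")
      res
    },
    "ld50" = {
      if (is.null(config$input)) stop("ld50 stage requires input CSV")
      tab <- utils::read.csv(config$input)
      drt <- dose_response_table(tab$dose, tab$n, tab$deaths)
      est <- spearman_karber_ld50(drt, trim = config$trim,
                                  isotonic = config$isotonic)
      write_results(data.frame(ld50 = est$ld50, log10_se = est$log10_se,
                               warnings = paste(est$warnings,
                                                collapse = "; ")),
                    file.path(config$out_dir, "ld50.tsv"), "tsv")
      est
    })
  inputs <- c(config$input, unlist(config$inputs))
  digests <- if (length(inputs) > 0) as.list(tools::md5sum(inputs)) else NULL
  manifest <- list(
    package = "venomont",
    version = as.character(utils::packageVersion("venomont")),
    stage = config$stage,
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("input", "inputs"))],
    input_digests = digests,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}
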