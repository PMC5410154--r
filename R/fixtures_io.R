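#' @title Data model and file I/O for the ontogeny pipeline
#' @description Lightweight S3 containers for the tables the pipeline
#'   consumes and produces, readers/writers for them, and packaged
#'   transcriptions of the published reference tables for
#'   *Crotalus adamanteus* (toxin TPM abundances, presence/absence calls,
#'   and per-population outlier/DE flags).
#' @name fixtures_io
NULL

POPULATIONS <- c("ANF", "BR", "CAL", "ENP", "LSG")
AGE_CLASSES <- c("adult", "juvenile")
GLANDS <- c("left", "right", "pooled")
FLAG_LEVELS <- c("up", "down", "none")

#' Build sample metadata
#'
#' @param sample_id Character vector of sample identifiers.
#' @param population Population codes, one of ANF, BR, CAL, ENP, LSG.
#' @param age_class "adult" or "juvenile".
#' @param gland "left", "right", or "pooled".
#' @return A data frame with one row per sample.
#' @export
sample_meta <- function(sample_id, population, age_class, gland = "pooled") {
  meta <- data.frame(sample_id = as.character(sample_id),
                     population = as.character(population),
                     age_class = as.character(age_class),
                     gland = rep_len(as.character(gland), length(sample_id)),
                     stringsAsFactors = FALSE)
  bad <- setdiff(meta$population, POPULATIONS)
  if (length(bad) > 0)
    stop("unknown population(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(POPULATIONS, collapse = ", "))
  if (!all(meta$age_class %in% AGE_CLASSES))
    stop("age_class must be one of: ", paste(AGE_CLASSES, collapse = ", "))
  if (!all(meta$gland %in% GLANDS))
    stop("gland must be one of: ", paste(GLANDS, collapse = ", "))
  key <- paste(meta$population, meta$age_class, meta$gland)
  if (anyDuplicated(key))
    stop("duplicate (population, age_class, gland) combination")
  meta
}

# Metadata for the ten pooled-gland transcriptomes, ids like "ANF-A".
canonical_sample_meta <- function(sample_ids) {
  parts <- strsplit(sample_ids, "-", fixed = TRUE)
  sample_meta(sample_ids,
              population = vapply(parts, `[`, "", 1L),
              age_class = ifelse(vapply(parts, `[`, "", 2L) == "A",
                                 "adult", "juvenile"),
              gland = "pooled")
}

#' Construct an expression matrix (transcripts x samples, TPM)
#'
#' @param values Non-negative numeric matrix; rownames are transcript ids,
#'   colnames are sample ids.
#' @param samples Sample metadata from [sample_meta()]; derived from the
#'   column names when omitted.
#' @param full_composition If TRUE the matrix is a complete transcriptome and
#'   each column must sum to one million TPM (within 1e-6 relative
#'   tolerance). Toxin-only slices use FALSE.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples = NULL, full_composition = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have transcript rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate transcript id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyNA(values)) stop("missing expression value")
  if (any(values < 0)) stop("negative expression value")
  if (is.null(samples)) samples <- canonical_sample_meta(colnames(values))
  if (!identical(samples$sample_id, colnames(values)))
    stop("sample metadata does not match matrix columns")
  if (full_composition) {
    sums <- colSums(values)
    if (any(abs(sums - 1e6) > 1e-6 * 1e6))
      stop("full-composition columns must sum to 1,000,000 TPM")
  }
  structure(list(values = values, samples = samples,
                 full_composition = full_composition),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d transcripts x %d samples (TPM)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a transcripts-by-samples expression table
#'
#' The file must have a header row of sample ids and transcript ids in the
#' first column; separators may be tabs or commas.
#'
#' @param path Path to a TSV/CSV file.
#' @param metadata Optional [sample_meta()] data frame; derived from the
#'   header when omitted.
#' @param full_composition Passed to [expression_matrix()].
#' @return An `expression_matrix`.
#' @export
read_expression_table <- function(path, metadata = NULL,
                                  full_composition = FALSE) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("no data rows in ", path)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("no data rows in ", path)
  ids <- tab[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate transcript id '", dup[1L], "' in ", path)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- matrix(suppressWarnings(as.numeric(vals)),
                nrow(vals), ncol(vals), dimnames = dimnames(vals))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-numeric value at row %d ('%s'), column '%s'",
                 bad[1L], ids[bad[1L]], colnames(vals)[bad[2L]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at row %d ('%s'), column '%s'",
                 bad[1L], ids[bad[1L]], colnames(vals)[bad[2L]]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  expression_matrix(num, samples = metadata,
                    full_composition = full_composition)
}

#' Build a transcript catalog
#'
#' Toxin families are derived from transcript ids by stripping the trailing
#' paralog number (e.g. "SVMPIII-5" belongs to family "SVMPIII").
#'
#' @param transcript_id Character vector of transcript ids.
#' @param is_toxin Logical vector (recycled).
#' @param cds_length Positive integer coding-sequence lengths (recycled).
#' @param family Optional explicit family labels; derived from ids when NULL.
#' @return A data frame of class `transcript_catalog`.
#' @export
transcript_catalog <- function(transcript_id, is_toxin = TRUE,
                               cds_length = 1000L, family = NULL) {
  if (anyDuplicated(transcript_id)) stop("duplicate transcript id in catalog")
  is_toxin <- rep_len(is_toxin, length(transcript_id))
  cds_length <- rep_len(as.integer(cds_length), length(transcript_id))
  if (any(cds_length < 1L)) stop("cds_length must be >= 1")
  if (is.null(family))
    family <- ifelse(is_toxin, sub("-[0-9]+$", "", transcript_id), "")
  if (any(is_toxin & !nzchar(family)))
    stop("toxin transcripts must have a nonempty family")
  structure(data.frame(transcript_id = transcript_id, is_toxin = is_toxin,
                       family = family, cds_length = cds_length,
                       stringsAsFactors = FALSE),
            class = c("transcript_catalog", "data.frame"))
}

#' Construct a presence/absence matrix
#'
#' @param present Logical matrix, transcripts x transcriptomes; rownames are
#'   transcript ids, colnames transcriptome ids.
#' @return An object of class `presence_absence_matrix` carrying the boolean
#'   body and the per-transcriptome absence counts.
#' @export
presence_absence_matrix <- function(present) {
  stopifnot(is.matrix(present), is.logical(present))
  if (is.null(rownames(present)) || is.null(colnames(present)))
    stop("present must have transcript rownames and transcriptome colnames")
  if (anyNA(present)) stop("missing presence/absence entry")
  structure(list(present = present,
                 absent_counts = colSums(!present)),
            class = "presence_absence_matrix")
}

#' @export
print.presence_absence_matrix <- function(x, ...) {
  cat(sprintf("presence_absence_matrix: %d transcripts x %d transcriptomes\n",
              nrow(x$present), ncol(x$present)))
  cat("absent per transcriptome:",
      paste(x$absent_counts, collapse = " "), "\n")
  invisible(x)
}

#' Construct an outlier flag matrix
#'
#' @param flags Character matrix with entries "up", "down" or "none";
#'   transcripts x populations.
#' @return An object of class `outlier_flag_matrix`.
#' @export
outlier_flag_matrix <- function(flags) {
  stopifnot(is.matrix(flags), is.character(flags))
  if (is.null(rownames(flags)) || is.null(colnames(flags)))
    stop("flags must have transcript rownames and population colnames")
  if (!all(flags %in% FLAG_LEVELS))
    stop("flags must be one of: ", paste(FLAG_LEVELS, collapse = ", "))
  structure(list(flags = flags), class = "outlier_flag_matrix")
}

#' Build detection flags from adjusted p-values
#'
#' A transcript is detected when its adjusted p-value is present (not
#' censored/NA) and strictly below the FDR threshold.
#'
#' @param transcript_id Character vector.
#' @param adjusted_p Numeric adjusted p-values; NA for censored (">0.1") or
#'   undefined entries.
#' @param method Label for the external DE method ("deseq", "deseq2", ...).
#' @param fdr_threshold False-discovery-rate cutoff (default 0.1).
#' @return A data frame of class `detection_flags`.
#' @export
detection_flags <- function(transcript_id, adjusted_p, method,
                            fdr_threshold = 0.1) {
  stopifnot(length(transcript_id) == length(adjusted_p))
  if (any(adjusted_p < 0 | adjusted_p > 1, na.rm = TRUE))
    stop("adjusted_p must lie in [0, 1]")
  structure(data.frame(transcript_id = as.character(transcript_id),
                       method = method,
                       adjusted_p = as.numeric(adjusted_p),
                       detected = !is.na(adjusted_p) &
                         adjusted_p < fdr_threshold,
                       stringsAsFactors = FALSE),
            class = c("detection_flags", "data.frame"))
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "venomont")
  if (!nzchar(p)) stop("fixture file not found: ", file)
  p
}

#' Load a packaged reference table
#'
#' The packaged fixtures transcribe the published *C. adamanteus* reference
#' tables: `table3` (toxin TPM abundances for 59 transcripts across the ten
#' pooled-gland transcriptomes), `table4_full` / `table4_sub`
#' (presence/absence calls using all merged reads and the 9.5M-read
#' subsample), `table5_outliers` (per-population adult/juvenile outlier
#' flags), and `table5_deseq` / `table5_deseq2` (external differential
#' expression detections at FDR 0.1).
#'
#' @param name One of "table3", "table4_full", "table4_sub",
#'   "table5_outliers", "table5_deseq", "table5_deseq2".
#' @param fdr_threshold FDR cutoff applied to the detection fixtures.
#' @return The typed table: an `expression_matrix`,
#'   `presence_absence_matrix`, `outlier_flag_matrix`, or `detection_flags`.
#' @export
load_fixture <- function(name, fdr_threshold = 0.1) {
  valid <- c("table3", "table4_full", "table4_sub", "table5_outliers",
             "table5_deseq", "table5_deseq2")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  switch(name,
    table3 = read_expression_table(fixture_path("table3_toxin_tpm.tsv")),
    table4_full = read_presence_absence(
      fixture_path("table4_presence_full.csv")),
    table4_sub = read_presence_absence(
      fixture_path("table4_presence_sub.csv")),
    table5_outliers = {
      tab <- utils::read.delim(fixture_path("table5_outlier_flags.tsv"),
                               stringsAsFactors = FALSE)
      flags <- as.matrix(tab[, POPULATIONS])
      rownames(flags) <- tab$transcript
      out <- outlier_flag_matrix(flags)
      out$published_consensus <- stats::setNames(tab$consensus, tab$transcript)
      out
    },
    table5_deseq = read_detection_table(fixture_path("table5_deseq.tsv"),
                                        "deseq", fdr_threshold),
    table5_deseq2 = read_detection_table(fixture_path("table5_deseq2.tsv"),
                                         "deseq2", fdr_threshold))
}

# Detection fixture files keep the printed p-value column verbatim; censored
# (">0.1") and undefined ("NA") entries both parse to NA and are never
# counted as detections.
read_detection_table <- function(path, method, fdr_threshold = 0.1) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  suppressWarnings(p <- as.numeric(tab$adjusted_p))
  flags <- detection_flags(tab$transcript, p, method, fdr_threshold)
  flags$log2fc <- as.numeric(tab$log2fc)
  flags
}

#' Read a presence/absence CSV in the reference-table layout
#'
#' Expects "+"/"-" entries and a trailing "# Absent" summary row; the stored
#' summary row must agree with counts recomputed from the boolean body.
#'
#' @param path CSV file path.
#' @return A `presence_absence_matrix`.
#' @export
read_presence_absence <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  is_summary <- tab[[1L]] == "# Absent"
  body <- tab[!is_summary, , drop = FALSE]
  present <- as.matrix(body[, -1L, drop = FALSE]) == "+"
  rownames(present) <- body[[1L]]
  pa <- presence_absence_matrix(present)
  if (any(is_summary)) {
    stored <- as.numeric(tab[is_summary, -1L][1L, ])
    if (!isTRUE(all.equal(unname(pa$absent_counts), stored)))
      stop("stored '# Absent' row disagrees with recomputed counts in ", path)
  }
  pa
}

#' Write a pipeline result to disk
#'
#' All tabular output is UTF-8 with LF line endings and "." as the decimal
#' separator, so written files are bit-stable across platforms.
#'
#' @param obj An `expression_matrix`, `presence_absence_matrix`,
#'   `outlier_flag_matrix`, `detection_flags`, or plain data frame.
#' @param path Output file path.
#' @param format One of "tsv", "csv", "json".
#' @return Invisibly, `path`.
#' @export
write_results <- function(obj, path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  if (format == "json") {
    jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  tab <- as_output_table(obj)
  con <- file(path, open = "wb")  # binary mode keeps LF endings everywhere
  on.exit(close(con))
  utils::write.table(tab, con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

as_output_table <- function(obj) UseMethod("as_output_table")

#' @export
as_output_table.data.frame <- function(obj) obj

#' @export
as_output_table.expression_matrix <- function(obj) {
  data.frame(transcript = rownames(obj$values),
             obj$values, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
as_output_table.presence_absence_matrix <- function(obj) {
  body <- data.frame(transcript = rownames(obj$present),
                     ifelse(obj$present, "+", "-"),
                     check.names = FALSE, stringsAsFactors = FALSE)
  names(body)[-1L] <- colnames(obj$present)
  rbind(body, c("# Absent", as.character(obj$absent_counts)))
}

#' @export
as_output_table.outlier_flag_matrix <- function(obj) {
  data.frame(transcript = rownames(obj$flags), obj$flags,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read an outlier flag TSV written by [write_results()]
#' @param path TSV file path.
#' @return An `outlier_flag_matrix`.
#' @export
read_outlier_flags <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  flags <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(flags) <- tab[[1L]]
  outlier_flag_matrix(flags)
}
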