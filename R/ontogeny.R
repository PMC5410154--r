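#' @title Compositional outlier test for ontogenetic expression change
#' @description The analysis centerpiece: TPM expression is centered
#'   log-ratio (clr) transformed, adult-minus-juvenile clr differences are
#'   computed per population pair, the empirical 99th percentile of the
#'   absolute nontoxin differences serves as the null threshold, and toxins
#'   exceeding it are flagged as outliers. A toxin is called ontogenetically
#'   variable when it is an outlier in a majority of population pairs (>= 3
#'   of 5) with a consistent direction in a majority, which shields the call
#'   from interpopulation expression variation. Calls can then be
#'   cross-checked against external differential expression detections
#'   (e.g. DESeq/DESeq2 flags consumed as input).
#' @name ontogeny_de
NULL

#' Replace exact zeros with a positive floor
#'
#' TPM estimates of exactly 0.0 are replaced with the floor (1.0 TPM by
#' default) so log-ratio transforms are defined; all other values pass
#' through unchanged.
#'
#' @param x An [expression_matrix()] or numeric matrix.
#' @param floor Replacement value for exact zeros (default 1.0).
#' @return The same type as the input.
#' @export
replace_zeros <- function(x, floor = 1.0) {
  if (inherits(x, "expression_matrix")) {
    x$values[x$values == 0] <- floor
    x$full_composition <- FALSE  # renormalization constraint no longer holds
    return(x)
  }
  x[x == 0] <- floor
  x
}

#' Centered log-ratio transform
#'
#' Per sample column, clr_i = ln(x_i) - mean_j ln(x_j), with the mean taken
#' over all transcripts present in the supplied matrix. The composition
#' basis is therefore whatever the matrix contains; transforming a
#' toxin-only slice is permitted but is flagged with a provenance warning,
#' because clr values then live in the toxin-only simplex.
#'
#' @param x An [expression_matrix()] or positive numeric matrix.
#' @param warn_toxin_only Emit the provenance warning for small matrices
#'   (fewer than 100 transcripts); default TRUE.
#' @return An object of class `clr_matrix`: `values` (columns sum to zero)
#'   and `samples`.
#' @export
clr_transform <- function(x, warn_toxin_only = TRUE) {
  values <- if (inherits(x, "expression_matrix")) x$values else x
  samples <- if (inherits(x, "expression_matrix")) x$samples
    else canonical_sample_meta(colnames(values))
  if (any(values <= 0))
    stop("nonpositive values; apply replace_zeros() before clr_transform()")
  if (warn_toxin_only && nrow(values) < 100L)
    warning("clr over ", nrow(values), " transcripts only; the composition ",
            "basis excludes the nontoxin background")
  lx <- log(values)
  clr <- sweep(lx, 2L, colMeans(lx), "-")
  structure(list(values = clr, samples = samples), class = "clr_matrix")
}

#' Flag toxin outliers per adult/juvenile population pair
#'
#' For each pair, delta = adult clr - juvenile clr per transcript. The null
#' threshold is the empirical `percentile`-th percentile (linear
#' interpolation between order statistics, R quantile type 7 by default) of
#' |delta| over nontoxin transcripts. A toxin is flagged "up" when its
#' delta strictly exceeds the threshold and "down" when it falls strictly
#' below its negative -- strict inequalities, so a difference exactly at
#' the threshold is not an outlier.
#'
#' @param clr A `clr_matrix` from [clr_transform()].
#' @param catalog A [transcript_catalog()] distinguishing toxins from
#'   nontoxins.
#' @param pairs Data frame with columns `population`, `adult`, `juvenile`
#'   naming the paired sample columns.
#' @param percentile Null percentile (default 99).
#' @param min_nontoxins Minimum nontoxin count required for a stable
#'   percentile (default 100).
#' @param quantile_type Order-statistic interpolation rule passed to
#'   [stats::quantile()] (default 7).
#' @return A list of `pair_comparison` objects (one per pair), each with
#'   `population`, `delta` (all transcripts), `null_threshold`, and `flags`
#'   ("up"/"down"/"none" per toxin).
#' @export
pair_outliers <- function(clr, catalog, pairs, percentile = 99,
                          min_nontoxins = 100L, quantile_type = 7L) {
  stopifnot(inherits(clr, "clr_matrix"), percentile > 0, percentile < 100)
  ids <- rownames(clr$values)
  nt <- intersect(catalog$transcript_id[!catalog$is_toxin], ids)
  tox <- intersect(catalog$transcript_id[catalog$is_toxin], ids)
  if (length(nt) < min_nontoxins)
    stop("only ", length(nt), " nontoxin transcripts available; ",
         min_nontoxins, " required for a stable null percentile")
  lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$adult[i]
    j <- pairs$juvenile[i]
    if (!all(c(a, j) %in% colnames(clr$values)))
      stop("pair samples not found: ", a, ", ", j)
    delta <- clr$values[, a] - clr$values[, j]
    thr <- unname(stats::quantile(abs(delta[nt]), percentile / 100,
                                  type = quantile_type))
    if (thr <= 0)
      stop("degenerate null: the ", percentile,
           "th percentile of nontoxin differences is not positive")
    flags <- rep("none", length(tox))
    names(flags) <- tox
    flags[delta[tox] > thr] <- "up"
    flags[delta[tox] < -thr] <- "down"
    structure(list(population = pairs$population[i],
                   adult_sample = a, juvenile_sample = j,
                   delta = delta, null_threshold = thr, flags = flags),
              class = "pair_comparison")
  })
}

#' Collect per-pair flags into an outlier flag matrix
#'
#' @param comparisons List of `pair_comparison` objects from
#'   [pair_outliers()].
#' @return An [outlier_flag_matrix()] (toxins x populations).
#' @export
flags_from_comparisons <- function(comparisons) {
  flags <- vapply(comparisons, `[[`, character(
    length(comparisons[[1L]]$flags)), "flags")
  colnames(flags) <- vapply(comparisons, `[[`, "", "population")
  outlier_flag_matrix(flags)
}

#' Majority-consensus ontogenetic call per toxin
#'
#' A toxin is called "up" (adult-biased) when it is an outlier in at least
#' `min_outlier` of the population pairs and at least `min_same_direction`
#' of those outliers point up; "down" symmetrically; otherwise "none".
#' Direction counts use only comparisons where the toxin was an outlier, so
#' `n_up + n_down = n_outlier`. If both directions ever satisfied the rule
#' (impossible with the defaults over five pairs), the larger count wins
#' and an exact tie yields "none".
#'
#' @param flags An [outlier_flag_matrix()] or character matrix of
#'   "up"/"down"/"none" (toxins x populations).
#' @param min_outlier Minimum outlier comparisons (default 3).
#' @param min_same_direction Minimum same-direction outliers (default 3).
#' @return A data frame of class `consensus_calls`: `transcript_id`,
#'   `n_outlier`, `n_up`, `n_down`, `call`, `confirmed` (NA until
#'   [intersect_detections()] is applied).
#' @export
consensus_call <- function(flags, min_outlier = 3L, min_same_direction = 3L) {
  m <- if (inherits(flags, "outlier_flag_matrix")) flags$flags else flags
  if (anyNA(m)) stop("missing population flag")
  if (!all(m %in% FLAG_LEVELS))
    stop("flags must be one of: ", paste(FLAG_LEVELS, collapse = ", "))
  n_up <- rowSums(m == "up")
  n_down <- rowSums(m == "down")
  n_outlier <- n_up + n_down
  up_ok <- n_outlier >= min_outlier & n_up >= min_same_direction
  down_ok <- n_outlier >= min_outlier & n_down >= min_same_direction
  call <- rep("none", nrow(m))
  call[up_ok & (!down_ok | n_up > n_down)] <- "up"
  call[down_ok & (!up_ok | n_down > n_up)] <- "down"
  structure(data.frame(transcript_id = rownames(m),
                       n_outlier = as.integer(n_outlier),
                       n_up = as.integer(n_up),
                       n_down = as.integer(n_down),
                       call = call, confirmed = NA,
                       stringsAsFactors = FALSE),
            class = c("consensus_calls", "data.frame"))
}

#' Confirm consensus calls against external DE detections
#'
#' A call is confirmed when the transcript was called ("up" or "down") and
#' at least one supplied method detected it (adjusted p below its FDR
#' threshold).
#'
#' @param calls A `consensus_calls` data frame from [consensus_call()].
#' @param detections A [detection_flags()] data frame or a list of them
#'   (e.g. DESeq and DESeq2 flag tables).
#' @return `calls` with the `confirmed` column filled in.
#' @export
intersect_detections <- function(calls, detections) {
  if (inherits(detections, "detection_flags")) detections <- list(detections)
  detected <- character(0)
  for (d in detections) {
    unknown <- setdiff(d$transcript_id, calls$transcript_id)
    if (length(unknown) > 0)
      warning("ignoring detections for unknown transcript(s): ",
              paste(utils::head(unknown, 3L), collapse = ", "),
              if (length(unknown) > 3L) ", ...")
    covered <- calls$transcript_id %in% d$transcript_id
    if (!all(covered))
      warning("method '", d$method[1L], "' does not cover ",
              sum(!covered), " called transcript(s)")
    detected <- union(detected, d$transcript_id[d$detected])
  }
  calls$confirmed <- calls$call != "none" &
    calls$transcript_id %in% detected
  calls
}

#' Rank and linear concordance between replicate samples
#'
#' @param clr_a,clr_b Numeric vectors of clr values for two replicates
#'   (e.g. left and right gland), named by transcript.
#' @param subset Optional transcript ids to restrict to (e.g. toxins).
#' @return List with `rank_correlation` (Spearman) and
#'   `linear_correlation` (Pearson); NA with a warning for constant input.
#' @export
replicate_concordance <- function(clr_a, clr_b, subset = NULL) {
  if (!is.null(subset)) {
    clr_a <- clr_a[subset]
    clr_b <- clr_b[subset]
  }
  stopifnot(length(clr_a) == length(clr_b), length(clr_a) >= 3L)
  if (stats::sd(clr_a) == 0 || stats::sd(clr_b) == 0) {
    warning("constant replicate column; correlations undefined")
    return(list(rank_correlation = NA_real_,
                linear_correlation = NA_real_))
  }
  list(rank_correlation = stats::cor(clr_a, clr_b, method = "spearman"),
       linear_correlation = stats::cor(clr_a, clr_b, method = "pearson"))
}

#' Naive TPM from counts and effective lengths
#'
#' rate_i = counts_i / length_i; TPM_i = 1e6 * rate_i / sum(rate). A
#' deliberately simple normalization utility (no expectation-maximization
#' read reassignment as in full quantifiers).
#'
#' @param counts Non-negative per-transcript read counts.
#' @param lengths Positive per-transcript lengths (nucleotides).
#' @return Per-transcript TPM summing to one million.
#' @export
tpm_from_counts <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0),
            all(counts >= 0))
  if (all(counts == 0)) stop("all counts are zero; TPM undefined")
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}
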