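#' @title Coverage-based transcript presence/absence calling
#' @description Per-base depth computation from an internal lightweight
#'   read mapper, the absence rule (a transcript is absent when more than
#'   10% of its coding sequence has depth below 5x), read subsampling, and
#'   per-transcriptome absence summaries. The mapper exists only to make
#'   the absence rule testable at desk scale; it performs exhaustive
#'   end-to-end substitution-only matching through Biostrings and is not a
#'   general aligner.
#' @name presence_absence
NULL

#' Alignment and absence-calling policy
#'
#' @param max_mismatches Reads with more mismatches than this are discarded
#'   (default 2).
#' @param min_depth Depth floor for a position to count as covered
#'   (default 5); the comparison is strict (`depth < min_depth` is low).
#' @param max_low_fraction A transcript is absent when the fraction of
#'   low-coverage positions strictly exceeds this (default 0.10).
#' @param both_strands Consider reverse-complement alignments (default
#'   TRUE); a read matching both strands equally is counted once, on the
#'   forward strand.
#' @param multi_map How to place reads tying across references:
#'   "fraction" spreads weight 1/k over the k tied placements (default,
#'   avoids artificial absence of near-identical paralogs); "random" picks
#'   one placement at random.
#' @return A policy list of class `alignment_policy`.
#' @export
alignment_policy <- function(max_mismatches = 2L, min_depth = 5L,
                             max_low_fraction = 0.10, both_strands = TRUE,
                             multi_map = c("fraction", "random")) {
  stopifnot(max_mismatches >= 0, min_depth >= 1,
            max_low_fraction > 0, max_low_fraction < 1)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 min_depth = as.integer(min_depth),
                 max_low_fraction = max_low_fraction,
                 both_strands = isTRUE(both_strands),
                 multi_map = match.arg(multi_map)),
            class = "alignment_policy")
}

# Seed-and-verify candidate placements for a batch of equal-width read
# sequences. The read is split into max_mismatches + 1 disjoint bands; by
# pigeonhole, any end-to-end placement with at most max_mismatches
# substitutions leaves at least one band exact, so exact matchPDict() on
# each band enumerates every admissible candidate. Candidates are then
# verified end-to-end by counting substitutions.
candidate_placements <- function(seqs, refs, max_mm) {
  width <- nchar(seqs[1L])
  nb <- max_mm + 1L
  bounds <- unique(round(seq(0L, width, length.out = nb + 1L)))
  pats <- Biostrings::DNAStringSet(seqs)
  out <- list()
  for (b in seq_len(length(bounds) - 1L)) {
    tb_start <- bounds[b] + 1L
    tb_width <- bounds[b + 1L] - bounds[b]
    pd <- Biostrings::PDict(pats, tb.start = tb_start,
                            tb.width = tb_width)
    for (r in seq_along(refs)) {
      mi <- Biostrings::matchPDict(pd, refs[[r]],
                                   max.mismatch = max_mm)
      starts <- Biostrings::startIndex(mi)
      hit <- which(lengths(starts) > 0L)
      if (length(hit) > 0L)
        out[[length(out) + 1L]] <- data.frame(
          pattern = rep(hit, lengths(starts)[hit]),
          ref = r,
          start = unlist(starts[hit]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(pattern = integer(0), ref = integer(0),
                      start = integer(0), mm = integer(0)))
  cand <- unique(do.call(rbind, out))
  # verify each candidate end-to-end (substitutions only)
  cand$mm <- NA_integer_
  for (key in unique(paste(cand$pattern, cand$ref))) {
    idx <- which(paste(cand$pattern, cand$ref) == key)
    p <- cand$pattern[idx[1L]]
    r <- cand$ref[idx[1L]]
    cand$mm[idx] <- Biostrings::neditStartingAt(
      pats[[p]], refs[[r]], starting.at = cand$start[idx],
      with.indels = FALSE)
  }
  cand[cand$mm <= max_mm, , drop = FALSE]
}

#' Map reads against reference transcripts and accumulate depth
#'
#' Each read is placed at its best-matching position(s) (end-to-end,
#' substitutions only) and discarded when the best placement exceeds
#' `max_mismatches`. Multi-mapping reads are spread fractionally (or
#' assigned randomly) according to the policy. Reads longer than every
#' reference are skipped and counted.
#'
#' @param reads Read set (data frame with `id`, `sequence`, `quality`).
#' @param references Named character vector of reference sequences.
#' @param policy An [alignment_policy()].
#' @param seed Seed used only for the "random" multi-map policy.
#' @return Named list of per-reference numeric depth vectors, with
#'   attributes `n_discarded` (too many mismatches) and `n_skipped` (read
#'   longer than every reference; a warning is raised when nonzero).
#' @export
map_reads <- function(reads, references, policy = alignment_policy(),
                      seed = 1L) {
  stopifnot(length(references) >= 1, !is.null(names(references)))
  refs <- Biostrings::DNAStringSet(references)
  depth <- lapply(nchar(references), numeric)
  names(depth) <- names(references)
  n_discarded <- 0L
  n_skipped <- 0L
  max_ref_len <- max(nchar(references))
  # identical read sequences share one placement lookup; equal-width
  # groups are matched in one batched pass
  seq_tab <- table(reads$sequence)
  uniq <- names(seq_tab)
  counts <- as.integer(seq_tab)
  too_long <- nchar(uniq) > max_ref_len
  n_skipped <- sum(counts[too_long])
  uniq <- uniq[!too_long]
  counts <- counts[!too_long]
  pick_random <- policy$multi_map == "random"
  local_seed(split_seed(seed, "multimap"), {
    for (w_group in split(seq_along(uniq), nchar(uniq))) {
      seqs <- uniq[w_group]
      cand <- candidate_placements(seqs, refs, policy$max_mismatches)
      cand$strand <- rep("fwd", nrow(cand))
      if (policy$both_strands) {
        rc <- candidate_placements(revcomp(seqs), refs,
                                   policy$max_mismatches)
        if (nrow(rc) > 0L) {
          rc$strand <- "rev"
          cand <- rbind(cand, rc)
        }
      }
      placed <- if (nrow(cand) > 0L) split(cand, cand$pattern) else list()
      for (i in seq_along(seqs)) {
        hit <- placed[[as.character(i)]]
        count <- counts[w_group[i]]
        if (is.null(hit)) { n_discarded <- n_discarded + count; next }
        best <- min(hit$mm)
        hit <- hit[hit$mm == best, , drop = FALSE]
        # a read matching both strands equally counts once, forward first
        if (any(hit$strand == "fwd"))
          hit <- hit[hit$strand == "fwd", , drop = FALSE]
        k <- nrow(hit)
        if (pick_random && k > 1L) {
          hit <- hit[sample.int(k, 1L), , drop = FALSE]
          k <- 1L
        }
        w <- count / k
        rl <- nchar(seqs[i])
        for (h in seq_len(k)) {
          ri <- hit$ref[h]
          span <- hit$start[h]:(hit$start[h] + rl - 1L)
          depth[[ri]][span] <- depth[[ri]][span] + w
        }
      }
    }
  })
  if (n_skipped > 0L)
    warning(n_skipped, " read(s) longer than every reference were skipped")
  attr(depth, "n_discarded") <- n_discarded
  attr(depth, "n_skipped") <- n_skipped
  depth
}

#' Call a transcript absent from a transcriptome
#'
#' Absent means that strictly more than `max_low_fraction` of positions
#' have depth strictly below `min_depth` (both inequalities exactly as in
#' the reference rule: ">10% of the coding sequence had <5x coverage").
#'
#' @param depth Per-base depth vector over the coding sequence.
#' @param policy An [alignment_policy()].
#' @return TRUE when absent.
#' @export
call_absent <- function(depth, policy = alignment_policy()) {
  stopifnot(length(depth) > 0)
  mean(depth < policy$min_depth) > policy$max_low_fraction
}

#' Subsample reads uniformly without replacement
#'
#' @param reads Read set.
#' @param n Number of reads to keep (at most `nrow(reads)`).
#' @param seed Integer seed.
#' @return The subsampled read set in canonical (id) order.
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  if (n > nrow(reads))
    stop("cannot subsample ", n, " reads from ", nrow(reads))
  idx <- local_seed(split_seed(seed, "subsample"),
                    sample.int(nrow(reads), n))
  out <- reads[idx, , drop = FALSE]
  out[order(out$id), , drop = FALSE]
}

#' Summarize a presence/absence matrix
#'
#' Reports per-transcriptome missing counts, the overall / adult / juvenile
#' mean counts, the number of transcripts absent from at least one
#' transcriptome, and a Welch two-sample t-test (two-sided, unequal
#' variances, Welch-Satterthwaite degrees of freedom) comparing adult and
#' juvenile missing counts.
#'
#' @param pa A [presence_absence_matrix()].
#' @param metadata [sample_meta()] rows matching the matrix columns.
#' @return A list of class `absence_summary`.
#' @export
summarize_absence <- function(pa, metadata) {
  stopifnot(inherits(pa, "presence_absence_matrix"))
  ids <- colnames(pa$present)
  if (!all(ids %in% metadata$sample_id))
    stop("metadata does not cover all transcriptome columns")
  meta <- metadata[match(ids, metadata$sample_id), ]
  missing <- pa$absent_counts
  adult <- missing[meta$age_class == "adult"]
  juv <- missing[meta$age_class == "juvenile"]
  welch_p <- if (length(adult) >= 2L && length(juv) >= 2L)
    stats::t.test(adult, juv)$p.value else NA_real_
  structure(list(per_transcriptome_missing = missing,
                 overall_mean_missing = mean(missing),
                 adult_mean = if (length(adult)) mean(adult) else NA_real_,
                 juvenile_mean = if (length(juv)) mean(juv) else NA_real_,
                 max_missing = max(missing),
                 n_variable_transcripts = sum(rowSums(!pa$present) > 0L),
                 welch_p = welch_p),
            class = "absence_summary")
}

#' @export
print.absence_summary <- function(x, ...) {
  cat(sprintf(paste0("absence summary: %d transcripts absent in >=1 ",
                     "transcriptome\nmean missing %.1f ",
                     "(adults %.1f, juveniles %.1f, max %d); Welch p = %s\n"),
              x$n_variable_transcripts, x$overall_mean_missing,
              x$adult_mean, x$juvenile_mean, x$max_missing,
              format(x$welch_p, digits = 2)))
  invisible(x)
}

#' Write depth profiles as a three-column TSV
#'
#' Positions are 1-based and inclusive.
#'
#' @param profiles Named list of depth vectors (as from [map_reads()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_depth_profiles <- function(profiles, path) {
  tab <- do.call(rbind, lapply(names(profiles), function(id)
    data.frame(transcript = id, position = seq_along(profiles[[id]]),
               depth = profiles[[id]], stringsAsFactors = FALSE)))
  write_results(tab, path, "tsv")
}
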