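#' @title Consensus toxin transcriptome construction
#' @description Clustering of assembled toxin transcripts at nucleotide
#'   divergence thresholds (1% within individuals, 1.5% across individuals
#'   in the reference workflow), consensus-sequence calling over clusters,
#'   a coverage-shape chimera screen, and duplicate/containment removal.
#'   Clustering at a divergence threshold is the operational definition of
#'   a toxin paralog here.
#' @name consensus_transcriptome
NULL

iupac_sets <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(map, function(x) strsplit(x, "")[[1L]])
}

# Do two alignment columns match? IUPAC codes match any compatible base;
# a gap never matches.
columns_match <- function(a, b, sets) {
  gap <- a == "-" | b == "-"
  out <- logical(length(a))
  for (i in which(!gap)) {
    sa <- sets[[a[i]]]
    sb <- sets[[b[i]]]
    out[i] <- !is.null(sa) && !is.null(sb) && length(intersect(sa, sb)) > 0L
  }
  out[gap] <- FALSE
  out
}

align_global <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = 2)
}

#' Pairwise nucleotide divergence from a global alignment
#'
#' Computes the p-distance of a Needleman-Wunsch global alignment (match
#' +1, mismatch -1, gap -2): mismatching columns plus gap columns, divided
#' by the alignment length. IUPAC ambiguity codes match any compatible base.
#'
#' @param seq_a,seq_b Nonempty nucleotide strings.
#' @return Divergence in [0, 1].
#' @export
pairwise_divergence <- function(seq_a, seq_b) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  if (identical(seq_a, seq_b)) return(0)
  aln <- align_global(seq_a, seq_b)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  1 - sum(columns_match(pa, sb, iupac_sets())) / length(pa)
}

# Symmetric divergence matrix over a set of sequences.
divergence_matrix <- function(sequences) {
  n <- length(sequences)
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- pairwise_divergence(sequences[[i]],
                                                sequences[[j]])
  d
}

# Connected components of the graph linking pairs at divergence <= threshold
# (single linkage), via union-find.
single_linkage_components <- function(d, threshold) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i < j && d[i, j] <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[c(ri, rj)] <- min(ri, rj)
      }
  # path-compress to representative labels
  vapply(seq_len(n), find, 1L)
}

#' Cluster transcripts at a nucleotide divergence threshold
#'
#' Single linkage by default: two sequences are linked when their
#' [pairwise_divergence()] is at or below the threshold, and clusters are
#' the connected components. Complete linkage (every within-cluster pair at
#' or below the threshold) is available behind the `linkage` flag. Input is
#' put into canonical (name) order first so clustering does not depend on
#' input order.
#'
#' @param sequences Named character vector of sequences.
#' @param threshold Divergence threshold in (0, 0.5), e.g. 0.01 within
#'   individuals and 0.015 across individuals.
#' @param linkage "single" (default) or "complete".
#' @return A list of `transcript_cluster` objects, each carrying
#'   `member_ids`, `member_sequences`, `consensus`, and
#'   `max_internal_divergence`.
#' @export
cluster_transcripts <- function(sequences, threshold,
                                linkage = c("single", "complete")) {
  stopifnot(threshold > 0, threshold < 0.5, length(sequences) >= 1)
  linkage <- match.arg(linkage)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq-%d", seq_along(sequences))
  sequences <- sequences[order(names(sequences))]
  d <- divergence_matrix(sequences)
  labels <- if (length(sequences) == 1L) {
    1L
  } else if (linkage == "single") {
    single_linkage_components(d, threshold)
  } else {
    tree <- stats::hclust(stats::as.dist(d), method = "complete")
    stats::cutree(tree, h = threshold)
  }
  lapply(split(seq_along(sequences), labels), function(idx) {
    members <- sequences[idx]
    structure(list(member_ids = names(members),
                   member_sequences = unname(members),
                   consensus = consensus_sequence(unname(members)),
                   max_internal_divergence =
                     if (length(idx) > 1L)
                       max(d[idx, idx]) else 0),
              class = "transcript_cluster")
  })
}

#' Column-wise majority consensus of cluster members
#'
#' The longest member anchors the coordinate system; every other member is
#' globally aligned to it and votes per anchor position. Majority base
#' wins; exact ties are written as the IUPAC ambiguity code of the tied
#' bases. Positions where a strict majority of members vote gap are
#' dropped.
#'
#' @param members Character vector of sequences (at least one).
#' @return The consensus sequence.
#' @export
consensus_sequence <- function(members) {
  if (length(members) == 0L) stop("consensus of an empty member list")
  if (length(members) == 1L) return(members[[1L]])
  ref <- members[[which.max(nchar(members))]]
  votes <- matrix("", nrow = nchar(ref), ncol = length(members))
  ref_chars <- strsplit(ref, "")[[1L]]
  code_map <- Biostrings::IUPAC_CODE_MAP
  for (m in seq_along(members)) {
    if (identical(members[[m]], ref)) { votes[, m] <- ref_chars; next }
    aln <- align_global(members[[m]], ref)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    ref_pos <- cumsum(sb != "-")
    keep <- sb != "-"
    votes[ref_pos[keep], m] <- pa[keep]
  }
  votes[votes == ""] <- "-"
  out <- character(nrow(votes))
  for (i in seq_len(nrow(votes))) {
    tab <- sort(table(votes[i, ]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) {
      out[i] <- top
    } else {
      bases <- setdiff(top, "-")
      if (length(bases) == 0L) { out[i] <- "-"; next }
      expanded <- sort(unique(unlist(strsplit(code_map[bases], ""))))
      hit <- names(code_map)[match(paste(expanded, collapse = ""),
                                   vapply(strsplit(code_map, ""), function(x)
                                     paste(sort(x), collapse = ""), ""))]
      out[i] <- if (length(hit) == 1L && !is.na(hit)) hit else bases[1L]
    }
  }
  paste(out[out != "-"], collapse = "")
}

#' Screen a depth profile for chimeric coverage steps
#'
#' Chimeric transcripts fuse segments of two real transcripts and betray
#' themselves by an abrupt step in read coverage at the fusion point. The
#' screen compares median depths of adjacent windows along the profile and
#' flags the transcript when their ratio reaches `step_ratio` (with both
#' windows at median depth >= 1).
#'
#' @param depth Per-base depth vector, length at least `2 * window`.
#' @param step_ratio Flagging ratio between adjacent window medians
#'   (default 5).
#' @param window Window length in bases (default 100).
#' @return A list: `keep` (FALSE when flagged), `breakpoint` (position of
#'   the strongest step, NA when kept), `max_ratio`.
#' @export
chimera_screen <- function(depth, step_ratio = 5, window = 100L) {
  stopifnot(length(depth) >= 2L * window, all(depth >= 0))
  candidates <- seq(window, length(depth) - window,
                    by = max(1L, window %/% 5L))
  best_ratio <- 0
  best_pos <- NA_integer_
  for (b in candidates) {
    ml <- stats::median(depth[(b - window + 1L):b])
    mr <- stats::median(depth[(b + 1L):(b + window)])
    if (min(ml, mr) < 1) next
    ratio <- max(ml, mr) / min(ml, mr)
    if (ratio > best_ratio) { best_ratio <- ratio; best_pos <- b }
  }
  flagged <- is.finite(best_ratio) && best_ratio >= step_ratio
  list(keep = !flagged,
       breakpoint = if (flagged) best_pos else NA_integer_,
       max_ratio = best_ratio)
}

#' Remove duplicate and contained sequences
#'
#' Drops sequences identical to, or wholly contained in (either strand), a
#' longer retained sequence.
#'
#' @param transcripts Character vector of sequences (names preserved).
#' @return The deduplicated vector.
#' @export
dedupe <- function(transcripts) {
  if (length(transcripts) <= 1L) return(transcripts)
  ord <- order(-nchar(transcripts),
               names(transcripts) %||% seq_along(transcripts))
  kept_idx <- integer(0)
  for (i in ord) {
    contained <- FALSE
    for (j in kept_idx) {
      if (grepl(transcripts[[i]], transcripts[[j]], fixed = TRUE) ||
          grepl(revcomp(transcripts[[i]]), transcripts[[j]], fixed = TRUE)) {
        contained <- TRUE
        break
      }
    }
    if (!contained) kept_idx <- c(kept_idx, i)
  }
  transcripts[sort(kept_idx)]
}
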