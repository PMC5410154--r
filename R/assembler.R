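#' @title Greedy seed-extension transcript assembly
#' @description A deliberately simple assembler for merged venom-gland
#'   reads: seeds are extended at both ends by reads whose sequence exactly
#'   matches the terminal overlap window (120 nt by default) and reach
#'   beyond it. It is not a general-purpose assembler -- no de Bruijn graph,
#'   no scaffolding -- but it handles long, highly paralogous toxin
#'   transcripts well because the long exact overlap keeps paralogs apart.
#' @name assembler
NULL

#' Keep only reads whose every base meets a phred floor
#'
#' @param reads Read set (data frame with `id`, `sequence`, `quality`).
#' @param min_phred Minimum per-base phred score (default 30).
#' @return The filtered read set.
#' @export
filter_high_quality <- function(reads, min_phred = 30L) {
  if (nrow(reads) == 0L) return(reads)
  ok <- vapply(reads$quality,
               function(q) min(utf8ToInt(q)) - 33L >= min_phred,
               NA, USE.NAMES = FALSE)
  reads[ok, , drop = FALSE]
}

# Extend the right end of `contig` one round. Candidate reads (either
# orientation) must contain the contig's terminal `overlap`-mer with bases
# after it. Among candidates the extension is the per-position majority base
# path: at each new position, candidates still consistent with the chosen
# path vote, and an exact tie stops the extension there (flagged), which
# avoids fabricating chimeras when paralogs conflict.
extend_right_once <- function(contig, pool, overlap) {
  len <- nchar(contig)
  key <- substr(contig, len - overlap + 1L, len)
  hit <- which(grepl(key, pool, fixed = TRUE))
  if (length(hit) == 0L)
    return(list(extension = "", tie = FALSE))
  pos <- regexpr(key, pool[hit], fixed = TRUE)
  exts <- substr(pool[hit], pos + overlap, nchar(pool[hit]))
  exts <- exts[nzchar(exts)]
  if (length(exts) == 0L)
    return(list(extension = "", tie = FALSE))
  built <- character(0)
  alive <- exts
  p <- 1L
  tie <- FALSE
  repeat {
    alive <- alive[nchar(alive) >= p]
    if (length(alive) == 0L) break
    tab <- table(substr(alive, p, p))
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) { tie <- TRUE; break }
    built[p] <- top
    alive <- alive[substr(alive, p, p) == top]
    p <- p + 1L
  }
  list(extension = paste(built, collapse = ""), tie = tie)
}

#' Extend a seed sequence through exact overlaps with reads
#'
#' At each end the contig's terminal `overlap` bases are matched exactly
#' against the reads (both orientations); matching reads that reach beyond
#' the end extend it by their majority base path. Extension stops at an end
#' when no read reaches past it, or when candidates tie at a position (the
#' contig is then flagged).
#'
#' @param seed Seed sequence, at least `overlap` nucleotides.
#' @param reads Read set; should already be quality-filtered
#'   ([filter_high_quality()]).
#' @param overlap Exact-match window length (default 120).
#' @param max_rounds Safety cap on extension rounds.
#' @return An object of class `contig`: `sequence`, `n_reads_assembled`,
#'   `per_base_depth`, and `tie_flag`.
#' @export
extend_seed <- function(seed, reads, overlap = 120L, max_rounds = 10000L) {
  if (nchar(seed) < overlap)
    stop("seed shorter than the overlap window (", overlap, " nt)")
  # canonical read ordering makes output independent of input file order
  reads <- reads[order(reads$id), , drop = FALSE]
  pool <- c(reads$sequence, revcomp(reads$sequence))
  contig <- seed
  tie_flag <- FALSE
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    r <- extend_right_once(contig, pool, overlap)
    contig <- paste0(contig, r$extension)
    # extend the left end by extending the right end of the reverse
    # complement (the pool carries both orientations)
    contig <- revcomp(contig)
    l <- extend_right_once(contig, pool, overlap)
    contig <- revcomp(paste0(contig, l$extension))
    tie_flag <- tie_flag || r$tie || l$tie
    grew <- nzchar(r$extension) || nzchar(l$extension)
    if (!grew || rounds >= max_rounds) break
  }
  contig_from_sequence(contig, reads, tie_flag)
}

# Map reads back onto the finished contig (exact full-length occurrence,
# either orientation, counted once) to obtain the assembled-read count and
# the per-base depth profile.
contig_from_sequence <- function(sequence, reads, tie_flag = FALSE) {
  depth <- integer(nchar(sequence))
  n_used <- 0L
  fwd_pos <- vapply(reads$sequence,
                    function(s) regexpr(s, sequence, fixed = TRUE)[1L],
                    1L, USE.NAMES = FALSE)
  rev_seqs <- if (nrow(reads) > 0L) revcomp(reads$sequence) else character(0)
  rev_pos <- vapply(rev_seqs,
                    function(s) regexpr(s, sequence, fixed = TRUE)[1L],
                    1L, USE.NAMES = FALSE)
  for (i in seq_len(nrow(reads))) {
    pos <- if (fwd_pos[i] > 0L) fwd_pos[i] else rev_pos[i]
    if (pos > 0L) {
      n_used <- n_used + 1L
      span <- pos:(pos + nchar(reads$sequence[i]) - 1L)
      depth[span] <- depth[span] + 1L
    }
  }
  structure(list(sequence = sequence, n_reads_assembled = n_used,
                 per_base_depth = depth, tie_flag = tie_flag),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("contig: %d nt, %d reads assembled%s\n", nchar(x$sequence),
              x$n_reads_assembled, if (x$tie_flag) " [tie-flagged]" else ""))
  invisible(x)
}

#' Assemble contigs from seed reads
#'
#' Extends every seed with [extend_seed()], removes contigs that are
#' identical to or contained in another (either strand), and discards
#' contigs supported by fewer than `min_reads` assembled reads.
#'
#' @param seeds Read set used as seeds (a subset of the quality-filtered
#'   reads).
#' @param reads Quality-filtered read set used for extension.
#' @param overlap Exact-match window (default 120).
#' @param min_reads Minimum assembled reads per retained contig
#'   (default 200).
#' @param max_rounds Safety cap per seed.
#' @return List of `contig` objects.
#' @export
assemble <- function(seeds, reads, overlap = 120L, min_reads = 200L,
                     max_rounds = 10000L) {
  if (nrow(seeds) == 0L) return(list())
  seeds <- seeds[order(seeds$id), , drop = FALSE]
  contigs <- lapply(seeds$sequence, extend_seed, reads = reads,
                    overlap = overlap, max_rounds = max_rounds)
  seqs <- vapply(contigs, `[[`, "", "sequence")
  keep_seq <- dedupe(seqs)
  contigs <- contigs[match(keep_seq, seqs)]
  contigs[vapply(contigs, `[[`, 1L, "n_reads_assembled") >= min_reads]
}
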