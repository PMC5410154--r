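#' @title Synthetic data generators
#' @description Generators that emulate the statistical structure the
#'   ontogeny analysis assumes: paired adult/juvenile venom-gland samples
#'   from up to five populations, a large nontoxin background with
#'   between-age log-expression noise, toxin transcripts with planted
#'   ontogenetic fold-changes, paralog families with controlled nucleotide
#'   divergence, uniform-coverage merged reads with transcript dropout, and
#'   binomial dose-mortality under a log-dose logistic tolerance curve.
#'   Every generator is a pure function of its spec, including the seed, and
#'   every planted signal is returned alongside a truth table so recovery
#'   tests never have to re-derive ground truth from outputs.
#' @name synthetic_data
NULL

#' Specify a synthetic paired adult/juvenile expression dataset
#'
#' @param n_nontoxins Number of nontoxin (null) transcripts.
#' @param n_toxins Number of toxin transcripts.
#' @param n_populations Number of populations, 1-5 (default 5); each
#'   contributes one adult and one juvenile sample.
#' @param log_noise_sd Standard deviation (natural-log scale) of the
#'   adult-juvenile expression difference for null transcripts.
#' @param planted_effects Named numeric vector of signed log fold-changes
#'   (adult minus juvenile, natural log) keyed by toxin transcript id.
#' @param population_effect_sd SD of per-population transcript effects.
#' @param zero_rate Probability that a toxin is unexpressed (0 TPM) in any
#'   given sample.
#' @param noise_df Degrees of freedom for a Student-t noise option; Inf
#'   (default) gives Gaussian noise. The t variant is rescaled to keep the
#'   difference SD equal to `log_noise_sd`, and exists to probe the
#'   robustness of the empirical-percentile null to heavy tails.
#' @param seed Integer seed.
#' @return A validated spec list of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_nontoxins, n_toxins, n_populations = 5L,
                                log_noise_sd = 0.4,
                                planted_effects = numeric(0),
                                population_effect_sd = 0,
                                zero_rate = 0, noise_df = Inf, seed = 1L) {
  stopifnot(n_nontoxins >= 1, n_toxins >= 1,
            n_populations >= 1, n_populations <= 5,
            log_noise_sd >= 0, population_effect_sd >= 0,
            zero_rate >= 0, zero_rate < 1, noise_df > 2)
  spec <- list(n_nontoxins = as.integer(n_nontoxins),
               n_toxins = as.integer(n_toxins),
               n_populations = as.integer(n_populations),
               log_noise_sd = log_noise_sd,
               planted_effects = planted_effects,
               population_effect_sd = population_effect_sd,
               zero_rate = zero_rate, noise_df = noise_df,
               seed = as.integer(seed))
  class(spec) <- "expression_sim_spec"
  spec
}

sim_toxin_ids <- function(n) sprintf("TOX-%d", seq_len(n))
sim_nontoxin_ids <- function(n) sprintf("NT-%d", seq_len(n))

# Noise on the natural-log scale with SD `sd`; optionally Student-t with
# `df` degrees of freedom, rescaled to the same SD.
rnoise <- function(n, sd, df = Inf) {
  if (is.infinite(df)) return(stats::rnorm(n, 0, sd))
  stats::rt(n, df) * sd / sqrt(df / (df - 2))
}

#' Generate a paired adult/juvenile expression dataset
#'
#' One adult and one juvenile sample are produced per population. Null
#' transcripts get independent adult and juvenile log-scale noise whose
#' difference has SD `log_noise_sd`; planted toxins additionally receive
#' their log fold-change in the adult sample of every population. Each
#' sample column is renormalized to 1,000,000 TPM.
#'
#' @param spec An [expression_sim_spec()].
#' @return A list with elements `expression` (an [expression_matrix()] whose
#'   columns each sum to one million), `catalog` (a [transcript_catalog()]),
#'   and `truth` (data frame of transcript id and planted log fold-change).
#' @export
gen_expression_dataset <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  tox_ids <- sim_toxin_ids(spec$n_toxins)
  nt_ids <- sim_nontoxin_ids(spec$n_nontoxins)
  ids <- c(tox_ids, nt_ids)
  planted <- spec$planted_effects
  if (length(planted) > 0) {
    unknown <- setdiff(names(planted), tox_ids)
    if (length(unknown) > 0)
      stop("planted effect on unknown transcript id: ",
           paste(unknown, collapse = ", "))
  }
  lfc <- stats::setNames(numeric(length(ids)), ids)
  lfc[names(planted)] <- planted
  pops <- POPULATIONS[seq_len(spec$n_populations)]
  n <- length(ids)
  local_seed(split_seed(spec$seed, "expression"), {
    # baseline log-TPM: toxins dominate the venom-gland composition
    base <- c(stats::rnorm(spec$n_toxins, log(2000), 1.5),
              stats::rnorm(spec$n_nontoxins, log(50), 1.5))
    cols <- list()
    for (pop in pops) {
      pop_eff <- if (spec$population_effect_sd > 0)
        stats::rnorm(n, 0, spec$population_effect_sd) else numeric(n)
      # independent per-age noise; the adult-juvenile difference has SD
      # log_noise_sd
      eps_a <- rnoise(n, spec$log_noise_sd / sqrt(2), spec$noise_df)
      eps_j <- rnoise(n, spec$log_noise_sd / sqrt(2), spec$noise_df)
      adult <- exp(base + pop_eff + eps_a + lfc)
      juv <- exp(base + pop_eff + eps_j)
      if (spec$zero_rate > 0) {
        ztox_a <- stats::runif(spec$n_toxins) < spec$zero_rate
        ztox_j <- stats::runif(spec$n_toxins) < spec$zero_rate
        adult[seq_len(spec$n_toxins)][ztox_a] <- 0
        juv[seq_len(spec$n_toxins)][ztox_j] <- 0
      }
      cols[[paste0(pop, "-A")]] <- adult
      cols[[paste0(pop, "-J")]] <- juv
    }
    values <- do.call(cbind, cols)
    rownames(values) <- ids
    values <- sweep(values, 2L, colSums(values), "/") * 1e6
    catalog <- transcript_catalog(
      ids, is_toxin = c(rep(TRUE, spec$n_toxins), rep(FALSE, spec$n_nontoxins)))
    list(expression = expression_matrix(values, full_composition = TRUE),
         catalog = catalog,
         truth = data.frame(transcript_id = ids, lfc = unname(lfc),
                            stringsAsFactors = FALSE))
  })
}

#' Generate a toxin paralog family by independent mutation of an ancestor
#'
#' Each paralog differs from the shared random ancestor at an expected
#' fraction `divergence` of sites (substitutions only, no indels), so the
#' expected pairwise divergence between paralogs is approximately
#' `2 * divergence`.
#'
#' @param ancestor_length Ancestor sequence length in nucleotides.
#' @param n_paralogs Number of paralogs to generate.
#' @param divergence Per-paralog expected per-site divergence from the
#'   ancestor, at most 0.5.
#' @param seed Integer seed.
#' @return Named character vector of paralog sequences ("par-1", ...) with
#'   the ancestor attached as attribute "ancestor".
#' @export
gen_paralog_family <- function(ancestor_length, n_paralogs, divergence,
                               seed = 1L) {
  stopifnot(ancestor_length >= 1, n_paralogs >= 1,
            divergence >= 0, divergence <= 0.5)
  local_seed(split_seed(seed, "paralog"), {
    anc <- sample(c("A", "C", "G", "T"), ancestor_length, replace = TRUE)
    seqs <- vapply(seq_len(n_paralogs), function(i) {
      s <- anc
      hit <- stats::runif(ancestor_length) < divergence
      if (any(hit))
        s[hit] <- vapply(s[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      paste(s, collapse = "")
    }, "")
    names(seqs) <- sprintf("par-%d", seq_len(n_paralogs))
    attr(seqs, "ancestor") <- paste(anc, collapse = "")
    seqs
  })
}

#' Specify a merged-read simulation
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param mean_depth Target mean per-base depth.
#' @param read_length Read length in nucleotides; must not exceed the
#'   shortest transcript.
#' @param error_rate Per-base substitution error rate (< 0.5); reads are
#'   error-free by default so assembler tests are exact.
#' @param dropout_ids Transcript ids that produce no reads.
#' @param quality_phred Phred score assigned uniformly to every base.
#' @param tile Use evenly spaced (deterministic) start positions that
#'   always include both transcript ends, instead of random uniform
#'   starts; guarantees end-to-end coverage for exact assembly tests.
#' @param seed Integer seed.
#' @return A spec list of class `read_sim_spec`.
#' @export
read_sim_spec <- function(transcripts, mean_depth, read_length = 150L,
                          error_rate = 0, dropout_ids = character(0),
                          quality_phred = 40L, tile = FALSE, seed = 1L) {
  stopifnot(length(transcripts) >= 1, !is.null(names(transcripts)),
            mean_depth > 0, read_length >= 1,
            error_rate >= 0, error_rate < 0.5,
            quality_phred >= 0, quality_phred <= 60)
  if (read_length > min(nchar(transcripts)))
    stop("read_length exceeds the shortest transcript")
  if (!all(dropout_ids %in% names(transcripts)))
    stop("dropout_ids must name transcripts")
  structure(list(transcripts = transcripts, mean_depth = mean_depth,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, dropout_ids = dropout_ids,
                 quality_phred = as.integer(quality_phred),
                 tile = isTRUE(tile), seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate merged single-end reads with uniform coverage
#'
#' Reads are drawn with uniformly random start positions along each
#' non-dropout transcript; the read count per transcript is chosen so the
#' mean per-base depth equals `mean_depth`. Dropout transcripts yield no
#' reads. Substitution errors are injected per base at `error_rate`.
#'
#' @param spec A [read_sim_spec()].
#' @return A data frame (read set) with columns `id`, `sequence`, `quality`.
#' @export
gen_reads <- function(spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  rl <- spec$read_length
  qual <- strrep(rawToChar(as.raw(spec$quality_phred + 33L)), rl)
  local_seed(split_seed(spec$seed, "reads"), {
    out <- lapply(names(spec$transcripts), function(tid) {
      if (tid %in% spec$dropout_ids) return(NULL)
      tseq <- spec$transcripts[[tid]]
      len <- nchar(tseq)
      n <- max(1L, as.integer(round(spec$mean_depth * len / rl)))
      starts <- if (spec$tile) {
        as.integer(round(seq(1L, len - rl + 1L, length.out = n)))
      } else {
        sample.int(len - rl + 1L, n, replace = TRUE)
      }
      seqs <- substring(tseq, starts, starts + rl - 1L)
      if (spec$error_rate > 0) {
        seqs <- vapply(seqs, function(s) {
          b <- strsplit(s, "")[[1L]]
          hit <- stats::runif(rl) < spec$error_rate
          if (any(hit))
            b[hit] <- vapply(b[hit], function(x)
              sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
          paste(b, collapse = "")
        }, "", USE.NAMES = FALSE)
      }
      data.frame(id = sprintf("%s_r%06d", tid, seq_len(n)),
                 sequence = seqs, quality = qual,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out) %||% data.frame(id = character(0),
                                        sequence = character(0),
                                        quality = character(0))
  })
}

#' Join two transcripts into an artificial chimera
#'
#' Concatenates the prefix of `seq_a` with the suffix of `seq_b`, splitting
#' each at the given fractional breakpoint. Used to exercise the
#' coverage-profile chimera screen.
#'
#' @param seq_a,seq_b Nonempty nucleotide strings.
#' @param breakpoint Fraction in (0, 1).
#' @return The hybrid sequence.
#' @export
gen_chimeric_transcript <- function(seq_a, seq_b, breakpoint = 0.5) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0,
            breakpoint > 0, breakpoint < 1)
  cut_a <- round(breakpoint * nchar(seq_a))
  cut_b <- round(breakpoint * nchar(seq_b))
  paste0(substr(seq_a, 1L, cut_a), substr(seq_b, cut_b + 1L, nchar(seq_b)))
}

#' Specify a dose-mortality simulation
#'
#' The design mirrors a serial-dilution toxicity assay: a top dose with
#' `n_doses - 1` further dilutions by `dilution_factor`, `group_size`
#' animals per dose, and mortality binomial under a logistic tolerance curve
#' on log10 dose.
#'
#' @param true_ld50 True median lethal dose (mg/kg).
#' @param slope Logistic slope on the log10-dose scale.
#' @param top_dose Highest dose (mg/kg).
#' @param n_doses Number of doses (default 5).
#' @param dilution_factor Ratio between consecutive doses (default 2).
#' @param group_size Animals per dose group (default 8).
#' @param seed Integer seed.
#' @return A spec list of class `dose_sim_spec`.
#' @export
dose_sim_spec <- function(true_ld50, slope, top_dose, n_doses = 5L,
                          dilution_factor = 2, group_size = 8L, seed = 1L) {
  stopifnot(true_ld50 > 0, slope > 0, top_dose > 0, n_doses >= 2,
            dilution_factor > 1, group_size >= 1)
  structure(list(true_ld50 = true_ld50, slope = slope, top_dose = top_dose,
                 n_doses = as.integer(n_doses),
                 dilution_factor = dilution_factor,
                 group_size = as.integer(group_size),
                 seed = as.integer(seed)),
            class = "dose_sim_spec")
}

#' Simulate a dose-mortality table
#'
#' @param spec A [dose_sim_spec()].
#' @return A [dose_response_table()] with doses in decreasing order.
#' @export
gen_dose_response <- function(spec) {
  stopifnot(inherits(spec, "dose_sim_spec"))
  doses <- spec$top_dose / spec$dilution_factor^(seq_len(spec$n_doses) - 1L)
  p <- stats::plogis(spec$slope * (log10(doses) - log10(spec$true_ld50)))
  local_seed(split_seed(spec$seed, "dose"), {
    deaths <- stats::rbinom(length(doses), spec$group_size, p)
    dose_response_table(dose = doses,
                        n = rep(spec$group_size, length(doses)),
                        deaths = deaths)
  })
}

#' Write sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a read set to FASTQ
#' @param reads Data frame with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                    reads$quality),
             con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ file path.
#' @return Data frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("^@", "", sub(" .*", "", lines[idx])),
             sequence = lines[idx + 1L],
             quality = lines[idx + 3L],
             stringsAsFactors = FALSE)
}
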