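# Shared helpers for building small synthetic cases in tests.

pops5 <- c("ANF", "BR", "CAL", "ENP", "LSG")

standard_pairs <- function(pops = pops5) {
  data.frame(population = pops,
             adult = paste0(pops, "-A"),
             juvenile = paste0(pops, "-J"),
             stringsAsFactors = FALSE)
}

random_transcript <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Substitute a fraction of sites (guaranteed base changes).
mutate_seq <- function(seq, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- strsplit(seq, "")[[1]]
  hit <- runif(length(b)) < rate
  b[hit] <- vapply(b[hit],
                   function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                   "")
  paste(b, collapse = "")
}

substitute_at <- function(seq, pos) {
  b <- strsplit(seq, "")[[1]]
  b[pos] <- chartr("ACGT", "CGTA", b[pos])
  paste(b, collapse = "")
}

# Full outlier+consensus pipeline on one synthetic dataset; returns the
# called set and the truth set.
run_recovery <- function(seed, planted, n_nontoxins = 2000, n_toxins = 59,
                         log_noise_sd = 0.4) {
  d <- gen_expression_dataset(expression_sim_spec(
    n_nontoxins, n_toxins, 5, log_noise_sd = log_noise_sd,
    planted_effects = planted, seed = seed))
  clr <- suppressWarnings(clr_transform(replace_zeros(d$expression)))
  cmp <- pair_outliers(clr, d$catalog, standard_pairs())
  calls <- consensus_call(flags_from_comparisons(cmp))
  list(calls = calls,
       called = calls$transcript_id[calls$call != "none"],
       truth = d$truth$transcript_id[d$truth$lfc != 0])
}
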