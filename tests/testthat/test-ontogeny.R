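test_that("zero replacement floors exact zeros only", {
  m <- matrix(c(0, 0.3, 2, 0), 2, 2,
              dimnames = list(c("a", "b"), c("ANF-A", "ANF-J")))
  out <- replace_zeros(m)
  expect_equal(unname(out), matrix(c(1, 0.3, 2, 1), 2, 2))
  pos <- matrix(c(1, 2, 3, 4), 2, 2,
                dimnames = dimnames(m))
  expect_equal(replace_zeros(pos), pos)
})

test_that("the clr transform centers each sample column", {
  m <- matrix(c(1, exp(2), exp(4)), 3, 1,
              dimnames = list(c("a", "b", "c"), "ANF-A"))
  clr <- clr_transform(m, warn_toxin_only = FALSE)
  expect_equal(unname(clr$values[, 1]), c(-2, 0, 2))
  # identical values collapse to zero
  flat <- matrix(7, 5, 1, dimnames = list(letters[1:5], "BR-J"))
  expect_equal(unname(clr_transform(flat, warn_toxin_only = FALSE)$values),
               matrix(0, 5, 1), ignore_attr = TRUE)
  # defining property on random positive columns
  set.seed(51)
  r <- matrix(rexp(500) * 1000, 100, 5,
              dimnames = list(sprintf("t%d", 1:100),
                              c("ANF-A", "ANF-J", "BR-A", "BR-J", "CAL-A")))
  expect_true(all(abs(colSums(clr_transform(r)$values)) < 1e-10 * 100))
  # zeros must be floored first
  z <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "ANF-A"))
  expect_error(clr_transform(z, warn_toxin_only = FALSE), "replace_zeros")
  # the toxin-only basis carries a provenance warning
  expect_warning(clr_transform(replace_zeros(load_fixture("table3"))),
                 "basis")
})

test_that("outlier flags use the strict nontoxin percentile threshold", {
  n_nt <- 120
  nt_ids <- sprintf("NT-%d", seq_len(n_nt))
  ids <- c("TOX-1", "TOX-2", "TOX-3", nt_ids)
  cat1 <- transcript_catalog(ids, is_toxin = c(TRUE, TRUE, TRUE,
                                               rep(FALSE, n_nt)))
  # fixed nontoxin deltas 1..120 (in units of 0.01): the type-7 99th
  # percentile is 118.81; flags must be strict
  nt_delta <- seq_len(n_nt) / 100
  thr <- unname(quantile(nt_delta, 0.99, type = 7))
  juv <- rep(0, length(ids))
  adult <- c(thr, thr + 0.001, -thr - 0.001, nt_delta)
  # the pair test consumes per-transcript deltas; build the clr container
  # directly with the intended column difference
  clr <- structure(list(
    values = cbind("ANF-A" = adult, "ANF-J" = juv),
    samples = canonical_sample_meta(c("ANF-A", "ANF-J"))),
    class = "clr_matrix")
  rownames(clr$values) <- ids
  cmp <- pair_outliers(clr, cat1, standard_pairs("ANF"))
  expect_equal(cmp[[1]]$null_threshold, thr)
  flags <- cmp[[1]]$flags
  expect_identical(unname(flags["TOX-1"]), "none")  # exactly at threshold
  expect_identical(unname(flags["TOX-2"]), "up")
  expect_identical(unname(flags["TOX-3"]), "down")
})

test_that("degenerate and underpowered nulls are refused", {
  ids <- c("TOX-1", sprintf("NT-%d", 1:120))
  cat1 <- transcript_catalog(ids, is_toxin = c(TRUE, rep(FALSE, 120)))
  clr <- structure(list(
    values = cbind("ANF-A" = c(1, rep(0, 120)),
                   "ANF-J" = rep(0, 121)),
    samples = canonical_sample_meta(c("ANF-A", "ANF-J"))),
    class = "clr_matrix")
  rownames(clr$values) <- ids
  expect_error(pair_outliers(clr, cat1, standard_pairs("ANF")),
               "degenerate null")
  expect_error(pair_outliers(clr, cat1, standard_pairs("ANF"),
                             min_nontoxins = 500),
               "nontoxin")
})

test_that("the empirical percentile matches a sort-based oracle", {
  # oracle: type-7 interpolation done by explicit index arithmetic
  oracle_q99 <- function(x) {
    s <- sort(x)
    h <- (length(x) - 1) * 0.99 + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(x))] - s[lo])
  }
  set.seed(52)
  for (i in 1:1000) {
    x <- abs(rnorm(sample(100:400, 1)))
    expect_equal(unname(quantile(x, 0.99, type = 7)), oracle_q99(x))
  }
})

test_that("outlier calls are invariant to the logarithm base", {
  d <- gen_expression_dataset(expression_sim_spec(
    300, 20, 5, log_noise_sd = 0.4,
    planted_effects = c("TOX-1" = 2.5, "TOX-2" = -2.5), seed = 77))
  x <- replace_zeros(d$expression)
  clr_e <- suppressWarnings(clr_transform(x))
  lx2 <- log2(x$values)
  clr_2 <- structure(list(values = sweep(lx2, 2, colMeans(lx2)),
                          samples = x$samples), class = "clr_matrix")
  f_e <- flags_from_comparisons(
    pair_outliers(clr_e, d$catalog, standard_pairs(), min_nontoxins = 100))
  f_2 <- flags_from_comparisons(
    pair_outliers(clr_2, d$catalog, standard_pairs(), min_nontoxins = 100))
  expect_identical(f_e$flags, f_2$flags)
})

test_that("the majority-consensus rule calls direction as specified", {
  f <- rbind("t1" = c("up", "up", "up", "none", "up"),
             "t2" = c("up", "up", "down", "down", "none"),
             "t3" = c("down", "down", "down", "none", "none"),
             "t4" = c("up", "up", "none", "none", "none"),
             "t5" = rep("none", 5))
  colnames(f) <- pops5
  calls <- consensus_call(f)
  expect_identical(calls$call, c("up", "none", "down", "none", "none"))
  expect_equal(calls$n_outlier, c(4L, 4L, 3L, 2L, 0L))
  expect_equal(calls$n_up + calls$n_down, calls$n_outlier)
  # missing flags are an error
  f_na <- f
  f_na[1, 1] <- NA
  expect_error(consensus_call(f_na), "missing")
})

test_that("adding an aligned outlier flag never demotes a call", {
  set.seed(53)
  for (i in 1:50) {
    f <- matrix(sample(c("up", "down", "none"), 5, replace = TRUE), 1, 5,
                dimnames = list("t", pops5))
    before <- consensus_call(f)$call
    if (before == "none") next
    idx <- which(f == "none")
    if (length(idx) == 0) next
    f[idx[1]] <- before
    expect_identical(consensus_call(f)$call, before)
  }
})

test_that("external detections confirm exactly the intersecting calls", {
  calls <- consensus_call(load_fixture("table5_outliers"))
  # no detections at all: nothing is confirmed
  none <- intersect_detections(calls, list())
  expect_equal(sum(none$confirmed), 0L)
  # blanket detection: the confirmed set equals the called set
  blanket <- detection_flags(calls$transcript_id,
                             rep(1e-6, nrow(calls)), "blanket")
  all_conf <- intersect_detections(calls, blanket)
  expect_identical(all_conf$confirmed, calls$call != "none")
  # detections on unknown transcripts warn and are ignored
  stray <- detection_flags(c("GHOST-1"), 0.001, "stray")
  expect_warning(
    expect_warning(intersect_detections(calls, list(stray)), "unknown"),
    "does not cover")
})

test_that("replicate concordance reports rank and linear agreement", {
  x <- c(a = 1.2, b = -0.5, c = 3.1, d = 0.4)
  same <- replicate_concordance(x, x)
  expect_equal(same$rank_correlation, 1.0)
  expect_equal(same$linear_correlation, 1.0)
  rev_ranks <- replicate_concordance(x, -x)
  expect_equal(rev_ranks$rank_correlation, -1.0)
  expect_warning(out <- replicate_concordance(x, c(a = 1, b = 1, c = 1,
                                                   d = 1)),
                 "constant")
  expect_true(is.na(out$rank_correlation))
  # paired gland replicates with small log-noise agree at rho >= 0.97 in
  # at least 95% of 200 simulated individuals (59 toxins each)
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    truth <- rnorm(59, 6, 2)
    left <- truth + rnorm(59, 0, 0.1)
    right <- truth + rnorm(59, 0, 0.1)
    replicate_concordance(left, right)$rank_correlation >= 0.97
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("naive TPM normalizes counts by length to one million", {
  expect_equal(tpm_from_counts(rep(10, 4), rep(100, 4)), rep(250000, 4))
  expect_equal(tpm_from_counts(c(10, 10), c(100, 200)),
               c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  set.seed(54)
  out <- tpm_from_counts(rpois(50, 100), sample(200:3000, 50))
  expect_equal(sum(out), 1e6, tolerance = 1e-6)
  expect_error(tpm_from_counts(c(0, 0), c(100, 100)), "zero")
})
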