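test_that("the absence rule applies its strict inequalities exactly", {
  policy <- alignment_policy()
  # depth exactly at the floor everywhere: present ("<5x" is strict)
  expect_false(call_absent(rep(5, 200), policy))
  # 11% of positions uncovered: absent (0.11 > 0.10)
  expect_true(call_absent(c(rep(0, 11), rep(100, 89)), policy))
  # exactly 10.0% low: present (">10%" is strict)
  expect_false(call_absent(c(rep(4, 10), rep(100, 90)), policy))
})

test_that("reads map end-to-end with at most two mismatches", {
  set.seed(81)
  tx <- stats::setNames(
    vapply(1:3, function(i) random_transcript(800), ""),
    c("t1", "t2", "t3"))
  reads <- gen_reads(read_sim_spec(tx, mean_depth = 10, read_length = 150,
                                   seed = 3))
  prof <- map_reads(reads, tx)
  expect_equal(attr(prof, "n_discarded"), 0L)
  expect_equal(sum(unlist(prof)), nrow(reads) * 150)
  # two substitutions survive, three do not
  r2 <- reads[1, ]
  r2$sequence <- substitute_at(r2$sequence, c(10, 70))
  r3 <- reads[1, ]
  r3$sequence <- substitute_at(r3$sequence, c(10, 70, 130))
  expect_equal(attr(map_reads(r2, tx), "n_discarded"), 0L)
  expect_equal(attr(map_reads(r3, tx), "n_discarded"), 1L)
  # a reverse-complement read is placed once, on the forward coordinates
  rc <- reads[2, ]
  rc$sequence <- revcomp(rc$sequence)
  prc <- map_reads(rc, tx)
  expect_equal(sum(unlist(prc)), 150)
})

test_that("a paralog read at 5% divergence is rejected by the mismatch filter", {
  fam <- gen_paralog_family(600, 2, 0.025, seed = 19)  # ~5% apart
  reads <- gen_reads(read_sim_spec(c(p2 = fam[["par-2"]]), mean_depth = 2,
                                   read_length = 150, seed = 5))
  # map against the other paralog only: every read should exceed 2
  # mismatches (expected ~7.5 over 150 nt)
  prof <- map_reads(reads, c(p1 = fam[["par-1"]]))
  expect_equal(attr(prof, "n_discarded"), nrow(reads))
})

test_that("multi-mapping between identical paralogs splits depth fractionally", {
  tr <- random_transcript(500, seed = 83)
  reads <- gen_reads(read_sim_spec(c(a = tr), mean_depth = 20,
                                   read_length = 150, tile = TRUE,
                                   seed = 7))
  prof <- map_reads(reads, c(a = tr, b = tr))
  # every read ties between the two copies; each gets half the depth and
  # neither is called absent
  expect_equal(prof$a, prof$b)
  expect_equal(sum(prof$a) + sum(prof$b), nrow(reads) * 150)
  # random single assignment keeps totals but breaks the tie per read
  pr <- map_reads(reads, c(a = tr, b = tr),
                  alignment_policy(multi_map = "random"), seed = 9)
  expect_equal(sum(pr$a) + sum(pr$b), nrow(reads) * 150)
})

test_that("subsampling is uniform, deterministic, and errors past the pool", {
  reads <- data.frame(id = sprintf("r%05d", 1:10000),
                      sequence = "ACGT", quality = "IIII",
                      stringsAsFactors = FALSE)
  expect_identical(subsample_reads(reads, nrow(reads), seed = 1)$id,
                   reads$id)
  expect_equal(nrow(subsample_reads(reads, 0, seed = 1)), 0L)
  expect_error(subsample_reads(reads, 10001, seed = 1), "cannot subsample")
  expect_identical(subsample_reads(reads, 5000, seed = 4)$id,
                   subsample_reads(reads, 5000, seed = 4)$id)
  # overlap of two independent half-samples concentrates at the
  # hypergeometric expectation of 50%
  s1 <- subsample_reads(reads, 5000, seed = 11)$id
  s2 <- subsample_reads(reads, 5000, seed = 12)$id
  overlap <- length(intersect(s1, s2)) / 5000
  sd_hyper <- sqrt(5000 * 0.5 * 0.5 * (5000 / 9999)) / 5000
  expect_lt(abs(overlap - 0.5), 3 * sd_hyper)
})

test_that("absence summaries reproduce the packaged reference statistics", {
  meta <- load_fixture("table3")$samples
  full <- summarize_absence(load_fixture("table4_full"), meta)
  expect_equal(full$n_variable_transcripts, 17L)
  expect_equal(full$overall_mean_missing, 4.5)
  expect_equal(full$adult_mean, 3.2)
  expect_equal(full$juvenile_mean, 5.8)
  expect_equal(unname(full$max_missing), 13)
  expect_equal(full$welch_p, 0.31, tolerance = 0.05)
  sub <- summarize_absence(load_fixture("table4_sub"), meta)
  expect_equal(sub$n_variable_transcripts, 20L)
  expect_equal(sub$overall_mean_missing, 5.4)
  expect_equal(sub$adult_mean, 3.4)
  expect_equal(sub$juvenile_mean, 7.4)
  expect_equal(sub$welch_p, 0.12, tolerance = 0.05)
  # an all-present matrix collapses every statistic to zero
  allp <- presence_absence_matrix(
    matrix(TRUE, 5, 10,
           dimnames = list(letters[1:5], meta$sample_id)))
  s0 <- summarize_absence(allp, meta)
  expect_equal(s0$overall_mean_missing, 0)
  expect_equal(s0$n_variable_transcripts, 0L)
})

test_that("relaxing the depth floor never produces more absence calls", {
  set.seed(84)
  for (i in 1:50) {
    depth <- rpois(300, lambda = runif(1, 2, 10))
    strict <- call_absent(depth, alignment_policy(min_depth = 5))
    relaxed <- call_absent(depth, alignment_policy(min_depth = 4))
    expect_true(!relaxed || strict)
  }
})

test_that("subsampling reads cannot decrease expected absence", {
  tr <- stats::setNames(vapply(1:5, function(i)
    random_transcript(600, seed = 90 + i), ""), paste0("t", 1:5))
  reads <- gen_reads(read_sim_spec(tr, mean_depth = 30, read_length = 150,
                                   seed = 13))
  full_absent <- sum(vapply(map_reads(reads, tr), call_absent, NA))
  sub <- subsample_reads(reads, nrow(reads) %/% 3, seed = 14)
  sub_absent <- sum(vapply(map_reads(sub, tr), call_absent, NA))
  expect_gte(sub_absent, full_absent)
})
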