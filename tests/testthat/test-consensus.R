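test_that("pairwise divergence is an alignment p-distance", {
  expect_equal(pairwise_divergence("ACGTACGT", "ACGTACGT"), 0)
  expect_equal(pairwise_divergence("ACGT", "ACGA"), 0.25)
  # IUPAC codes match any compatible base
  expect_equal(pairwise_divergence("ACGT", "ACRT"), 0)
  expect_equal(pairwise_divergence("ACGT", "ACYT"), 0.25)
  # a paralog pair generated at per-copy rate q sits near 2q(1-q)
  q <- 0.01
  fam <- gen_paralog_family(1000, 2, q, seed = 9)
  expected <- 2 * q * (1 - q)
  sd3 <- 3 * sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(pairwise_divergence(fam[[1]], fam[[2]]) - expected), sd3)
})

test_that("single-linkage clustering follows the connectivity criterion", {
  base <- random_transcript(1000, seed = 41)
  near <- substitute_at(base, 1:5)        # 0.5% apart
  far <- substitute_at(base, seq(1, 961, by = 48))  # ~2% apart
  one <- cluster_transcripts(c(a = base, b = near), threshold = 0.01)
  expect_length(one, 1L)
  expect_setequal(one[[1]]$member_ids, c("a", "b"))
  two <- cluster_transcripts(c(a = base, b = far), threshold = 0.015)
  expect_length(two, 2L)
  # chain a-b at 0.9%, b-c at 0.9%, a-c at 1.8%: one component at 1%
  # (substitutions scattered so the aligner cannot trade them for gaps)
  pos_ab <- seq(10, 810, by = 100)
  pos_bc <- seq(60, 860, by = 100)
  b2 <- substitute_at(base, pos_ab)
  c2 <- substitute_at(base, c(pos_ab, pos_bc))
  expect_equal(pairwise_divergence(base, c2), 0.018)
  chain <- cluster_transcripts(c(a = base, b = b2, c = c2),
                               threshold = 0.01)
  expect_length(chain, 1L)
  expect_length(chain[[1]]$member_ids, 3L)
  # complete linkage splits the same chain
  expect_gt(length(cluster_transcripts(c(a = base, b = b2, c = c2),
                                       threshold = 0.01,
                                       linkage = "complete")), 1L)
})

test_that("clustering is order-invariant and monotone in the threshold", {
  set.seed(42)
  seqs <- c(gen_paralog_family(400, 3, 0.004, seed = 1),
            gen_paralog_family(400, 2, 0.004, seed = 2) )
  names(seqs) <- sprintf("s%d", seq_along(seqs))
  members <- function(cl) lapply(cl, `[[`, "member_ids")
  canon <- function(cl) {
    ms <- lapply(members(cl), sort)
    unname(ms[order(vapply(ms, `[`, "", 1L))])
  }
  a <- cluster_transcripts(seqs, 0.012)
  b <- cluster_transcripts(rev(seqs), 0.012)
  expect_identical(canon(a), canon(b))
  # refinement: every cluster at the tight threshold sits inside one
  # cluster at the loose threshold
  tight <- members(cluster_transcripts(seqs, 0.005))
  loose <- members(cluster_transcripts(seqs, 0.05))
  for (cl in tight)
    expect_equal(sum(vapply(loose, function(L) all(cl %in% L), NA)), 1L)
})

test_that("two-stage clustering recovers the true paralog count", {
  # three true paralogs >= 4% apart; per individual, two variant copies of
  # each at ~0.4% divergence
  paralogs <- gen_paralog_family(600, 3, 0.025, seed = 14)
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(pairwise_divergence(paralogs[[i]], paralogs[[j]]), 0.04)
  individuals <- lapply(1:3, function(ind) {
    v <- unlist(lapply(1:3, function(p) {
      c(mutate_seq(paralogs[[p]], 0.002, seed = 100 * ind + p),
        mutate_seq(paralogs[[p]], 0.002, seed = 200 * ind + p))
    }))
    names(v) <- sprintf("ind%d-t%d", ind, seq_along(v))
    v
  })
  # stage 1: within-individual clustering at 1%, keep consensus sequences
  stage1 <- unlist(lapply(seq_along(individuals), function(i) {
    cl <- cluster_transcripts(individuals[[i]], threshold = 0.01)
    stats::setNames(vapply(cl, `[[`, "", "consensus"),
                    sprintf("ind%d-c%d", i, seq_along(cl)))
  }))
  # stage 2: cross-individual clustering at 1.5%
  stage2 <- cluster_transcripts(stage1, threshold = 0.015)
  expect_length(stage2, 3L)
})

test_that("consensus sequences take the columnwise majority with IUPAC ties", {
  expect_identical(consensus_sequence("ACGT"), "ACGT")
  expect_error(consensus_sequence(character(0)), "empty")
  maj <- consensus_sequence(c("ACGTACGT", "ACGTACGT", "ACTTACGT"))
  expect_identical(maj, "ACGTACGT")
  # even split at one site collapses to the ambiguity code
  expect_identical(consensus_sequence(c("ACGT", "ACAT")), "ACRT")
  # members from a tight family recover the stored ancestor closely
  fam <- gen_paralog_family(800, 5, 0.002, seed = 15)
  cons <- consensus_sequence(unname(fam))
  expect_lt(pairwise_divergence(cons, attr(fam, "ancestor")), 0.002)
})

test_that("the chimera screen flags coverage steps and keeps even profiles", {
  expect_true(chimera_screen(rep(50, 400))$keep)
  expect_true(chimera_screen(rep(c(49, 51), 200))$keep)
  stepped <- c(rep(200, 300), rep(10, 300))
  res <- chimera_screen(stepped)
  expect_false(res$keep)
  expect_lt(abs(res$breakpoint - 300), 50)
  # a simulated chimera of a low- and a high-expression transcript shows
  # the step at the junction once reads are mapped back onto it
  a <- random_transcript(400, seed = 61)
  b <- random_transcript(400, seed = 62)
  hyb <- gen_chimeric_transcript(a, b, 0.5)
  reads <- rbind(
    gen_reads(read_sim_spec(c(a = a), mean_depth = 10, read_length = 100,
                            tile = TRUE, seed = 1)),
    gen_reads(read_sim_spec(c(b = b), mean_depth = 200, read_length = 100,
                            tile = TRUE, seed = 2)))
  depth <- map_reads(reads, c(hyb = hyb))$hyb
  expect_false(chimera_screen(depth, step_ratio = 5, window = 100)$keep)
})

test_that("dedupe removes duplicates and contained sequences on either strand", {
  x <- random_transcript(300, seed = 71)
  expect_identical(unname(dedupe(c(x, x))), x)
  expect_identical(unname(dedupe(c(x, substr(x, 50, 200)))), x)
  expect_length(dedupe(c(x, revcomp(x))), 1L)
  y <- random_transcript(300, seed = 72)
  expect_length(dedupe(c(x, y)), 2L)
})
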