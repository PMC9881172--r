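# Masked similarity, greedy rank-seeded clustering, consensus statistics.

test_that("masked_similarity matches the stated examples", {
  expect_equal(masked_similarity("ACGT", "ACGT"), 1)
  expect_equal(masked_similarity("ACGT", "ACGA"), 0.75)
  # constant strings removed before comparison
  expect_equal(masked_similarity("GGACGTCC", "GGACGACC", c("GG", "CC")), 0.75)
  # missing constant region: full-length comparison with a warning
  expect_warning(
    s <- masked_similarity("TTACGTTT", "GGACGTCC", c("GG", "CC")),
    "full-length"
  )
  expect_equal(s, 1 - 4 / 8)
})

test_that("masked_similarity is symmetric and 1 iff variable regions match", {
  withr::with_seed(20, {
    for (i in 1:50) {
      a <- random_seq(sample(4:12, 1))
      b <- random_seq(sample(4:12, 1))
      expect_equal(masked_similarity(a, b), masked_similarity(b, a))
      expect_equal(masked_similarity(a, b) == 1, a == b)
    }
  })
})

test_that("masked similarity agrees with a DP edit-distance oracle", {
  withr::with_seed(21, {
    for (i in 1:400) {
      a <- random_seq(sample(1:12, 1))
      b <- random_seq(sample(1:12, 1))
      expect_equal(
        masked_similarity(a, b),
        1 - lev_oracle(a, b) / max(nchar(a), nchar(b)),
        info = paste(a, b)
      )
    }
  })
})

test_that("cluster_pool admits mutants of the seed and excludes unrelated", {
  sc <- scaffold_s1()
  withr::with_seed(22, {
    seed_seq <- sample_pool(sc, 1)
    # 30 distinct single-mutants of the variable region (non-constant part)
    mut_pos <- setdiff(seq_len(nchar(seed_seq)), c(1:20, 82:101))
    mutants <- character()
    while (length(mutants) < 30) {
      p <- sample(mut_pos, 1)
      m <- seed_seq
      substr(m, p, p) <- sample(setdiff(BASES, substr(seed_seq, p, p)), 1)
      mutants <- union(mutants, m)
    }
    unrelated <- sample_pool(sc, 30)
    reads <- c(rep(seed_seq, 50), rep(mutants, times = 30:1),
               rep(unrelated, times = rep(2, 30)))
    pool <- tally_pool(reads)
    cl <- cluster_pool(pool, 1, threshold = 0.9,
                       constant_seqs = constant_strings(sc))
    got <- cl$members$sequence
    expect_true(seed_seq %in% got)
    expect_true(all(mutants %in% got))
    expect_false(any(unrelated %in% got))
    # confirmed by brute-force similarity of every member
    for (s in got) {
      expect_gte(masked_similarity(s, seed_seq, constant_strings(sc)), 0.9)
    }
    expect_equal(cl$summary$cluster_percent,
                 sum(pool$percent[pool$sequence %in% got]))
  })
})

test_that("cluster_pool skips queries already clustered and is exclusive", {
  sc <- scaffold_s1()
  withr::with_seed(23, {
    seed_seq <- sample_pool(sc, 1)
    near <- seed_seq
    substr(near, 25, 25) <- setdiff(BASES, substr(seed_seq, 25, 25))[1]
    other <- sample_pool(sc, 1)
    pool <- tally_pool(c(rep(seed_seq, 5), rep(near, 3), rep(other, 2)))
    cl <- cluster_pool(pool, c(1, 2, 3),
                       constant_seqs = constant_strings(sc))
    expect_equal(nrow(cl$summary), 2)       # rank-2 absorbed by cluster 1
    expect_equal(cl$skipped$query_rank, 2L)
    expect_equal(cl$skipped$owner_cluster, 1L)
    # clusters are pairwise disjoint
    expect_false(any(duplicated(cl$members$sequence)))
    expect_lte(sum(cl$summary$cluster_percent), 100 + 1e-9)
    # deterministic on re-run
    cl2 <- cluster_pool(pool, c(1, 2, 3),
                        constant_seqs = constant_strings(sc))
    expect_identical(cl$members, cl2$members)
  })
})

test_that("cluster_pool respects threshold 1, max_members, and rank checks", {
  pool <- tally_pool(c("AAAA", "AAAA", "AAAT", "CCCC"))
  cl <- cluster_pool(pool, c(1, 2, 3), threshold = 1)
  expect_true(all(cl$summary$n_members == 1))
  cl2 <- cluster_pool(pool, 1, threshold = 0.5, max_members = 2)
  expect_equal(cl2$summary$n_members, 2)
  expect_error(cluster_pool(pool, 99), class = "selexr_argument_error")
  expect_error(cluster_pool(pool, 1, threshold = 0),
               class = "selexr_argument_error")
})

test_that("clustering recovers planted classes with no cross-assignment", {
  sc <- scaffold_s1()
  planted <- make_planted_pool(sc, n_members = 40, seed = 24)
  pool <- tally_pool(planted$reads)
  ranks <- vapply(planted$seeds, function(s) lookup_rank(pool, s)$rank, 1L)
  cl <- cluster_pool(pool, ranks, threshold = 0.9,
                     constant_seqs = constant_strings(sc))
  truth_by_seq <- split(planted$truth, planted$reads)
  for (k in 1:3) {
    members <- cl$members$sequence[cl$members$cluster == k]
    truths <- unique(unlist(truth_by_seq[members]))
    expect_equal(truths, paste0("class", k))  # zero cross-class
  }
})

test_that("consensus_profile computes column frequencies and covariation", {
  prof <- consensus_profile(rep("ACGT", 5))
  expect_true(all(prof$frequencies$freq %in% c(0, 1)))
  sums <- tapply(prof$frequencies$freq, prof$frequencies$position, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # GC vs AT at an annotated pair: two complementary identities -> 1
  seqs <- c("GAAC", "AAAT")
  prof2 <- consensus_profile(seqs, pair_annotation = list(c(0, 3)))
  expect_equal(prof2$covariation$covariation, 1L)
  # a non-complementary identity is not counted
  prof3 <- consensus_profile(c("GAAC", "GAAG"),
                             pair_annotation = list(c(0, 3)))
  expect_equal(prof3$covariation$n_pair_types, 1L)
  expect_equal(prof3$covariation$covariation, 0L)
  # G:U wobble counts as complementary
  prof4 <- consensus_profile(c("GAAC", "GAAT"),
                             pair_annotation = list(c(0, 3)))
  expect_equal(prof4$covariation$covariation, 1L)

  expect_error(consensus_profile(character()), class = "selexr_empty_error")
  expect_message(consensus_profile(c("ACGT", "ACGT", "ACG")), "excluded 1")
})
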