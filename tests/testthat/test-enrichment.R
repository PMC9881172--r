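# Generation tracking, capture-oligo complementarity scanning, elution
# profiles.

test_that("track_classes sums class percents per generation", {
  sc <- scaffold_s1()
  seed_seq <- sample_pool(sc, 1, seed = 30)
  pool <- tally_pool(rep(seed_seq, 10), "G1")
  tr <- track_classes(list(G1 = pool),
                      c(classA = seed_seq),
                      constant_seqs = constant_strings(sc))
  expect_equal(tr$percent, 100)

  # absent seed: flat zero trajectory
  other <- sample_pool(sc, 1, seed = 31)
  pools <- list(G1 = pool, G2 = pool)
  tr2 <- track_classes(pools, c(ghost = other),
                       constant_seqs = constant_strings(sc))
  expect_equal(tr2$percent, c(0, 0))

  expect_error(
    track_classes(list(pool), tibble::tibble(label = c("a", "a"),
                                             sequence = c(seed_seq, other))),
    class = "selexr_argument_error"
  )
})

test_that("track_classes assigns exclusively in seed order", {
  sc <- scaffold_s1()
  seed_seq <- sample_pool(sc, 1, seed = 32)
  pool <- tally_pool(rep(seed_seq, 4), "G1")
  # two identical seeds: first label takes the sequence, second gets 0
  tr <- track_classes(list(G1 = pool),
                      c(first = seed_seq, second = seed_seq),
                      constant_seqs = constant_strings(sc))
  expect_equal(tr$percent[tr$class == "first"], 100)
  expect_equal(tr$percent[tr$class == "second"], 0)
  # within one generation class percents sum to <= 100
  expect_lte(sum(tr$percent), 100 + 1e-9)
})

test_that("a strongly eluting class has a non-decreasing expected trajectory", {
  sc <- scaffold_s1()
  winner <- sample_pool(sc, 1, seed = 33)
  loser <- sample_pool(sc, 1, seed = 34)
  traj <- sapply(1:10, function(s) {
    cfg <- selex_config(
      sc,
      list(sim_class("winner", winner, 5000, p_elute = c(quinine = 0.5)),
           sim_class("slow", loser, 5000, p_leak = 0.01)),
      rounds = 4, amplification_target = 2e4, seed = 100 + s
    )
    sim <- simulate_selex(cfg)
    pools <- lapply(sim$pools[2:5], function(p) {
      tally_pool(rep(p$sequence, p$copies))
    })
    tr <- track_classes(pools, c(winner = winner),
                        constant_seqs = constant_strings(sc))
    tr$percent
  })
  mean_traj <- rowMeans(traj)
  expect_true(all(diff(mean_traj) > -1))  # non-decreasing up to sampling noise
  expect_gt(mean_traj[4], mean_traj[1])
})

test_that("scan finds planted complementarity and flags the capture site", {
  oligo <- capture_oligo()
  # plant the reverse complement of an oligo region outside the capture site
  insert <- rc_oracle(substr(oligo, 21, 27))  # oligo span [20, 27) 0-based
  seqq <- paste0("TTTT", insert, "TTTT")
  hits <- scan_capture_complementarity(seqq, oligo, min_len = 7)
  expect_equal(nrow(hits), 1)
  expect_gte(hits$length, 7)
  expect_false(hits$inside_capture_site)
  # the reported spans really are reverse complements of each other
  read_sub <- substr(seqq, hits$read_start + 1, hits$read_end)
  oligo_sub <- substr(oligo, hits$oligo_start + 1, hits$oligo_end)
  expect_identical(read_sub, rc_oracle(oligo_sub))

  # a full reverse complement of the oligo: one maximal hit spanning it,
  # flagged where it overlaps the annotated capture site on the read
  full <- rc_oracle(oligo)
  hits2 <- scan_capture_complementarity(full, oligo, min_len = 7,
                                        capture_site_span = c(0L, 10L))
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$length, nchar(oligo))
  expect_true(hits2$inside_capture_site)

  expect_error(scan_capture_complementarity("ACGT", oligo, min_len = 1),
               class = "selexr_argument_error")
})

test_that("scan agrees with the all-substrings oracle", {
  withr::with_seed(35, {
    for (i in 1:150) {
      seqq <- random_seq(sample(10:30, 1))
      oligo <- random_seq(sample(8:15, 1))
      got <- scan_capture_complementarity(seqq, oligo, min_len = 3)
      want <- scan_oracle(seqq, oligo, min_len = 3)
      got_df <- as.data.frame(got[, 1:5])
      rownames(got_df) <- rownames(want) <- NULL
      expect_equal(got_df, want, info = paste(seqq, oligo))
    }
  })
})

test_that("match counts on random sequences follow the closed form", {
  withr::with_seed(36, {
    n <- 100
    m <- 30
    min_len <- 7
    oligo <- random_seq(m)
    nsim <- 10000
    counts <- vapply(seq_len(nsim), function(i) {
      nrow(scan_capture_complementarity(random_seq(n), oligo,
                                        min_len = min_len))
    }, 1L)
    # expected maximal runs >= 7: per diagonal of length d, one boundary
    # start at (1/4)^7 plus (d - 7) interior starts at (3/4)(1/4)^7
    diag_lens <- vapply(seq(-(m - 1), n - 1), function(off) {
      i0 <- max(1, 1 + off)
      j0 <- i0 - off
      min(n - i0, m - j0) + 1
    }, 1)
    diag_lens <- diag_lens[diag_lens >= min_len]
    p7 <- (1 / 4)^min_len
    expected <- sum(p7 + pmax(0, diag_lens - min_len) * (3 / 4) * p7)
    se <- stats::sd(counts) / sqrt(nsim)
    expect_lt(abs(mean(counts) - expected), 3 * se + 1e-12)
  })
})

test_that("summarize_elution normalizes and calls specific elution", {
  prof <- tibble::tibble(
    label = c("unbound", "wash#1", "wash#2", "compound:caffeine",
              "remaining-matrix"),
    signal = c(50, 1.5, 0.5, 9, 39)
  )
  out <- summarize_elution(prof, c("wash#1", "wash#2"))
  expect_equal(sum(out$percent), 100)
  expect_true(out$specific[out$label == "compound:caffeine"])

  # compound equal to background mean: not specific
  prof2 <- prof
  prof2$signal[4] <- 1
  out2 <- summarize_elution(prof2, c("wash#1", "wash#2"))
  expect_false(out2$specific[out2$label == "compound:caffeine"])

  # pure normalization example
  prof3 <- tibble::tibble(
    label = c("wash#1", "wash#2", "compound:x"),
    signal = c(50, 30, 20)
  )
  out3 <- summarize_elution(prof3, c("wash#1", "wash#2"))
  expect_equal(out3$percent, c(50, 30, 20))

  expect_error(
    summarize_elution(tibble::tibble(label = c("wash#1", "wash#2", "compound:x"),
                                     signal = c(0, 0, 0)),
                      c("wash#1", "wash#2")),
    class = "selexr_degenerate_error"
  )
  expect_error(summarize_elution(prof, "wash#1"),
               class = "selexr_argument_error")
  expect_error(
    summarize_elution(tibble::tibble(label = c("wash#1", "wash#2"),
                                     signal = c(1, 2)),
                      c("wash#1", "wash#2")),
    class = "selexr_argument_error"
  )
})
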