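# The Capture-SELEX round simulator and read emitter.

toy_scaffold <- function() scaffold_s1()

test_that("a guaranteed-elution class stays at abundance 1", {
  sc <- toy_scaffold()
  cfg <- selex_config(
    sc,
    list(sim_class("only", sample_pool(sc, 1, seed = 50), 1000,
                   p_elute = c(quinine = 1))),
    rounds = 4, amplification_target = 5000, seed = 1
  )
  sim <- simulate_selex(cfg)
  expect_true(all(sim$truth$true_fraction == 1))
  expect_equal(nrow(sim$truth), 5)  # rounds 0..4
})

test_that("per-round fractions sum to 1 and reads trace to classes", {
  sc <- toy_scaffold()
  cfg <- selex_config(
    sc,
    list(sim_class("a", sample_pool(sc, 1, seed = 51), 2000,
                   cloud_degeneracy = 0.02, p_elute = c(quinine = 0.5)),
         sim_class("b", sample_pool(sc, 1, seed = 52), 2000, p_leak = 0.05)),
    rounds = 3, background_copies = 2000, amplification_target = 2e4,
    seed = 2
  )
  sim <- simulate_selex(cfg)
  sums <- tapply(sim$truth$true_fraction, sim$truth$round, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  reads <- emit_reads(sim$pools[[4]], 500, seed = 3)
  expect_true(all(reads$class %in% c("a", "b", ".background")))
  expect_equal(nrow(reads), 500)
})

test_that("two-class enrichment follows the closed-form update rule", {
  sc <- toy_scaffold()
  a_seq <- sample_pool(sc, 1, seed = 53)
  b_seq <- sample_pool(sc, 1, seed = 54)
  r <- 3
  ratios <- vapply(1:20, function(s) {
    cfg <- selex_config(
      sc,
      list(sim_class("A", a_seq, 1e4, p_elute = c(quinine = 0.5)),
           sim_class("B", b_seq, 1e4, p_leak = 0.05)),
      rounds = r, amplification_target = 1e5, seed = 200 + s
    )
    sim <- simulate_selex(cfg)
    fin <- sim$truth[sim$truth$round == r, ]
    fin$true_fraction[fin$class == "A"] / fin$true_fraction[fin$class == "B"]
  }, 1)
  closed_form <- (0.5 / 0.05)^r
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - closed_form), 3 * se)
})

test_that("neutral configurations show no systematic enrichment", {
  sc <- toy_scaffold()
  seqs <- sample_pool(sc, 3, seed = 55)
  finals <- sapply(1:20, function(s) {
    cfg <- selex_config(
      sc,
      list(sim_class("x", seqs[1], 3000, p_elute = c(quinine = 0.2)),
           sim_class("y", seqs[2], 3000, p_elute = c(quinine = 0.2)),
           sim_class("z", seqs[3], 3000, p_elute = c(quinine = 0.2))),
      rounds = 4, amplification_target = 3e4, seed = 300 + s
    )
    sim <- simulate_selex(cfg)
    sim$truth$true_fraction[sim$truth$round == 4]
  })
  means <- rowMeans(finals)
  se <- apply(finals, 1, stats::sd) / sqrt(20)
  expect_true(all(abs(means - 1 / 3) < 3 * se))
})

test_that("removing a class's ligand causes its expected decline", {
  sc <- toy_scaffold()
  q_seq <- sample_pool(sc, 1, seed = 56)
  o_seq <- sample_pool(sc, 1, seed = 57)
  # quinine leaves the mix after round 3; the quinine class keeps only a
  # small leak and must decline relative to the surviving eluter
  drop_round <- 3
  fracs <- sapply(1:10, function(s) {
    cfg <- selex_config(
      sc,
      list(sim_class("quin", q_seq, 5000,
                     p_elute = c(quinine = 0.5), p_leak = 0.02),
           sim_class("caff", o_seq, 5000, p_elute = c(caffeine = 0.3))),
      rounds = 6,
      elution_mix_schedule = default_mix_schedule(6, switch_after = drop_round),
      amplification_target = 5e4, seed = 400 + s
    )
    sim <- simulate_selex(cfg)
    sim$truth$true_fraction[sim$truth$class == "quin"]
  })
  mean_traj <- rowMeans(fracs)
  post <- mean_traj[(drop_round + 2):length(mean_traj)]
  expect_true(all(diff(post) < 1e-3))       # non-increasing after the drop
  expect_lt(mean_traj[7], mean_traj[drop_round + 1])
})

test_that("emit_reads has exact depth, overlap-consistent mates, qualities", {
  pool <- tibble::tibble(sequence = random_seq(100), copies = 1L)
  reads <- emit_reads(pool, depth = 25, seed = 60)
  expect_equal(nrow(reads), 25)
  # error-free pairs merge back to the template exactly
  merged <- merge_pairs(reads, quiet = TRUE)
  expect_true(all(merged$merged))
  expect_true(all(merged$merged_seq == pool$sequence))
  # qualities encode the error rate
  reads_err <- emit_reads(pool, depth = 5, error_rate = 0.01, seed = 61)
  expect_equal(substr(reads_err$r1_qual[1], 1, 1), rawToChar(as.raw(20 + 33)))

  long_pool <- tibble::tibble(sequence = random_seq(400), copies = 1L)
  expect_warning(expect_error(emit_reads(long_pool, 5, read_length = 150),
                              class = "selexr_empty_error"),
                 "longer than 2x")
})

test_that("sequencing errors occur at the configured per-base rate", {
  withr::with_seed(62, {
    pool <- tibble::tibble(sequence = random_seq(100), copies = 1L)
    n_pairs <- 10000
    reads <- emit_reads(pool, depth = n_pairs, error_rate = 0.01)
    obs <- mean(strsplit(paste(reads$r1_seq, collapse = ""), "")[[1]] !=
                  strsplit(strrep(pool$sequence, n_pairs), "")[[1]])
    n_bases <- n_pairs * 100
    se <- sqrt(0.01 * 0.99 / n_bases)
    expect_lt(abs(obs - 0.01), 3 * se)
  })
})

test_that("identical config and seed give byte-identical FASTQ", {
  sc <- toy_scaffold()
  cfg <- selex_config(
    sc, list(sim_class("a", sample_pool(sc, 1, seed = 63), 500,
                       cloud_degeneracy = 0.02, p_elute = c(quinine = 0.5))),
    rounds = 2, amplification_target = 2000, seed = 9
  )
  out <- replicate(2, {
    sim <- simulate_selex(cfg)
    reads <- emit_reads(sim$pools[[3]], 200, error_rate = 0.005, seed = 10)
    r1 <- withr::local_tempfile(fileext = ".fastq")
    r2 <- withr::local_tempfile(fileext = ".fastq")
    write_read_pairs(reads, r1, r2)
    c(paste(readLines(r1), collapse = "\n"), paste(readLines(r2), collapse = "\n"))
  })
  expect_identical(out[, 1], out[, 2])
})

test_that("extinction stops the simulation early with a warning", {
  sc <- toy_scaffold()
  cfg <- selex_config(
    sc, list(sim_class("doomed", sample_pool(sc, 1, seed = 64), 10,
                       p_elute = c(quinine = 0))),
    rounds = 5, amplification_target = 100, seed = 11
  )
  expect_warning(sim <- simulate_selex(cfg), "extinct")
  expect_true(sim$early_stop)
})

test_that("synthetic titrations have the right shape and scaling", {
  ser <- synth_titration(1e-6, noise_sd = 0, n_sites = 2)
  expect_equal(unique(ser$direction), c("increase", "decrease"))
  # scaling kd and concentrations together leaves normalized curves identical
  ser10 <- synth_titration(1e-5, concentrations = unique(ser$concentration_M) * 10,
                           noise_sd = 0, n_sites = 2)
  n1 <- normalize_sites(ser)
  n10 <- normalize_sites(ser10)
  expect_equal(n1$fraction_modulated, n10$fraction_modulated, tolerance = 1e-12)
})
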