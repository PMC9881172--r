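# Stochastic Capture-SELEX round simulator.
#
# Generative model, per round: each molecule is released from the capture
# column (and so survives into the amplified next-generation pool)
# independently with probability
#   p = 1 - (1 - p_elute_effective) * (1 - p_leak)
# where p_elute_effective is the max over the compounds present in that
# round's elution mix of the class's per-compound elution probability (0 when
# the ligand is absent — ligand removal mid-selection). Survivors are then
# resampled multinomially to the amplification target (the RT-PCR /
# transcription step), and sequencing draws reads multinomially from the
# amplified pool with i.i.d. per-base substitution errors.

#' Define a simulated sequence class
#'
#' A class is a seed sequence plus a mutational cloud and a survival
#' strategy: ligand-dependent elution probabilities per compound
#' (`p_elute`), ligand-independent slow leak (`p_leak`, the "selfish"
#' mechanism), or both (a mixed strategy).
#'
#' @param label Class label.
#' @param seed_sequence The class's reference sequence.
#' @param initial_copies Copies at generation 0.
#' @param cloud_degeneracy Per-position mutation fraction used to build the
#'   class's mutational cloud around the seed.
#' @param p_elute Named numeric vector: compound label -> per-round elution
#'   probability when that compound is present in the elution mix.
#' @param p_leak Per-round ligand-independent release probability.
#' @param n_cloud_variants Distinct cloud variants generated (copies are
#'   spread evenly across them).
#' @return A `sim_class` list.
#' @export
sim_class <- function(label, seed_sequence, initial_copies,
                      cloud_degeneracy = 0, p_elute = numeric(),
                      p_leak = 0, n_cloud_variants = 200) {
  if (any(p_elute < 0 | p_elute > 1) || p_leak < 0 || p_leak > 1) {
    abort("probabilities must be in [0, 1]", class = "selexr_argument_error")
  }
  if (initial_copies < 0) {
    abort("initial_copies must be >= 0", class = "selexr_argument_error")
  }
  structure(
    list(label = label,
         seed_sequence = normalize_seq(seed_sequence, what = "seed_sequence"),
         initial_copies = initial_copies,
         cloud_degeneracy = cloud_degeneracy,
         p_elute = p_elute, p_leak = p_leak,
         n_cloud_variants = n_cloud_variants),
    class = "sim_class"
  )
}

#' Configure a Capture-SELEX simulation
#'
#' @param scaffold A `selex_scaffold`; its constant spans protect the
#'   mutational clouds and its random sampling provides the background.
#' @param classes List of [sim_class()] objects.
#' @param rounds Number of selection rounds (>= 1).
#' @param elution_mix_schedule List (length `rounds`) of character vectors:
#'   the compounds present in each round's elution mix. Default: the
#'   eight-compound mix for rounds 1-13, then the six-compound mix (guanine
#'   and quinine removed) for later rounds, mirroring a mid-selection ligand
#'   removal.
#' @param background_copies Copies of unrelated random scaffold molecules at
#'   generation 0.
#' @param background_p_survive Per-round survival probability of background
#'   molecules.
#' @param amplification_target Total copies after each round's amplification.
#' @param sequencing_depth Read pairs per sequenced round.
#' @param read_length Read length (default 150).
#' @param per_base_error_rate Sequencing substitution error rate per base.
#' @param n_background_variants Distinct background sequences sampled.
#' @param seed Integer seed making the whole simulation reproducible.
#' @return A `selex_sim_config` list.
#' @export
selex_config <- function(scaffold, classes, rounds,
                         elution_mix_schedule = NULL,
                         background_copies = 0,
                         background_p_survive = 0.02,
                         amplification_target = 1e5,
                         sequencing_depth = 1e4,
                         read_length = 150,
                         per_base_error_rate = 0,
                         n_background_variants = 1000,
                         seed = 1) {
  if (rounds < 1) abort("rounds must be >= 1", class = "selexr_argument_error")
  if (sequencing_depth < 1) {
    abort("sequencing_depth must be >= 1", class = "selexr_argument_error")
  }
  elution_mix_schedule <- elution_mix_schedule %||%
    default_mix_schedule(rounds)
  if (length(elution_mix_schedule) != rounds) {
    abort("elution_mix_schedule must have one entry per round",
          class = "selexr_argument_error")
  }
  structure(
    list(scaffold = scaffold, classes = classes, rounds = as.integer(rounds),
         elution_mix_schedule = elution_mix_schedule,
         background_copies = background_copies,
         background_p_survive = background_p_survive,
         amplification_target = amplification_target,
         sequencing_depth = sequencing_depth,
         read_length = as.integer(read_length),
         per_base_error_rate = per_base_error_rate,
         n_background_variants = n_background_variants,
         seed = as.integer(seed)),
    class = "selex_sim_config"
  )
}

#' Default multiplexed elution schedule
#'
#' Eight compounds (several over-the-counter drugs plus guanine and glucose)
#' for rounds 1-13, then a six-compound subset excluding guanine and quinine
#' for any later rounds.
#'
#' @param rounds Number of rounds.
#' @param switch_after Last round using the full mix (default 13).
#' @return List of character vectors, one per round.
#' @export
default_mix_schedule <- function(rounds, switch_after = 13) {
  eight <- c("quinine", "guanine", "caffeine", "naproxen", "acetaminophen",
             "aspirin", "ibuprofen", "glucose")
  six <- setdiff(eight, c("guanine", "quinine"))
  lapply(seq_len(rounds), function(r) if (r <= switch_after) eight else six)
}

# effective survival probability for a class given a round's elution mix
class_survival_prob <- function(cls, mix) {
  pe <- 0
  present <- intersect(names(cls$p_elute), mix)
  if (length(present)) pe <- max(cls$p_elute[present])
  1 - (1 - pe) * (1 - cls$p_leak)
}

#' Run a Capture-SELEX simulation
#'
#' Builds the generation-0 pool (per-class mutational clouds plus random
#' scaffold background), then iterates rounds of independent Bernoulli
#' survival and multinomial re-amplification. Identical configuration and
#' seed give identical results.
#'
#' @param config A [selex_config()].
#' @return A `selex_sim` list: `truth` (tibble `round`, `class`,
#'   `true_fraction`; round 0 = initial pool), `pools` (list, per round 0..R,
#'   of tibbles `sequence`, `class`, `copies`), `survival` (tibble `round`,
#'   `class`, `survivors`), `config`.
#' @export
simulate_selex <- function(config) {
  stopifnot(inherits(config, "selex_sim_config"))
  with_seed_if(config$seed, {
    pool <- build_g0_pool(config)
    pools <- list(pool)
    truth <- list(pool_fractions(pool, 0L))
    survival <- list()
    early_stop <- FALSE
    class_labels <- vapply(config$classes, `[[`, "", "label")
    for (r in seq_len(config$rounds)) {
      mix <- config$elution_mix_schedule[[r]]
      p_map <- c(
        setNames(vapply(config$classes, class_survival_prob, 0, mix = mix),
                 class_labels),
        .background = config$background_p_survive
      )
      p <- unname(p_map[pool$class])
      surv <- rbinom(nrow(pool), size = pool$copies, prob = p)
      survival[[r]] <- tibble(round = r, class = pool$class,
                              survivors = surv) %>%
        group_by(.data$round, .data$class) %>%
        summarise(survivors = sum(.data$survivors), .groups = "drop")
      if (sum(surv) == 0) {
        warn(sprintf("all molecules extinct at round %d; stopping early", r))
        early_stop <- TRUE
        break
      }
      keep <- surv > 0
      amp <- rmultinom(1, size = config$amplification_target,
                       prob = surv[keep])[, 1]
      pool <- tibble(sequence = pool$sequence[keep],
                     class = pool$class[keep],
                     copies = as.integer(amp))
      pool <- pool[pool$copies > 0, ]
      pools[[r + 1]] <- pool
      truth[[r + 1]] <- pool_fractions(pool, r)
    }
    structure(
      list(truth = bind_rows(truth), pools = pools,
           survival = bind_rows(survival), early_stop = early_stop,
           config = config),
      class = "selex_sim"
    )
  })
}

build_g0_pool <- function(config) {
  prot <- config$scaffold$constant_spans
  parts <- purrr::map(config$classes, function(cls) {
    if (cls$initial_copies == 0) return(NULL)
    nvar <- max(1L, min(cls$n_cloud_variants, cls$initial_copies))
    seqs <- if (cls$cloud_degeneracy > 0 && nvar > 1L) {
      c(cls$seed_sequence,
        mutagenize(cls$seed_sequence, cls$cloud_degeneracy, prot,
                   n = nvar - 1L))
    } else {
      cls$seed_sequence
    }
    copies <- rep(cls$initial_copies %/% length(seqs), length(seqs))
    copies[1] <- copies[1] + cls$initial_copies %% length(seqs)
    tibble(sequence = seqs, class = cls$label, copies = as.integer(copies))
  })
  bg <- NULL
  if (config$background_copies > 0) {
    nbg <- max(1L, min(config$n_background_variants, config$background_copies))
    seqs <- sample_pool(config$scaffold, nbg)
    copies <- rep(config$background_copies %/% nbg, nbg)
    copies[1] <- copies[1] + config$background_copies %% nbg
    bg <- tibble(sequence = seqs, class = ".background",
                 copies = as.integer(copies))
  }
  pool <- bind_rows(c(parts, list(bg)))
  pool[pool$copies > 0, ]
}

pool_fractions <- function(pool, round) {
  pool %>%
    group_by(.data$class) %>%
    summarise(copies = sum(.data$copies), .groups = "drop") %>%
    mutate(round = round, true_fraction = .data$copies / sum(.data$copies)) %>%
    select("round", "class", "true_fraction")
}

#' @export
print.selex_sim <- function(x, ...) {
  cat(sprintf("<selex_sim> %d round(s)%s\n",
              length(x$pools) - 1L,
              if (x$early_stop) " (stopped early: extinction)" else ""))
  print(tidyr::pivot_wider(x$truth, names_from = "class",
                           values_from = "true_fraction"))
  invisible(x)
}

# apply i.i.d. substitution errors to a character vector of sequences
add_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    ch <- seq_chars1(seqs[i])
    pos <- sample.int(length(ch), n_err[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Emit paired-end reads from a simulated pool
#'
#' Reads are drawn multinomially by copy number. Each template yields a mate
#' pair covering it from both ends (R1 from the 5' end, R2 the reverse
#' complement from the 3' end, in sequencer orientation), overlapping
#' whenever the template is shorter than twice the read length. Substitution
#' errors are i.i.d. per base; qualities are constant at the Phred score
#' corresponding to the error rate. Templates longer than twice the read
#' length cannot be merged and are skipped with a warning.
#'
#' @param pool Tibble with columns `sequence`, `copies` (and optionally
#'   `class`), e.g. one element of a `selex_sim`'s `pools`.
#' @param depth Number of read pairs.
#' @param read_length Read length (default 150).
#' @param error_rate Per-base substitution error rate.
#' @param seed Optional integer seed.
#' @return Tibble: `id`, `class`, `template`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual` — every read traceable to its true template and class.
#' @export
emit_reads <- function(pool, depth, read_length = 150, error_rate = 0,
                       seed = NULL) {
  stopifnot(all(c("sequence", "copies") %in% names(pool)))
  if (nrow(pool) == 0) {
    abort("empty pool", class = "selexr_empty_error")
  }
  if (depth < 1) abort("depth must be >= 1", class = "selexr_argument_error")
  too_long <- nchar(pool$sequence) > 2 * read_length
  if (any(too_long)) {
    warn(sprintf(
      "%d template(s) longer than 2x read length skipped (cannot be merged)",
      sum(too_long)
    ))
    pool <- pool[!too_long, ]
    if (nrow(pool) == 0) abort("empty pool", class = "selexr_empty_error")
  }
  with_seed_if(seed, {
    counts <- rmultinom(1, size = depth, prob = pool$copies)[, 1]
    idx <- rep.int(seq_len(nrow(pool)), counts)
    templates <- pool$sequence[idx]
    classes <- if ("class" %in% names(pool)) pool$class[idx] else
      NA_character_
    len <- nchar(templates)
    r1 <- substr(templates, 1, pmin(read_length, len))
    r2 <- revcomp(substr(templates, pmax(1, len - read_length + 1), len))
    r1 <- add_read_errors(r1, error_rate)
    r2 <- add_read_errors(r2, error_rate)
    q <- if (error_rate > 0) {
      min(40L, as.integer(round(-10 * log10(error_rate))))
    } else 40L
    qc <- intToUtf8(q + 33L)
    tibble(
      id = sprintf("read%06d", seq_along(templates)),
      class = classes,
      template = templates,
      r1_seq = r1, r1_qual = strrep(qc, nchar(r1)),
      r2_seq = r2, r2_qual = strrep(qc, nchar(r2))
    )
  })
}

#' Write emitted read pairs as a pair of FASTQ files
#'
#' @param reads Tibble from [emit_reads()].
#' @param r1_path,r2_path Output FASTQ paths (".gz" supported).
#' @return `c(r1_path, r2_path)`, invisibly.
#' @export
write_read_pairs <- function(reads, r1_path, r2_path) {
  write_fastq(tibble(id = reads$id, seq = reads$r1_seq, qual = reads$r1_qual),
              r1_path)
  write_fastq(tibble(id = reads$id, seq = reads$r2_seq, qual = reads$r2_qual),
              r2_path)
  invisible(c(r1_path, r2_path))
}

#' Generate a synthetic titration series
#'
#' Band intensities follow the n = 1 binding isotherm with multiplicative
#' Gaussian noise; site directions alternate (odd sites increase with ligand,
#' even sites decrease), mimicking structural modulation read out at several
#' sites of an in-line probing gel.
#'
#' @param kd Dissociation constant (M, > 0).
#' @param concentrations Ligand concentrations (M). Default: 8 log-spaced
#'   points spanning 0.01-100 x Kd.
#' @param noise_sd Multiplicative Gaussian noise SD.
#' @param n_sites Number of modulating sites.
#' @param f0 Baseline fraction bound contribution.
#' @param amplitude Isotherm amplitude.
#' @param seed Optional integer seed.
#' @return A titration tibble: `concentration_M`, `site_id`, `intensity`,
#'   `direction` — ready for [fit_kd()].
#' @export
synth_titration <- function(kd, concentrations = NULL, noise_sd = 0,
                            n_sites = 3, f0 = 0, amplitude = 1, seed = NULL) {
  if (kd <= 0) abort("kd must be > 0", class = "selexr_argument_error")
  concentrations <- concentrations %||% (kd * 10^seq(-2, 2, length.out = 8))
  theta <- f0 + amplitude * concentrations / (kd + concentrations)
  with_seed_if(seed, {
    purrr::map_dfr(seq_len(n_sites), function(s) {
      increasing <- s %% 2 == 1
      base <- if (increasing) 0.1 + theta else 1.1 - theta
      noise <- if (noise_sd > 0) {
        1 + rnorm(length(base), sd = noise_sd)
      } else 1
      tibble(
        concentration_M = concentrations,
        site_id = sprintf("site%d", s),
        intensity = pmax(0, base * noise),
        direction = if (increasing) "increase" else "decrease"
      )
    })
  })
}
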