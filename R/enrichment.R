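# Cross-generation class tracking, selfish capture-oligo complementarity
# scanning, and elution-profile summaries.

#' Track class abundances across selection generations
#'
#' For each generation pool, every sequence is assigned to the first class
#' seed (in seed order) whose masked similarity is at least `threshold` —
#' the same exclusive-membership rule as [cluster_pool()] — and per-class
#' percents are summed. The result is the long table behind
#' class-vs-generation enrichment plots.
#'
#' @param pools List of `tallied_pool` objects, in generation order. Names
#'   (or each pool's `generation_label` attribute) label the generations.
#' @param seeds Tibble (or named character vector) with columns `label`,
#'   `sequence`: one reference sequence per class. Labels must be distinct.
#' @param threshold Similarity threshold (default 0.90, matching clustering).
#' @param constant_seqs Constant-region strings excluded from comparison.
#' @return A `generation_track` tibble: `class`, `generation`, `percent`,
#'   with `generation` an ordered factor.
#' @export
track_classes <- function(pools, seeds, threshold = 0.90,
                          constant_seqs = character()) {
  if (length(pools) < 1) {
    abort("need at least one pool", class = "selexr_argument_error")
  }
  if (is.character(seeds)) {
    seeds <- tibble(label = names(seeds) %||% paste0("class", seq_along(seeds)),
                    sequence = unname(seeds))
  }
  if (anyDuplicated(seeds$label)) {
    abort("duplicate class labels", class = "selexr_argument_error")
  }
  gen_labels <- names(pools) %||% vapply(seq_along(pools), function(i) {
    attr(pools[[i]], "generation_label") %||% paste0("G", i)
  }, "")
  seed_vars <- suppressWarnings(
    mask_constant_regions(seeds$sequence, constant_seqs)
  )
  out <- purrr::map_dfr(seq_along(pools), function(g) {
    pool <- pools[[g]]
    pool <- pool[order(pool$rank), ]
    vars <- suppressWarnings(
      mask_constant_regions(pool$sequence, constant_seqs)
    )
    taken <- rep(FALSE, nrow(pool))
    purrr::map_dfr(seq_len(nrow(seeds)), function(s) {
      sims <- similarity_to(seed_vars[s], vars)
      hit <- !taken & sims >= threshold
      taken[hit] <<- TRUE
      tibble(class = seeds$label[s], generation = gen_labels[g],
             percent = sum(pool$percent[hit]))
    })
  })
  out$generation <- factor(out$generation, levels = unique(gen_labels),
                           ordered = TRUE)
  class(out) <- c("generation_track", class(out))
  out
}

#' Scan a sequence for complementarity to the capture oligonucleotide
#'
#' Reports every maximal exact reverse-complement match of length at least
#' `min_len` between the sequence and the capture oligo. Hits whose span on
#' the read overlaps the annotated intended capture site are flagged
#' `inside_capture_site`; candidate "selfish" hits — unintended transient
#' hybridization sites that let molecules leak off the capture column — are
#' the unflagged ones. All coordinates are 0-based, half-open: `read_start`/
#' `read_end` on the query, `oligo_start`/`oligo_end` on the oligo itself.
#'
#' @param sequence Query sequence (a pool member).
#' @param capture_oligo Capture oligonucleotide sequence.
#' @param min_len Minimum match length (default 7, >= 2).
#' @param capture_site_span Optional 0-based half-open interval on the
#'   *sequence* marking the intended capture site.
#' @return Tibble: `read_start`, `read_end`, `oligo_start`, `oligo_end`,
#'   `length`, `inside_capture_site`.
#' @export
scan_capture_complementarity <- function(sequence, capture_oligo, min_len = 7,
                                         capture_site_span = NULL) {
  if (min_len < 2) {
    abort("min_len must be >= 2", class = "selexr_argument_error")
  }
  sequence <- normalize_seq(sequence, what = "sequence")
  capture_oligo <- normalize_seq(capture_oligo, what = "capture_oligo")
  a <- seq_chars1(sequence)
  rco <- seq_chars1(revcomp(capture_oligo))
  n <- length(a)
  m <- length(rco)
  if (!is.null(capture_site_span)) check_span(capture_site_span, n)
  hits <- list()
  # scan every alignment diagonal of sequence vs revcomp(oligo) for maximal
  # runs of equality
  for (off in seq(-(m - 1), n - 1)) {
    i0 <- max(1L, 1L + off)          # first seq index on this diagonal
    j0 <- i0 - off                   # matching rc-oligo index
    len <- min(n - i0, m - j0) + 1L
    if (len < min_len) next
    eq <- a[i0:(i0 + len - 1)] == rco[j0:(j0 + len - 1)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_len)
    for (k in runs) {
      si <- i0 + starts[k] - 1L      # 1-based seq start
      oj <- j0 + starts[k] - 1L      # 1-based rc-oligo start
      L <- r$lengths[k]
      read_span <- c(si - 1L, si - 1L + L)
      # rc-oligo positions [oj, oj+L) map back to oligo [m-oj-L+1, m-oj+1)
      oligo_span <- c(m - (oj - 1L) - L, m - (oj - 1L))
      inside <- if (is.null(capture_site_span)) FALSE else
        spans_overlap(read_span, capture_site_span)
      hits[[length(hits) + 1]] <- tibble(
        read_start = read_span[1], read_end = read_span[2],
        oligo_start = oligo_span[1], oligo_end = oligo_span[2],
        length = L, inside_capture_site = inside
      )
    }
  }
  if (length(hits) == 0) {
    return(tibble(read_start = integer(), read_end = integer(),
                  oligo_start = integer(), oligo_end = integer(),
                  length = integer(), inside_capture_site = logical()))
  }
  bind_rows(hits) %>% arrange(.data$read_start, .data$oligo_start)
}

#' Summarize an elution profile
#'
#' Converts per-fraction signals (e.g. scintillation or densitometry counts
#' for unbound, wash, mock, and compound elution fractions) into
#' percent-of-total, and calls a compound fraction "specific" iff its signal
#' is at least `k` times the mean of the designated background fractions.
#' Compound fractions are those labelled `compound:<name>`.
#'
#' @param profile Tibble with columns `label`, `signal` (non-negative), in
#'   fraction order. Conventional labels: `unbound`, `wash#N`, `mock`,
#'   `compound:<name>`, `remaining-matrix`.
#' @param background_fractions Labels of the fractions treated as background
#'   (>= 2 required), e.g. the two washes preceding the elution.
#' @param k Specificity multiple over mean background (default 3).
#' @return An `elution_summary` tibble: `label`, `signal`, `percent`,
#'   `is_compound`, `specific` (NA for non-compound fractions).
#' @export
#' @examples
#' summarize_elution(
#'   tibble::tibble(
#'     label = c("unbound", "wash#1", "wash#2", "compound:caffeine",
#'               "remaining-matrix"),
#'     signal = c(50, 2, 1, 9, 38)
#'   ),
#'   background_fractions = c("wash#1", "wash#2")
#' )
summarize_elution <- function(profile, background_fractions, k = 3) {
  stopifnot(all(c("label", "signal") %in% names(profile)))
  if (any(profile$signal < 0)) {
    abort("signals must be non-negative", class = "selexr_argument_error")
  }
  if (sum(profile$signal) == 0) {
    abort("degenerate input: all signals are zero",
          class = "selexr_degenerate_error")
  }
  is_compound <- startsWith(profile$label, "compound:")
  if (sum(is_compound) < 1) {
    abort("need at least one compound:<name> fraction",
          class = "selexr_argument_error")
  }
  bg <- profile$signal[profile$label %in% background_fractions]
  if (length(bg) < 2) {
    abort("need at least two background fractions",
          class = "selexr_argument_error")
  }
  out <- profile %>%
    mutate(
      percent = 100 * .data$signal / sum(.data$signal),
      is_compound = is_compound,
      specific = ifelse(is_compound, .data$signal >= k * mean(bg), NA)
    )
  class(out) <- c("elution_summary", class(out))
  out
}
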