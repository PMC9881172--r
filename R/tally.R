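# Collapse merged reads into a ranked abundance table: one row per unique
# sequence with its read count, percent abundance, and 1-based rank.

new_tallied_pool <- function(df, total_reads, generation_label) {
  structure(
    df,
    total_reads = as.integer(total_reads),
    generation_label = generation_label,
    class = c("tallied_pool", class(tibble()))
  )
}

#' Tally reads into a ranked abundance table
#'
#' Collapses a stream of sequences by exact match (case-insensitive, U
#' normalized to T) and ranks unique sequences by count, descending. Ties are
#' broken by first occurrence in the stream, then lexicographically. Exact
#' matching is deliberate: sequencing errors are absorbed later, at the
#' clustering stage.
#'
#' @param sequences Character vector of merged reads (or a file path readable
#'   by [read_sequences()]).
#' @param generation_label Label for the pool (e.g. `"G13"`).
#' @param drop_ambiguous Drop reads containing degenerate codes (default
#'   keeps them).
#' @return A `tallied_pool` tibble with columns `sequence`, `count`,
#'   `percent`, `rank`; attributes `total_reads` and `generation_label`.
#' @export
#' @examples
#' tally_pool(c("AC", "AC", "GT"), "G1")
tally_pool <- function(sequences, generation_label = "pool",
                       drop_ambiguous = FALSE) {
  if (length(sequences) == 1 && file.exists(sequences) &&
      !grepl("^[ACGTUacgtu]+$", sequences)) {
    sequences <- read_sequences(sequences)
  }
  if (length(sequences) == 0) {
    abort("empty input: no sequences to tally", class = "selexr_empty_error")
  }
  sequences <- normalize_seq(sequences, what = "read")
  if (drop_ambiguous) {
    sequences <- sequences[grepl("^[ACGT]*$", sequences)]
    if (length(sequences) == 0) {
      abort("empty input: all reads ambiguous", class = "selexr_empty_error")
    }
  }
  first_seen <- match(sequences, sequences)  # index of first occurrence
  df <- tibble(sequence = sequences, first = first_seen) %>%
    group_by(.data$sequence) %>%
    summarise(count = dplyr::n(), first = min(.data$first), .groups = "drop") %>%
    arrange(desc(.data$count), .data$first, .data$sequence) %>%
    mutate(
      percent = 100 * .data$count / sum(.data$count),
      rank = row_number()
    ) %>%
    select("sequence", "count", "percent", "rank")
  new_tallied_pool(df, length(sequences), generation_label)
}

#' @export
print.tallied_pool <- function(x, ...) {
  cat(sprintf("<tallied_pool> %s: %d unique sequences, %d reads\n",
              attr(x, "generation_label") %||% "pool",
              nrow(x), attr(x, "total_reads")))
  NextMethod()
}

#' Look up a sequence in a tallied pool
#'
#' Exact-match lookup after normalization. Absence is a result
#' (`found = FALSE`), not an error.
#'
#' @param pool A `tallied_pool`.
#' @param sequence Query sequence.
#' @return One-row tibble: `found`, `rank`, `percent`, `count`.
#' @export
#' @examples
#' lookup_rank(tally_pool(c("AC", "AC", "GT")), "GT")
lookup_rank <- function(pool, sequence) {
  sequence <- normalize_seq(sequence, what = "query")
  i <- match(sequence, pool$sequence)
  if (is.na(i)) {
    tibble(found = FALSE, rank = NA_integer_, percent = NA_real_,
           count = NA_integer_)
  } else {
    tibble(found = TRUE, rank = pool$rank[i], percent = pool$percent[i],
           count = pool$count[i])
  }
}
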