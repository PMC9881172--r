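# Paired-end read merging by overlap. The contract: scan all overlap lengths
# >= min_overlap between R1 and the reverse complement of R2 (given in
# sequencer orientation), pick the overlap with the fewest mismatches (ties
# broken toward the longest), succeed iff the mismatch fraction is within
# max_mismatch_rate, and resolve mismatched overlap positions toward the base
# with the higher Phred score (ties toward R1).

phred_scores <- function(qual) {
  s <- utf8ToInt(qual) - 33L
  if (any(s < 0 | s > 93)) {
    abort("Phred scores must be in [0, 93]", class = "selexr_format_error")
  }
  s
}

# core single-pair merge on pre-split character/score vectors
merge_one <- function(a, qa, b, qb, min_overlap, max_mismatch_rate) {
  n1 <- length(a)
  n2 <- length(b)
  best_len <- 0L
  best_mm <- Inf
  upper <- min(n1, n2)
  if (upper >= min_overlap) {
    for (L in seq(upper, min_overlap)) {
      mm <- sum(a[(n1 - L + 1):n1] != b[1:L])
      if (mm < best_mm) {
        best_mm <- mm
        best_len <- L
        if (mm == 0L) break
      }
    }
  }
  if (best_len == 0L || best_mm / best_len > max_mismatch_rate) {
    return(list(merged = NA_character_, overlap = 0L, mismatches = NA_integer_))
  }
  L <- best_len
  ov_a <- (n1 - L + 1):n1
  ov <- a[ov_a]
  if (best_mm > 0L) {
    bad <- which(ov != b[1:L])
    take_b <- qb[bad] > qa[ov_a[bad]]
    ov[bad[take_b]] <- b[bad[take_b]]
  }
  merged <- paste(c(a[seq_len(n1 - L)], ov, b[seq(L + 1, length.out = n2 - L)]),
                  collapse = "")
  list(merged = merged, overlap = L, mismatches = as.integer(best_mm))
}

#' Merge one paired-end read by overlap
#'
#' `r2_seq` is expected in sequencer orientation and is reverse-complemented
#' internally before the overlap search. On success the merged length equals
#' `nchar(r1) + nchar(r2) - overlap_len`. Failure to find a qualifying
#' overlap is reported with `merged = FALSE`, not an error.
#'
#' @param r1_seq,r2_seq Mate sequences.
#' @param r1_qual,r2_qual Phred+33 quality strings (default: uniform Q40).
#' @param min_overlap Minimum overlap length considered (>= 1).
#' @param max_mismatch_rate Maximum tolerated mismatches/overlap fraction.
#' @return One-row tibble: `merged` (logical), `merged_seq`, `overlap_len`,
#'   `mismatches_in_overlap`.
#' @export
#' @examples
#' merge_pair("ACGTACGT", revcomp("TACGTGGG"), min_overlap = 4)
merge_pair <- function(r1_seq, r2_seq, r1_qual = NULL, r2_qual = NULL,
                       min_overlap = 10, max_mismatch_rate = 0.1) {
  if (min_overlap < 1) {
    abort("min_overlap must be >= 1", class = "selexr_argument_error")
  }
  r1_seq <- normalize_seq(r1_seq, what = "r1")
  r2_seq <- normalize_seq(r2_seq, what = "r2")
  r1_qual <- r1_qual %||% strrep("I", nchar(r1_seq))
  r2_qual <- r2_qual %||% strrep("I", nchar(r2_seq))
  if (nchar(r1_qual) != nchar(r1_seq) || nchar(r2_qual) != nchar(r2_seq)) {
    abort("sequence and quality lengths differ", class = "selexr_format_error")
  }
  a <- seq_chars1(r1_seq)
  qa <- phred_scores(r1_qual)
  b <- seq_chars1(revcomp(r2_seq))
  qb <- rev(phred_scores(r2_qual))
  res <- merge_one(a, qa, b, qb, as.integer(min_overlap), max_mismatch_rate)
  tibble(
    merged = !is.na(res$merged),
    merged_seq = res$merged,
    overlap_len = res$overlap,
    mismatches_in_overlap = res$mismatches
  )
}

#' Merge a table of paired-end reads
#'
#' Vectorized front end to [merge_pair()]: identical (sequence, quality)
#' pairs are merged once and the result broadcast, which makes merging deeply
#' sequenced pools of short templates fast. Unmergeable pairs are flagged, and
#' a summary message reports how many were dropped.
#'
#' @param pairs Tibble with columns `r1_seq`, `r2_seq` and optionally
#'   `r1_qual`, `r2_qual`, `id`.
#' @inheritParams merge_pair
#' @param quiet Suppress the dropped-pair message.
#' @return `pairs` with columns `merged`, `merged_seq`, `overlap_len`,
#'   `mismatches_in_overlap` appended.
#' @export
merge_pairs <- function(pairs, min_overlap = 10, max_mismatch_rate = 0.1,
                        quiet = FALSE) {
  stopifnot(all(c("r1_seq", "r2_seq") %in% names(pairs)))
  n <- nrow(pairs)
  if (n == 0) {
    return(dplyr::mutate(pairs, merged = logical(0),
                         merged_seq = character(0),
                         overlap_len = integer(0),
                         mismatches_in_overlap = integer(0)))
  }
  q1 <- if ("r1_qual" %in% names(pairs)) pairs$r1_qual else
    strrep("I", nchar(pairs$r1_seq))
  q2 <- if ("r2_qual" %in% names(pairs)) pairs$r2_qual else
    strrep("I", nchar(pairs$r2_seq))
  key <- paste(pairs$r1_seq, q1, pairs$r2_seq, q2, sep = "\r")
  uniq <- which(!duplicated(key))
  res <- vector("list", length(uniq))
  for (k in seq_along(uniq)) {
    i <- uniq[k]
    res[[k]] <- merge_pair(pairs$r1_seq[i], pairs$r2_seq[i], q1[i], q2[i],
                           min_overlap = min_overlap,
                           max_mismatch_rate = max_mismatch_rate)
  }
  res <- dplyr::bind_rows(res)
  idx <- match(key, key[uniq])
  out <- dplyr::bind_cols(pairs, res[idx, ])
  n_fail <- sum(!out$merged)
  if (!quiet && n_fail > 0) {
    inform(sprintf("merge_pairs: dropped %d of %d pairs with no qualifying overlap",
                   n_fail, n))
  }
  out
}
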