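# Greedy rank-seeded similarity clustering with constant-region masking, plus
# lightweight per-column consensus/covariation statistics for cluster members.

# Remove constant-region strings (first exact occurrence of each, in order)
# from each sequence. Sequences in which a constant string is not found
# exactly are returned full-length with full_length = TRUE.
strip_constants <- function(x, constant_seqs) {
  if (length(constant_seqs) == 0) {
    return(list(var = x, full_length = rep(FALSE, length(x))))
  }
  var <- x
  flagged <- rep(FALSE, length(x))
  for (cs in constant_seqs) {
    pos <- stringi::stri_locate_first_fixed(var, cs)
    miss <- is.na(pos[, 1])
    flagged <- flagged | miss
    hit <- which(!miss)
    if (length(hit)) {
      var[hit] <- stringi::stri_sub_replace(var[hit], pos[hit, 1], pos[hit, 2],
                                            replacement = "")
    }
  }
  var[flagged] <- x[flagged]
  list(var = var, full_length = flagged)
}

#' Variable regions after constant-region masking
#'
#' Removes each constant-region string (first exact occurrence) from every
#' sequence. Sequences in which some constant string is not found exactly are
#' left full-length and flagged with a warning — comparison then falls back to
#' the full-length sequence.
#'
#' @param x Character vector of sequences.
#' @param constant_seqs Character vector of constant-region strings (e.g.
#'   [constant_strings()] of a scaffold).
#' @param quiet Suppress the fallback warning.
#' @return Character vector of variable regions.
#' @export
mask_constant_regions <- function(x, constant_seqs, quiet = FALSE) {
  x <- normalize_seq(x)
  constant_seqs <- normalize_seq(constant_seqs)
  res <- strip_constants(x, constant_seqs)
  if (!quiet && any(res$full_length)) {
    warn(sprintf(
      "%d sequence(s) lack an exact constant-region match; compared full-length",
      sum(res$full_length)
    ))
  }
  res$var
}

#' Masked pairwise similarity
#'
#' Similarity between two sequences after removing constant-region strings:
#' `1 - d / max(len_a, len_b)` where `d` is the Levenshtein edit distance
#' between the variable regions. A sequence whose constant regions cannot be
#' located exactly is compared full-length (with a warning).
#'
#' @param a,b Sequences to compare.
#' @param constant_seqs Constant-region strings to mask (may be empty).
#' @param quiet Suppress the fallback warning.
#' @return Similarity fraction in `[0, 1]`.
#' @export
#' @examples
#' masked_similarity("ACGT", "ACGA")                      # 0.75
#' masked_similarity("PPACGTSS", "PPACGASS", c("PP", "SS"))
masked_similarity <- function(a, b, constant_seqs = character(),
                              quiet = FALSE) {
  va <- mask_constant_regions(a, constant_seqs, quiet = quiet)
  vb <- mask_constant_regions(b, constant_seqs, quiet = quiet)
  similarity_to(va, vb)
}

# similarity of one variable region against a vector of variable regions
similarity_to <- function(ref_var, vars) {
  d <- as.integer(adist(ref_var, vars))
  denom <- pmax(nchar(ref_var), nchar(vars))
  s <- ifelse(denom == 0, 1, 1 - d / denom)
  as.numeric(s)
}

#' Greedy rank-seeded clustering of a tallied pool
#'
#' Reproduces the rank-seeded greedy clustering used to define sequence
#' classes in SELEX pools: query ranks are processed in order; each query not
#' already absorbed by an earlier cluster becomes a seed, and the pool is
#' scanned in rank order, admitting sequences whose masked similarity to the
#' seed is at least `threshold`, until `max_members` are admitted or the pool
#' is exhausted. Membership is exclusive — a sequence admitted to an earlier
#' cluster is never admitted again — so cluster percents are additive. A query
#' already clustered is reported as skipped, with the cluster that owns it.
#'
#' @param pool A `tallied_pool`.
#' @param query_ranks 1-based ranks to use as seeds, in processing order.
#' @param threshold Similarity threshold (default 0.90).
#' @param max_members Maximum sequences admitted per cluster (default 1000).
#' @param constant_seqs Constant-region strings excluded from comparison.
#' @return A `selex_clusters` object: list with `members` (tibble:
#'   `cluster`, `seed_rank`, `rank`, `sequence`, `count`, `percent`,
#'   `similarity`), `skipped` (tibble: `query_rank`, `owner_cluster`), and
#'   `summary` (tibble: `cluster`, `seed_rank`, `n_members`,
#'   `cluster_percent`).
#' @export
cluster_pool <- function(pool, query_ranks, threshold = 0.90,
                         max_members = 1000, constant_seqs = character()) {
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]", class = "selexr_argument_error")
  }
  if (max_members < 1) {
    abort("max_members must be >= 1", class = "selexr_argument_error")
  }
  query_ranks <- as.integer(query_ranks)
  if (any(!query_ranks %in% pool$rank)) {
    abort(sprintf("query rank %d not present in pool",
                  query_ranks[which(!query_ranks %in% pool$rank)[1]]),
          class = "selexr_argument_error")
  }
  ord <- order(pool$rank)
  pool <- pool[ord, ]
  vars <- suppressWarnings(
    mask_constant_regions(pool$sequence, constant_seqs, quiet = FALSE)
  )
  assigned <- rep(NA_integer_, nrow(pool))  # cluster id owning each row
  members <- list()
  skipped <- list()
  cluster_id <- 0L
  for (qr in query_ranks) {
    qi <- match(qr, pool$rank)
    if (!is.na(assigned[qi])) {
      skipped[[length(skipped) + 1]] <- tibble(
        query_rank = qr, owner_cluster = assigned[qi]
      )
      next
    }
    cluster_id <- cluster_id + 1L
    sims <- similarity_to(vars[qi], vars)
    cand <- which(is.na(assigned) & sims >= threshold)
    cand <- cand[order(pool$rank[cand])]
    cand <- head(cand, max_members)
    assigned[cand] <- cluster_id
    members[[cluster_id]] <- tibble(
      cluster = cluster_id,
      seed_rank = qr,
      rank = pool$rank[cand],
      sequence = pool$sequence[cand],
      count = pool$count[cand],
      percent = pool$percent[cand],
      similarity = sims[cand]
    )
  }
  members <- if (length(members)) bind_rows(members) else
    tibble(cluster = integer(), seed_rank = integer(), rank = integer(),
           sequence = character(), count = integer(), percent = double(),
           similarity = double())
  skipped <- if (length(skipped)) bind_rows(skipped) else
    tibble(query_rank = integer(), owner_cluster = integer())
  summary <- members %>%
    group_by(.data$cluster, .data$seed_rank) %>%
    summarise(n_members = dplyr::n(),
              cluster_percent = sum(.data$percent), .groups = "drop")
  structure(
    list(members = members, skipped = skipped, summary = summary,
         threshold = threshold, constant_seqs = constant_seqs),
    class = "selex_clusters"
  )
}

#' @export
print.selex_clusters <- function(x, ...) {
  cat(sprintf("<selex_clusters> %d cluster(s) at threshold %.2f\n",
              nrow(x$summary), x$threshold))
  print(x$summary)
  if (nrow(x$skipped)) {
    cat("skipped queries (already clustered):\n")
    print(x$skipped)
  }
  invisible(x)
}

#' Write each cluster to a FASTA file
#'
#' One record per member, headers `rank|count|percent|similarity`.
#'
#' @param clusters A `selex_clusters` object.
#' @param dir Output directory.
#' @param prefix File name prefix (`<prefix><cluster>.fa`).
#' @return Character vector of written paths, invisibly.
#' @export
write_cluster_fasta <- function(clusters, dir, prefix = "cluster") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cid in unique(clusters$members$cluster)) {
    m <- clusters$members[clusters$members$cluster == cid, ]
    path <- file.path(dir, sprintf("%s%d.fa", prefix, cid))
    write_fasta(tibble(
      id = sprintf("%d|%d|%.6f|%.4f", m$rank, m$count, m$percent, m$similarity),
      seq = m$sequence
    ), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Consensus column statistics for cluster members
#'
#' Computes per-column base frequencies over the (masked) variable regions of
#' cluster members, and, for annotated column pairs, the number of distinct
#' complementary (Watson-Crick or G:U wobble) pair identities observed — the
#' covariation count (`distinct complementary identities - 1`, floored at 0).
#' Members whose variable regions differ in length from the majority are
#' excluded with a message.
#'
#' @param sequences Character vector of member sequences (e.g. a cluster's
#'   `members$sequence`).
#' @param pair_annotation Optional list of `c(i, j)` 0-based column index
#'   pairs annotated as base-paired.
#' @param constant_seqs Constant-region strings to mask before computing
#'   columns.
#' @return A `consensus_profile` list: `frequencies` (tibble `position`
#'   (0-based), `base`, `freq`), `covariation` (tibble `pos_i`, `pos_j`,
#'   `n_pair_types`, `covariation`), `n_used`, `n_excluded`.
#' @export
consensus_profile <- function(sequences, pair_annotation = list(),
                              constant_seqs = character()) {
  if (length(sequences) == 0) {
    abort("empty cluster: no sequences", class = "selexr_empty_error")
  }
  vars <- suppressWarnings(mask_constant_regions(sequences, constant_seqs))
  lens <- nchar(vars)
  modal <- as.integer(names(which.max(table(lens))))
  keep <- lens == modal
  if (any(!keep)) {
    inform(sprintf("consensus_profile: excluded %d member(s) with variable region length != %d",
                   sum(!keep), modal))
  }
  vars <- vars[keep]
  mat <- do.call(rbind, seq_chars(vars))
  freqs <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    tibble(position = j - 1L, base = names(tab),
           freq = as.numeric(tab) / sum(tab))
  })
  comp_pairs <- c("AT", "TA", "GC", "CG", "GT", "TG")
  cov <- purrr::map_dfr(pair_annotation, function(p) {
    i <- p[1] + 1L
    j <- p[2] + 1L
    if (i < 1 || j < 1 || i > ncol(mat) || j > ncol(mat)) {
      abort("pair annotation outside variable region",
            class = "selexr_argument_error")
    }
    ids <- paste0(mat[, i], mat[, j])
    comp <- unique(ids[ids %in% comp_pairs])
    tibble(pos_i = p[1], pos_j = p[2],
           n_pair_types = length(comp),
           covariation = max(0L, length(comp) - 1L))
  })
  if (length(pair_annotation) == 0) {
    cov <- tibble(pos_i = integer(), pos_j = integer(),
                  n_pair_types = integer(), covariation = integer())
  }
  structure(
    list(frequencies = freqs, covariation = cov,
         n_used = sum(keep), n_excluded = sum(!keep)),
    class = "consensus_profile"
  )
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("<consensus_profile> %d members over %d columns (%d excluded)\n",
              x$n_used, max(x$frequencies$position) + 1L, x$n_excluded))
  if (nrow(x$covariation)) print(x$covariation)
  invisible(x)
}
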