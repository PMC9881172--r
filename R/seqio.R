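# Sequence file I/O: FASTQ (4-line, Phred+33), FASTA, plain sequence lists,
# and the tally TSV dialect. Readers are gzip-transparent.

open_text <- function(path) {
  con <- gzfile(path, "rt")
  con
}

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records (Phred+33) into a tibble. Gzip-transparent.
#' Truncated records or quality strings whose length differs from the
#' sequence raise a format error carrying the record index.
#'
#' @param path FASTQ file path (optionally gzipped).
#' @return Tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0) {
    return(tibble(id = character(), seq = character(), qual = character()))
  }
  if (length(lines) %% 4 != 0) {
    abort(sprintf("truncated FASTQ record %d in %s",
                  length(lines) %/% 4 + 1, path),
          class = "selexr_format_error")
  }
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  if (any(!startsWith(ids, "@"))) {
    abort(sprintf("malformed FASTQ header at record %d",
                  which(!startsWith(ids, "@"))[1]),
          class = "selexr_format_error")
  }
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    abort(sprintf(
      "FASTQ record %d: quality length (%d) != sequence length (%d)",
      which(bad)[1], nchar(quals[which(bad)[1]]), nchar(seqs[which(bad)[1]])
    ), class = "selexr_format_error")
  }
  tibble(id = sub("^@", "", ids), seq = seqs, qual = quals)
}

#' Write a FASTQ file
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param path Output path (".gz" suffix writes gzipped).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort("sequence and quality lengths differ", class = "selexr_format_error")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Read a FASTA file
#'
#' Accepts wrapped or single-line FASTA (via Biostrings). Gzip-transparent.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  tibble(id = names(set), seq = unname(toupper(as.character(set))))
}

#' Write a FASTA file (single-line records)
#'
#' @param records Tibble with columns `id`, `seq` (or a named character
#'   vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- tibble(
      id = if (is.null(names(records))) paste0("seq", seq_along(records)) else
        names(records),
      seq = unname(records)
    )
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0(">", records$id, "\n", records$seq), con)
  invisible(path)
}

#' Read sequences from FASTA, FASTQ, or plain one-per-line text
#'
#' Format is sniffed from the first non-empty character (`>` FASTA, `@`
#' FASTQ, otherwise plain).
#'
#' @param path Input path.
#' @return Character vector of sequences.
#' @export
read_sequences <- function(path) {
  con <- open_text(path)
  first <- readLines(con, n = 1, warn = FALSE)
  close(con)
  if (length(first) == 0) return(character())
  if (startsWith(first, ">")) {
    read_fasta(path)$seq
  } else if (startsWith(first, "@")) {
    read_fastq(path)$seq
  } else {
    con <- open_text(path)
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    lines[nzchar(lines)]
  }
}

#' Write a tallied pool as TSV
#'
#' Columns: `sequence`, `count`, `percent` (6 decimal places), `rank`, with a
#' header line.
#'
#' @param pool A tallied pool (see [tally_pool()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tally <- function(pool, path) {
  out <- data.frame(
    sequence = pool$sequence,
    count = pool$count,
    percent = sprintf("%.6f", pool$percent),
    rank = pool$rank
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tally TSV
#'
#' @param path Tally TSV path.
#' @param generation_label Optional generation label to attach.
#' @return A `tallied_pool` tibble (columns `sequence`, `count`, `percent`,
#'   `rank`).
#' @export
read_tally <- function(path, generation_label = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "numeric",
                                         "integer"))
  new_tallied_pool(as_tibble(df), sum(df$count),
                   generation_label %||% basename(path))
}
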