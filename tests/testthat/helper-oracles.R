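# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (utils::adist, the diagonal run scanner, the
# IUPAC table) so that agreement is informative.

BASES <- c("A", "C", "G", "T")

random_seq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

random_seqs <- function(n, len) vapply(seq_len(n), function(i) random_seq(len), "")

# textbook dynamic-programming Levenshtein distance
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(
        prev[j + 1] + 1,
        cur[j] + 1,
        prev[j] + (ca[i] != cb[j])
      )
    }
    prev <- cur
  }
  prev[m + 1]
}

# brute-force enumeration of every concrete sequence a template admits,
# using an independently written degeneracy table
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

enumerate_template <- function(template) {
  opts <- ORACLE_IUPAC[strsplit(template, "")[[1]]]
  grid <- do.call(expand.grid, c(opts, stringsAsFactors = FALSE))
  apply(grid, 1, paste, collapse = "")
}

# simple complement for the oracle (ACGT only)
rc_oracle <- function(x) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

# all-substrings oracle for maximal reverse-complement matches: every
# (read_start, oligo_start, length) triple, 0-based half-open on read and
# oligo, where seq[i, i+L) equals revcomp(oligo)[j, j+L) maximally
scan_oracle <- function(sequence, oligo, min_len) {
  rco <- rc_oracle(oligo)
  a <- strsplit(sequence, "")[[1]]
  b <- strsplit(rco, "")[[1]]
  n <- length(a)
  m <- length(b)
  subs <- list()
  for (L in min_len:n) {
    if (L > m) break
    starts <- seq_len(n - L + 1)
    pats <- substring(sequence, starts, starts + L - 1)
    loc <- stringi::stri_locate_all_fixed(rco, pats, overlap = TRUE)
    for (k in seq_along(starts)) {
      hits <- loc[[k]]
      if (is.na(hits[1, 1])) next
      for (h in seq_len(nrow(hits))) {
        i <- starts[k]
        j <- unname(hits[h, 1])
        # maximal: cannot extend left or right
        left_ok <- i == 1 || j == 1 || a[i - 1] != b[j - 1]
        right_ok <- i + L - 1 == n || j + L - 1 == m ||
          a[i + L] != b[j + L]
        if (left_ok && right_ok) {
          # rc-oligo span [j, j+L) maps to oligo span [m-j-L+1, m-j+1) 1-based
          subs[[length(subs) + 1]] <- c(
            read_start = i - 1, read_end = i - 1 + L,
            oligo_start = m - (j - 1) - L, oligo_end = m - (j - 1),
            length = L
          )
        }
      }
    }
  }
  if (length(subs) == 0) {
    return(data.frame(read_start = integer(), read_end = integer(),
                      oligo_start = integer(), oligo_end = integer(),
                      length = integer()))
  }
  df <- unique(as.data.frame(do.call(rbind, subs)))
  df[order(df$read_start, df$oligo_start), , drop = FALSE]
}

# plant a cloud of classes into a tallied pool for clustering tests: three
# divergent seeds with mutational clouds plus unrelated background
make_planted_pool <- function(scaffold, n_members = 60, cloud_degeneracy = 0.02,
                              n_background = 100, seed = 1) {
  withr::with_seed(seed, {
    seeds <- sample_pool(scaffold, 3)
    reads <- character()
    truth <- character()
    for (k in 1:3) {
      cloud <- unique(c(seeds[k],
                        mutagenize(seeds[k], cloud_degeneracy,
                                   scaffold$constant_spans, n = n_members)))
      copies <- c(n_members * 10, rev(seq_along(cloud))[-1])
      reads <- c(reads, rep(cloud, copies))
      truth <- c(truth, rep(paste0("class", k), sum(copies)))
    }
    bg <- sample_pool(scaffold, n_background)
    reads <- c(reads, bg)
    truth <- c(truth, rep("background", n_background))
    list(reads = reads, truth = truth, seeds = seeds)
  })
}
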