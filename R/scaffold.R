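#' Define a selection-pool scaffold
#'
#' A scaffold is the generative definition of a combinatorial pool: an IUPAC
#' nucleotide template in which degenerate codes (N, R, Y, ...) mark the
#' randomized positions, together with annotated constant spans (primer-binding
#' regions, fixed in every molecule) and the span that hybridizes to the
#' capture oligonucleotide. All coordinates are 0-based, half-open.
#'
#' @param name Scaffold label.
#' @param template IUPAC nucleotide string (DNA alphabet; U mapped to T).
#' @param constant_spans List of 0-based half-open `c(start, end)` intervals
#'   that are fixed in every molecule. Must be pairwise disjoint, and every
#'   position inside them must hold a non-degenerate code.
#' @param capture_site_span Single 0-based half-open interval complementary to
#'   the capture oligonucleotide, or `NULL`.
#' @return A `selex_scaffold` object.
#' @export
#' @examples
#' sc <- scaffold("toy", "GGACNNNNGTCC",
#'   constant_spans = list(c(0, 4), c(8, 12))
#' )
#' pool_diversity(sc)
scaffold <- function(name, template, constant_spans = list(),
                     capture_site_span = NULL) {
  template <- normalize_seq(template, what = "template")
  len <- nchar(template)
  if (len == 0) abort("template must be non-empty", class = "selexr_argument_error")
  chars <- seq_chars1(template)
  for (i in seq_along(constant_spans)) {
    check_span(constant_spans[[i]], len, sprintf("constant_spans[[%d]]", i))
  }
  if (length(constant_spans) > 1) {
    for (i in seq_len(length(constant_spans) - 1)) {
      for (j in seq(i + 1, length(constant_spans))) {
        if (spans_overlap(constant_spans[[i]], constant_spans[[j]])) {
          abort("constant_spans must be pairwise disjoint",
                class = "selexr_argument_error")
        }
      }
    }
  }
  for (sp in constant_spans) {
    idx <- seq(sp[1] + 1, sp[2])
    if (any(!chars[idx] %in% c("A", "C", "G", "T"))) {
      abort("constant spans must hold only non-degenerate codes",
            class = "selexr_argument_error")
    }
  }
  if (!is.null(capture_site_span)) {
    check_span(capture_site_span, len, "capture_site_span")
  }
  structure(
    list(
      name = as.character(name),
      template = template,
      constant_spans = lapply(constant_spans, as.integer),
      capture_site_span = if (is.null(capture_site_span)) NULL else
        as.integer(capture_site_span)
    ),
    class = "selex_scaffold"
  )
}

#' @export
print.selex_scaffold <- function(x, ...) {
  cat(sprintf(
    "<selex_scaffold> %s (%d nt, %d randomized positions)\n",
    x$name, nchar(x$template), sum(randomized_positions(x))
  ))
  cat("  template:", x$template, "\n")
  if (length(x$constant_spans)) {
    cat("  constant spans:",
        paste(vapply(x$constant_spans,
                     function(s) sprintf("[%d,%d)", s[1], s[2]), ""),
              collapse = " "), "\n")
  }
  if (!is.null(x$capture_site_span)) {
    cat(sprintf("  capture site: [%d,%d)\n",
                x$capture_site_span[1], x$capture_site_span[2]))
  }
  invisible(x)
}

# logical vector over template positions: TRUE where the code is degenerate
randomized_positions <- function(scaffold) {
  chars <- seq_chars1(scaffold$template)
  lengths(IUPAC_CODES[chars]) > 1
}

#' Constant-region strings of a scaffold
#'
#' Extracts the literal sequences of the annotated constant spans, in span
#' order. These are the strings masked out during similarity comparison.
#'
#' @param scaffold A `selex_scaffold`.
#' @return Character vector of constant-region sequences.
#' @export
constant_strings <- function(scaffold) {
  vapply(scaffold$constant_spans, function(sp) span_sub(scaffold$template, sp), "")
}

#' Exact diversity of a scaffold pool
#'
#' The number of distinct sequences a scaffold can realize: the product over
#' template positions of the number of bases each IUPAC code admits (N = 4,
#' R/Y/S/W/K/M = 2, B/D/H/V = 3, fixed = 1). A scaffold with 23 fully
#' randomized (N) positions admits 4^23 = 70,368,744,177,664 distinct
#' sequences, i.e. about 7e13.
#'
#' @param scaffold A `selex_scaffold`.
#' @return Exact count as a double (exact while below 2^53).
#' @export
#' @examples
#' pool_diversity(scaffold("x", "ANRN"))  # 1 * 4 * 2 * 4 = 32
pool_diversity <- function(scaffold) {
  stopifnot(inherits(scaffold, "selex_scaffold"))
  chars <- seq_chars1(scaffold$template)
  prod(lengths(IUPAC_CODES[chars]))
}

#' Sample concrete pool members from a scaffold
#'
#' Each degenerate template position is drawn uniformly and independently from
#' the bases its IUPAC code admits; fixed positions are copied verbatim.
#'
#' @param scaffold A `selex_scaffold`.
#' @param n Number of sequences to draw (>= 1).
#' @param seed Optional integer seed; the same seed reproduces the same draw.
#' @return Character vector of `n` sequences.
#' @export
#' @examples
#' sample_pool(scaffold("x", "ACNNGT"), 3, seed = 1)
sample_pool <- function(scaffold, n, seed = NULL) {
  stopifnot(inherits(scaffold, "selex_scaffold"))
  if (length(n) != 1 || is.na(n) || n < 1) {
    abort("n must be >= 1", class = "selexr_argument_error")
  }
  n <- as.integer(n)
  chars <- seq_chars1(scaffold$template)
  deg <- which(lengths(IUPAC_CODES[chars]) > 1)
  mat <- matrix(chars, nrow = n, ncol = length(chars), byrow = TRUE)
  with_seed_if(seed, {
    for (j in deg) {
      mat[, j] <- sample(IUPAC_CODES[[chars[j]]], n, replace = TRUE)
    }
  })
  apply(mat, 1, paste, collapse = "")
}

#' Mutagenize a parent sequence at a given degeneracy
#'
#' Models doped resynthesis of a selected sequence: at every unprotected
#' position, with probability `degeneracy` the parent base is replaced by one
#' of the three alternative bases (chosen uniformly); with probability
#' `1 - degeneracy` the parent base is retained. Protected spans (typically
#' the primer-binding regions) never change. A reselection pool mutagenized at
#' 6% degeneracy uses `degeneracy = 0.06`.
#'
#' @param parent Parent sequence (non-degenerate DNA/RNA).
#' @param degeneracy Per-position substitution probability in `[0, 1)`.
#' @param protected_spans List of 0-based half-open intervals never mutated.
#' @param n Number of variants to generate.
#' @param seed Optional integer seed.
#' @return Character vector of `n` variant sequences.
#' @export
#' @examples
#' mutagenize("ACGTACGT", 0.25, list(c(0, 2)), n = 5, seed = 1)
mutagenize <- function(parent, degeneracy, protected_spans = list(), n = 1,
                       seed = NULL) {
  parent <- normalize_seq(parent, what = "parent")
  if (length(degeneracy) != 1 || is.na(degeneracy) ||
      degeneracy < 0 || degeneracy >= 1) {
    abort("degeneracy must be in [0, 1)", class = "selexr_argument_error")
  }
  if (n < 1) abort("n must be >= 1", class = "selexr_argument_error")
  len <- nchar(parent)
  for (i in seq_along(protected_spans)) {
    check_span(protected_spans[[i]], len, sprintf("protected_spans[[%d]]", i))
  }
  chars <- seq_chars1(parent)
  protected <- rep(FALSE, len)
  for (sp in protected_spans) protected[seq(sp[1] + 1, sp[2])] <- TRUE
  open <- which(!protected)
  n <- as.integer(n)
  mat <- matrix(chars, nrow = n, ncol = len, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  with_seed_if(seed, {
    if (length(open) > 0 && degeneracy > 0) {
      hit <- matrix(runif(n * length(open)) < degeneracy,
                    nrow = n, ncol = length(open))
      for (k in seq_along(open)) {
        j <- open[k]
        rows <- which(hit[, k])
        if (length(rows)) {
          alt <- setdiff(bases, chars[j])
          mat[rows, j] <- sample(alt, length(rows), replace = TRUE)
        }
      }
    }
  })
  apply(mat, 1, paste, collapse = "")
}

#' Specify an aptamer-onto-expression-platform graft
#'
#' Describes the string assembly that places a selected aptamer core back into
#' a riboswitch context: an enclosing P1 stem (`p1_left`/`p1_right`, which must
#' be reverse-complementary over their length) around the aptamer core,
#' followed by the natural expression platform.
#'
#' @param aptamer_core Aptamer core sequence.
#' @param p1_left,p1_right The two strands of the enclosing stem.
#' @param expression_platform Sequence appended downstream (may be empty).
#' @return A `graft_design` list.
#' @export
graft_design <- function(aptamer_core, p1_left, p1_right,
                         expression_platform = "") {
  structure(
    list(
      aptamer_core = normalize_seq(aptamer_core, what = "aptamer_core"),
      p1_left = normalize_seq(p1_left, what = "p1_left"),
      p1_right = normalize_seq(p1_right, what = "p1_right"),
      expression_platform = normalize_seq(expression_platform,
                                          what = "expression_platform")
    ),
    class = "graft_design"
  )
}

#' Assemble a grafted riboswitch sequence
#'
#' Concatenates `p1_left + aptamer_core + p1_right + expression_platform`
#' after verifying that the annotated P1 stem is Watson-Crick
#' reverse-complementary; a mismatch is a design error naming the offending
#' pair.
#'
#' @param design A [graft_design()].
#' @param rna Emit RNA lettering (U instead of T).
#' @return The assembled sequence.
#' @export
#' @examples
#' graft(graft_design("AAA", "GG", "CC", "TT"))
graft <- function(design, rna = FALSE) {
  stopifnot(inherits(design, "graft_design"))
  l <- design$p1_left
  r <- design$p1_right
  if (nchar(l) != nchar(r)) {
    abort("p1_left and p1_right must have equal length",
          class = "selexr_design_error")
  }
  rc <- revcomp(l)
  if (nchar(l) > 0 && rc != r) {
    lc <- seq_chars1(l)
    rcch <- seq_chars1(rc)
    rch <- seq_chars1(r)
    bad <- which(rcch != rch)[1]
    # pair i of the stem couples p1_left position i with p1_right position
    # (len - i + 1); report in 1-based stem coordinates
    abort(sprintf(
      "P1 stem pair %d is not Watson-Crick: %s does not pair with %s",
      bad, lc[nchar(l) - bad + 1], rch[bad]
    ), class = "selexr_design_error")
  }
  out <- paste0(l, design$aptamer_core, r, design$expression_platform)
  if (rna) as_rna(out) else out
}

# ---------------------------------------------------------------------------
# Built-in synthetic scaffolds.
#
# The published S1/S2/S3 scaffold sequences live in supplementary material that
# is not redistributed here; these built-ins are synthetic stand-ins with the
# same architecture: a 5' constant primer region containing the capture site,
# 23 randomized nucleotides split 8+9+6 among the three joining regions
# between two fixed stems, and a 3' constant primer region.
# ---------------------------------------------------------------------------

SCAFFOLD_CONST5 <- "GGAAGTCGTACGACTCACGC"  # capture site at [4,16)
SCAFFOLD_CONST3 <- "GAGCTTCGATCGTGACTGAC"
SCAFFOLD_P2A <- "GCTGGA"
SCAFFOLD_L2  <- "GTTCGAA"
SCAFFOLD_P2B <- "TCCAGC"
SCAFFOLD_P3A <- "GGCAGT"
SCAFFOLD_L3  <- "TCCGTAA"
SCAFFOLD_P3B <- "ACTGCC"

build_joined_scaffold <- function(name, n1, n2, n3, randomize_mismatch = FALSE) {
  p2a <- SCAFFOLD_P2A
  p2b <- SCAFFOLD_P2B
  if (randomize_mismatch) {
    # open the engineered C-A mismatch pair: randomize the last position of
    # P2a and the first position of P2b so they can pair
    substr(p2a, nchar(p2a), nchar(p2a)) <- "N"
    substr(p2b, 1, 1) <- "N"
  }
  parts <- c(
    SCAFFOLD_CONST5,
    strrep("N", n1), p2a, SCAFFOLD_L2, p2b,
    strrep("N", n2), SCAFFOLD_P3A, SCAFFOLD_L3, SCAFFOLD_P3B,
    strrep("N", n3), SCAFFOLD_CONST3
  )
  template <- paste(parts, collapse = "")
  ends <- cumsum(nchar(parts))
  starts <- ends - nchar(parts)
  const_spans <- if (randomize_mismatch) {
    # P2a/P2b now contain one degenerate position each, so only the primer
    # regions are annotated constant
    list(c(starts[1], ends[1]), c(starts[11], ends[11]))
  } else {
    list(c(starts[1], ends[1]), c(starts[11], ends[11]))
  }
  scaffold(name, template,
           constant_spans = const_spans,
           capture_site_span = c(4L, 16L))
}

#' Built-in synthetic scaffolds
#'
#' Three scaffolds emulating a riboswitch-derived Capture-SELEX pool design:
#' `scaffold_s1()` carries 23 fully randomized positions distributed 8+9+6
#' among the three joining regions between two fixed stems; `scaffold_s2()`
#' additionally randomizes the engineered stem mismatch pair (25 randomized
#' positions); `scaffold_s3()` swaps the first (N8) and third (N6) randomized
#' regions. The sequences themselves are synthetic: the constant regions,
#' stems, and capture site are stand-ins with the published architecture, not
#' the published sequences.
#'
#' @return A `selex_scaffold`.
#' @export
#' @examples
#' pool_diversity(scaffold_s1())  # 4^23
scaffold_s1 <- function() build_joined_scaffold("S1", 8, 9, 6)

#' @rdname scaffold_s1
#' @export
scaffold_s2 <- function() build_joined_scaffold("S2", 8, 9, 6,
                                                randomize_mismatch = TRUE)

#' @rdname scaffold_s1
#' @export
scaffold_s3 <- function() build_joined_scaffold("S3", 6, 9, 8)

#' Synthetic capture oligonucleotide
#'
#' A 30-nt DNA oligo whose central 12 nt are reverse-complementary to the
#' capture site of the built-in scaffolds (positions 4-16 of the 5' constant
#' region). Synthetic stand-in: the published capture oligo sequence is not
#' redistributed.
#'
#' @return Character scalar.
#' @export
capture_oligo <- function() {
  paste0("ACTCA", revcomp(span_sub(SCAFFOLD_CONST5, c(4L, 16L))),
         "TTGCAACGATCGA")
}

#' Read or write a scaffold definition as YAML
#'
#' The document stores the template string plus named spans with 0-based
#' half-open coordinates.
#'
#' @param path File path.
#' @param scaffold A `selex_scaffold` (for writing).
#' @return `read_scaffold()` returns a `selex_scaffold`;
#'   `write_scaffold()` returns `path` invisibly.
#' @export
read_scaffold <- function(path) {
  doc <- yaml::read_yaml(path)
  scaffold(
    name = doc$name,
    template = doc$template,
    constant_spans = lapply(doc$constant_spans, unlist),
    capture_site_span = if (is.null(doc$capture_site_span)) NULL else
      unlist(doc$capture_site_span)
  )
}

#' @rdname read_scaffold
#' @export
write_scaffold <- function(scaffold, path) {
  stopifnot(inherits(scaffold, "selex_scaffold"))
  yaml::write_yaml(
    list(
      name = scaffold$name,
      template = scaffold$template,
      constant_spans = lapply(scaffold$constant_spans, as.integer),
      capture_site_span = if (is.null(scaffold$capture_site_span)) NULL else
        as.integer(scaffold$capture_site_span)
    ),
    path
  )
  invisible(path)
}
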