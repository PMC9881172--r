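# Nucleotide alphabet helpers. Everything downstream works on a single
# internal alphabet: uppercase DNA with IUPAC degeneracy codes; U is accepted
# on input and mapped to T.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CHARS <- names(IUPAC_CODES)

#' Normalize nucleotide sequences to the internal DNA alphabet
#'
#' Uppercases, maps U to T, and (optionally) validates that only IUPAC
#' nucleotide codes remain. All selexr functions call this on their sequence
#' inputs, so RNA and DNA, upper- and lowercase, can be mixed freely.
#'
#' @param x Character vector of sequences.
#' @param validate Check that every character is a valid IUPAC code.
#' @param what Label used in error messages (e.g. "read").
#' @return Character vector of normalized sequences.
#' @export
#' @examples
#' normalize_seq(c("acgu", "ACGT"))
normalize_seq <- function(x, validate = TRUE, what = "sequence") {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  if (validate) {
    bad <- !grepl(paste0("^[", paste(IUPAC_CHARS, collapse = ""), "]*$"), x)
    if (any(bad)) {
      abort(sprintf(
        "invalid IUPAC nucleotide code in %s %d: %s",
        what, which(bad)[1], x[which(bad)[1]]
      ), class = "selexr_alphabet_error")
    }
  }
  x
}

#' Reverse complement
#'
#' IUPAC-aware, vectorized reverse complement on the DNA alphabet (U is
#' normalized to T first).
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
#' revcomp(revcomp("GATTACA")) == "GATTACA"
revcomp <- function(x) {
  x <- normalize_seq(x)
  stringi::stri_reverse(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x))
}

#' Convert a DNA-alphabet sequence to RNA lettering
#'
#' @param x Character vector of sequences.
#' @return Sequences with T replaced by U.
#' @export
as_rna <- function(x) {
  chartr("Tt", "Uu", x)
}

# split sequences into character matrices / lists
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

seq_chars1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# run `code` under a temporary RNG state when seed is given
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# validate a 0-based half-open span against a sequence length
check_span <- function(span, len, what = "span") {
  if (length(span) != 2 || anyNA(span) || span[1] < 0 || span[2] > len ||
      span[1] >= span[2]) {
    abort(sprintf(
      "%s must be a 0-based half-open interval within [0, %d)", what, len
    ), class = "selexr_argument_error")
  }
  invisible(span)
}

spans_overlap <- function(a, b) a[1] < b[2] && b[1] < a[2]

# extract template substring by 0-based half-open span
span_sub <- function(x, span) substr(x, span[1] + 1, span[2])
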