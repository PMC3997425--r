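#' Nucleotide alphabet helpers
#'
#' Sequences move between two alphabets inside the pipeline: reads and
#' duplex logic use RNA (U), genome matching uses DNA (T). `as_rna()` and
#' `as_dna()` are total functions on upper-case nucleotide strings: they
#' only ever exchange T and U and leave every other character alone.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @examples
#' as_rna("ACGT")  # "ACGU"
#' as_dna("ACGU")  # "ACGT"
#' @name alphabet
NULL

#' @rdname alphabet
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname alphabet
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement
#'
#' Works on either alphabet and returns the same alphabet it was given
#' (a sequence containing U complements to one containing U).
#'
#' @param x character vector of nucleotide sequences (A/C/G/T/U/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  up <- toupper(x)
  comp <- chartr("ACGTUN", "TGCAAN", up)
  # preserve RNA alphabet where the input used it
  is_rna <- grepl("U", up, fixed = TRUE) & !grepl("T", up, fixed = TRUE)
  comp[is_rna] <- chartr("T", "U", comp[is_rna])
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' GC content of a sequence
#'
#' @param x character vector of nucleotide sequences.
#' @return numeric vector, percentage of G+C bases (0-100).
#' @export
gc_content <- function(x) {
  up <- toupper(x)
  n <- nchar(up)
  gc <- nchar(gsub("[^GC]", "", up))
  100 * gc / n
}

# Watson-Crick (+ G:U wobble, optionally) pairing test on RNA letters.
# `a` and `b` are single upper-case RNA characters, vectorized.
pairs_with <- function(a, b, wobble = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (!wobble) return(wc)
  wc | (a == "G" & b == "U") | (a == "U" & b == "G")
}

# split a string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
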