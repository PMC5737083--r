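#' Reverse complement of DNA sequences
#'
#' Base-wise complement (A<->T, C<->G, N<->N) with the order reversed.
#' Applying the function twice returns the input (involution).
#'
#' @param x Character vector of DNA sequences over the alphabet A, C, G, T, N
#'   (case-insensitive; output is uppercase).
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' revcomp("CCTTGGCT")  # "AGCCAAGG"
#' @export
revcomp <- function(x) {
  x <- normalize_sequence(x)
  if (length(x) == 0L) return(character(0))
  out <- character(length(x))
  empty <- !nzchar(x)
  out[empty] <- ""
  if (any(!empty)) {
    out[!empty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[!empty]))
    )
  }
  out
}

#' Normalize and validate a DNA sequence
#'
#' Folds to uppercase and rejects any character outside A, C, G, T, N,
#' reporting the sequence element and position of the first offender.
#'
#' @param x Character vector.
#' @return Uppercase character vector.
#' @export
normalize_sequence <- function(x) {
  if (!is.character(x)) stop("sequence must be a character vector")
  x <- toupper(x)
  bad <- regexpr("[^ACGTN]", x)
  hit <- which(bad > 0L)
  if (length(hit) > 0L) {
    stop(sprintf(
      "invalid character '%s' at position %d of sequence %d",
      substr(x[hit[1L]], bad[hit[1L]], bad[hit[1L]]), bad[hit[1L]], hit[1L]
    ))
  }
  x
}

# Complement lookup used by the scanner; N complements to NA so that a
# candidate arm pair touching an N can never match.
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = NA_character_)

#' GC content of DNA sequences
#'
#' Fraction (G + C) / (A + C + G + T). N bases are excluded from the
#' denominator; a sequence with no non-N base returns NA.
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector in [0, 1] (NA where undefined).
#' @export
gc_content <- function(x) {
  x <- normalize_sequence(x)
  if (length(x) == 0L) return(numeric(0))
  counts <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(x), baseOnly = TRUE
  )
  acgt <- counts[, "A"] + counts[, "C"] + counts[, "G"] + counts[, "T"]
  gc <- counts[, "C"] + counts[, "G"]
  unname(ifelse(acgt > 0, gc / acgt, NA_real_))
}
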