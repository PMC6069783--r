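#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

RAW_N <- charToRaw("N")

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement in DNA space (`N` maps to `N`).
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Mismatch count between two equal-length sequences given as raw vectors.
# N never matches any base, including another N.
hamming_raw <- function(a, b) {
  sum(a != b | a == RAW_N | b == RAW_N)
}

# Normalise a nucleotide string: uppercase, U -> T. Returns NULL if the
# result contains characters outside {A,C,G,T,N}.
normalize_nt <- function(x) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) return(list(seq = x, bad = which(bad)))
  list(seq = x, bad = integer(0))
}

validate_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  invisible(strand)
}

# Empty alignment-hit tibble, the common currency of the aligner.
empty_hits <- function() {
  tibble(
    read_id = character(0), ref_name = character(0),
    start = integer(0), strand = character(0),
    mismatches = integer(0), read_len = integer(0)
  )
}
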