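#' Read a FASTQ file of small RNA reads
#'
#' Parses a phred+33 FASTQ file of adapter-trimmed single-end reads into a
#' tibble, one row per read. Sequences are uppercased and `U` residues are
#' converted to `T`; every record is validated (4-line structure, matching
#' sequence/quality lengths, `{A,C,G,T,N}` alphabet) and a malformed record
#' raises an error naming the offending line. Reads are never collapsed:
#' each FASTQ record is an independent unit.
#'
#' @param path Path to a FASTQ file. An empty file yields an empty tibble.
#' @return A tibble with columns `read_id`, `seq`, `qual`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGU", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(read_id = character(0), seq = character(0), qual = character(0)))
  }
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ record starting at line ",
         4L * (length(lines) %/% 4L) + 1L, call. = FALSE)
  }
  hd <- seq(1L, length(lines), by = 4L)
  header <- lines[hd]
  sq <- lines[hd + 1L]
  sep <- lines[hd + 2L]
  qual <- lines[hd + 3L]

  bad <- which(!startsWith(header, "@"))
  if (length(bad)) stop("FASTQ header missing '@' at line ", hd[bad[1]], call. = FALSE)
  bad <- which(!startsWith(sep, "+"))
  if (length(bad)) stop("FASTQ separator missing '+' at line ", hd[bad[1]] + 2L, call. = FALSE)
  bad <- which(nchar(sq) != nchar(qual) | nchar(sq) == 0L)
  if (length(bad)) {
    stop("sequence/quality length mismatch at line ", hd[bad[1]] + 1L, call. = FALSE)
  }
  norm <- normalize_nt(sq)
  if (length(norm$bad)) {
    stop("illegal sequence character at line ", hd[norm$bad[1]] + 1L, call. = FALSE)
  }
  bad <- which(grepl("[^\\x21-\\x7e]", qual))
  if (length(bad)) stop("illegal quality character at line ", hd[bad[1]] + 3L, call. = FALSE)

  tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", header)),
    seq = norm$seq,
    qual = qual
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with columns `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  out <- character(4L * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$read_id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$seq
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Read a multi-FASTA reference file
#'
#' Loads one category of reference sequences (genome contigs, transposable
#' elements, transcripts, miRNAs, rRNAs, tRNAs or snRNAs). Header names are
#' tokenised at the first whitespace; duplicate names and illegal characters
#' are rejected. `U` residues are converted to `T`.
#'
#' @param path Path to a (multi-)FASTA file.
#' @param category Category tag, one of `"genome"`, `"TE"`, `"transcript"`,
#'   `"miRNA"`, `"rRNA"`, `"tRNA"`, `"snRNA"`.
#' @return A tibble with columns `category`, `name`, `seq`, `length`.
#' @export
read_fasta <- function(path, category = "genome") {
  category <- match.arg(category,
    c("genome", "TE", "transcript", "miRNA", "rRNA", "tRNA", "snRNA"))
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name in ", path, ": ",
         nm[duplicated(nm)][1], call. = FALSE)
  }
  sq <- as.character(set)
  norm <- normalize_nt(sq)
  if (length(norm$bad)) {
    stop("illegal characters in reference sequence '", nm[norm$bad[1]], "'",
         call. = FALSE)
  }
  if (any(nchar(norm$seq) == 0L)) {
    stop("empty reference sequence '", nm[nchar(norm$seq) == 0L][1], "'",
         call. = FALSE)
  }
  tibble(category = category, name = unname(nm), seq = unname(norm$seq),
         length = unname(nchar(norm$seq)))
}

#' Write a reference set to FASTA
#'
#' @param refs Tibble with columns `name`, `seq` (as from [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path) {
  set <- Biostrings::DNAStringSet(refs$seq)
  names(set) <- refs$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Writes any of the pipeline's tabular outputs (feature count tables,
#' ping-pong statistics, length distributions, ...) as a tab-separated file
#' with a header row. Floating-point values are rendered with full
#' (shortest round-trip, >= 15 significant digits) precision so that
#' normalized columns are reproducible bit-for-bit as text.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
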