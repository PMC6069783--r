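#' Import alignments from a SAM file
#'
#' Imports mapped records from a SAM file (e.g. produced by an external
#' aligner such as BWA) into the alignment-hit tibble used throughout the
#' package. SAM 1-based `POS` is converted to a 0-based start, `FLAG` bit
#' 16 becomes the minus strand, and unmapped records are dropped. The
#' mismatch count is taken from the `NM` tag when present and recomputed
#' against the reference otherwise. The model is ungapped: records whose
#' CIGAR contains indels or clipping are skipped with a warning.
#'
#' @param path Path to a SAM file with `@SQ` header lines.
#' @param refs Reference tibble from [read_fasta()]; every `@SQ` name must
#'   match a reference of identical length.
#' @return A tibble with columns `read_id`, `ref_name`, `start`, `strand`,
#'   `mismatches`, `read_len`.
#' @export
import_alignments <- function(path, refs) {
  if (!file.exists(path)) stop("SAM file not found: ", path, call. = FALSE)
  bam <- suppressMessages(
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  )
  on.exit(unlink(bam), add = TRUE)
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  known <- stats::setNames(refs$length, refs$name)
  miss <- setdiff(names(targets), names(known))
  if (length(miss)) {
    stop("SAM header references not present in reference set: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  badlen <- names(targets)[targets != known[names(targets)]]
  if (length(badlen)) {
    stop("SAM header length mismatch for reference: ",
         paste(badlen, collapse = ", "), call. = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qwidth"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  if (n == 0) return(empty_hits())

  gapped <- grepl("[^0-9M]", rec$cigar)
  if (any(gapped)) {
    warning(sum(gapped), " SAM record(s) with indels or clipping skipped ",
            "(ungapped model)", call. = FALSE)
  }
  keep <- !gapped
  nm <- rec$tag$NM[keep]
  hits <- tibble(
    read_id = rec$qname[keep],
    ref_name = as.character(rec$rname[keep]),
    start = rec$pos[keep] - 1L,
    strand = ifelse(bitwAnd(rec$flag[keep], 16L) > 0L, "-", "+"),
    mismatches = if (is.null(nm)) rep(NA_integer_, sum(keep)) else as.integer(nm),
    read_len = rec$qwidth[keep]
  )
  need <- which(is.na(hits$mismatches))
  if (length(need)) {
    seqs <- as.character(rec$seq[keep])  # stored on the reference's plus strand
    refseq <- stats::setNames(refs$seq, refs$name)
    hits$mismatches[need] <- vapply(need, function(i) {
      window <- substr(refseq[[hits$ref_name[i]]],
                       hits$start[i] + 1L, hits$start[i] + hits$read_len[i])
      hamming_raw(charToRaw(seqs[i]), charToRaw(window))
    }, integer(1))
  }
  hits
}

#' Export alignment hits as SAM
#'
#' Writes placements in minimal ungapped SAM (full-length `M` CIGAR, `NM`
#' tag, `@SQ` header per reference, records sorted by reference and
#' position). Minus-strand records store the reverse complement of the
#' read, per the SAM convention.
#'
#' @param hits Alignment-hit tibble.
#' @param reads Read tibble from [read_fastq()] supplying `seq`/`qual`.
#' @param refs Reference tibble from [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, reads, refs, path) {
  validate_strand(hits$strand)
  hits <- dplyr::arrange(hits, .data$ref_name, .data$start, .data$strand)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", refs$name, refs$length)
  )
  if (nrow(hits) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  idx <- match(hits$read_id, reads$read_id)
  if (anyNA(idx)) stop("hit for unknown read id", call. = FALSE)
  seqs <- reads$seq[idx]
  quals <- reads$qual[idx]
  minus <- hits$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  quals[minus] <- vapply(
    quals[minus], function(q) intToUtf8(rev(utf8ToInt(q))), character(1),
    USE.NAMES = FALSE)
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                  hits$read_id, ifelse(minus, 16L, 0L), hits$ref_name,
                  hits$start + 1L, hits$read_len, seqs, quals, hits$mismatches)
  writeLines(c(header, body), path)
  invisible(path)
}
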