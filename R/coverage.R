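#' Strand-specific coverage track
#'
#' Builds a binned coverage track for one reference sequence and strand.
#' `depth` mode accumulates full read footprints (per-base depth, summed
#' within each bin); `five_prime` mode accumulates 5' ends. `per_million`
#' normalization divides by `denominator / 1e6`; `rpkm_binned`
#' additionally divides by `bin_size / 1000`, giving the
#' reads-per-kilobase-per-million unit used for chromosome profiles
#' (default bin 1000 nt).
#'
#' @param placements Alignment-hit tibble.
#' @param ref_name Reference sequence to profile.
#' @param ref_len Its length in nt.
#' @param strand `"+"` or `"-"`.
#' @param mode `"depth"` or `"five_prime"`.
#' @param bin_size Bin width in nt (1 = per-base).
#' @param normalization `"raw"`, `"per_million"` or `"rpkm_binned"`.
#' @param denominator Mapper total for the per-million term (required
#'   unless `normalization = "raw"`).
#' @return Tibble `ref_name`, `strand`, `start`, `end`, `value` (one row
#'   per bin, 0-based half-open), with attributes `bin_size`, `mode`,
#'   `normalization`.
#' @export
coverage_track <- function(placements, ref_name, ref_len, strand = "+",
                           mode = c("depth", "five_prime"), bin_size = 1L,
                           normalization = c("raw", "per_million", "rpkm_binned"),
                           denominator = NULL) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  bin_size <- as.integer(bin_size)
  if (bin_size < 1L) stop("bin_size must be >= 1", call. = FALSE)
  if (normalization != "raw" && (is.null(denominator) || denominator <= 0)) {
    stop("positive denominator required for normalized tracks", call. = FALSE)
  }
  validate_strand(strand)
  pl <- dplyr::filter(placements, .data$ref_name == !!ref_name,
                      .data$strand == !!strand)
  if (mode == "depth") {
    ir <- IRanges::IRanges(start = pl$start + 1L, width = pl$read_len)
  } else {
    five <- ifelse(pl$strand == "+", pl$start, pl$start + pl$read_len - 1L)
    ir <- IRanges::IRanges(start = five + 1L, width = 1L)
  }
  base <- as.numeric(IRanges::coverage(ir, width = ref_len))
  nb <- ceiling(ref_len / bin_size)
  bin_idx <- rep(seq_len(nb), each = bin_size)[seq_len(ref_len)]
  values <- as.numeric(rowsum(base, bin_idx)[, 1])
  if (normalization %in% c("per_million", "rpkm_binned")) {
    values <- values / (denominator / 1e6)
  }
  if (normalization == "rpkm_binned") {
    values <- values / (bin_size / 1000)
  }
  starts <- (seq_len(nb) - 1L) * bin_size
  structure(
    tibble(ref_name = ref_name, strand = strand, start = starts,
           end = pmin(starts + bin_size, ref_len), value = values),
    bin_size = bin_size, mode = mode, normalization = normalization,
    class = c("srna_track", class(tibble())))
}

#' Write a coverage track as bedgraph
#'
#' Emits standard bedgraph lines (`ref start end value`, 0-based
#' half-open). Zero-valued runs are omitted and adjacent equal-valued
#' bins are merged into single intervals. Input intervals must be sorted
#' and non-overlapping.
#'
#' @param track Tibble with columns `ref_name`, `start`, `end`, `value`
#'   (as from [coverage_track()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if (nrow(track) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  per_ref <- split(track, factor(track$ref_name, levels = unique(track$ref_name)))
  lines <- unlist(lapply(per_ref, function(tr) {
    if (is.unsorted(tr$start, strictly = TRUE) ||
        any(tr$start[-1] < tr$end[-nrow(tr)])) {
      stop("bedgraph intervals must be sorted and non-overlapping", call. = FALSE)
    }
    merged <- tr |>
      dplyr::mutate(run = cumsum(
        dplyr::row_number() == 1L |
          .data$value != dplyr::lag(.data$value) |
          .data$start != dplyr::lag(.data$end))) |>
      dplyr::group_by(.data$run) |>
      dplyr::summarise(ref_name = .data$ref_name[1], start = min(.data$start),
                       end = max(.data$end), value = .data$value[1],
                       .groups = "drop") |>
      dplyr::filter(.data$value != 0)
    sprintf("%s %d %d %s", merged$ref_name, merged$start, merged$end,
            vapply(merged$value, format, character(1), digits = 15))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedgraph file into interval form
#'
#' @param path Path to a bedgraph file.
#' @return Tibble `ref_name`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (length(readLines(path)) == 0) {
    return(tibble(ref_name = character(0), start = integer(0),
                  end = integer(0), value = numeric(0)))
  }
  readr::read_delim(path, delim = " ",
                    col_names = c("ref_name", "start", "end", "value"),
                    col_types = "ciid", progress = FALSE)
}
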