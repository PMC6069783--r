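CATEGORY_LEVELS <- c("miRNA", "rRNA", "tRNA", "snRNA", "transcript", "TE", "other")
DEFAULT_CATEGORY_ORDER <- c("rRNA", "miRNA", "tRNA", "snRNA", "transcript", "TE")

#' Pipeline parameters
#'
#' Bundles the tunable parameters of the classification cascade: the read
#' length selection window, the siRNA and piRNA length windows used for
#' subgroup extraction, the mismatch bounds for genomic and
#' TE/transcript/category alignment, and the order in which genome-mapping
#' reads are tested against the category references (first match wins).
#'
#' @param min_len,max_len Inclusive read-length selection window (nt).
#' @param sirna_min,sirna_max siRNA length window (nt), within the
#'   selection window.
#' @param pirna_min,pirna_max piRNA length window (nt), within the
#'   selection window. `pirna_min` also sets the maximum overlap size of
#'   the ping-pong spectrum.
#' @param genome_mm Mismatch bound for genomic alignment.
#' @param te_mm Mismatch bound for TE/transcript (and category filtering)
#'   alignment.
#' @param category_order Order in which categories claim reads in
#'   [categorize()].
#' @param seed_len Default k-mer seed length for index construction.
#' @param placement_seed Seed for the multi-mapper placement draw.
#' @param placement_mode `"random_one"` or `"all"` (see [place_reads()]).
#' @return A list of class `srna_params`.
#' @export
srna_params <- function(min_len = 18L, max_len = 29L,
                        sirna_min = 21L, sirna_max = 21L,
                        pirna_min = 23L, pirna_max = 29L,
                        genome_mm = 0L, te_mm = 3L,
                        category_order = DEFAULT_CATEGORY_ORDER,
                        seed_len = 10L, placement_seed = 1L,
                        placement_mode = "random_one") {
  stopifnot(min_len >= 1, min_len <= max_len,
            sirna_min <= sirna_max, pirna_min <= pirna_max,
            genome_mm >= 0, te_mm >= 0)
  if (pirna_min < min_len || pirna_max > max_len ||
      sirna_min < min_len || sirna_max > max_len) {
    stop("siRNA/piRNA windows must lie within [min_len, max_len]", call. = FALSE)
  }
  bad <- setdiff(category_order, setdiff(CATEGORY_LEVELS, "other"))
  if (length(bad)) stop("unknown category in order: ", bad[1], call. = FALSE)
  structure(
    list(min_len = as.integer(min_len), max_len = as.integer(max_len),
         sirna_min = as.integer(sirna_min), sirna_max = as.integer(sirna_max),
         pirna_min = as.integer(pirna_min), pirna_max = as.integer(pirna_max),
         genome_mm = as.integer(genome_mm), te_mm = as.integer(te_mm),
         category_order = category_order, seed_len = as.integer(seed_len),
         placement_seed = as.integer(placement_seed),
         placement_mode = placement_mode),
    class = "srna_params"
  )
}

# Seed length that keeps pigeonhole seeding complete for the shortest
# admissible read at a given mismatch bound.
stage_seed_len <- function(params, max_mm) {
  max(4L, min(params$seed_len, params$min_len %/% (max_mm + 1L)))
}

#' Select reads by length
#'
#' Keeps exactly the reads whose length lies in the inclusive window,
#' preserving input order.
#'
#' @param reads Read tibble.
#' @param min_len,max_len Inclusive bounds (nt).
#' @return Filtered read tibble.
#' @export
filter_by_length <- function(reads, min_len = 18L, max_len = 29L) {
  stopifnot(min_len >= 1, min_len <= max_len)
  dplyr::filter(reads, nchar(.data$seq) >= min_len, nchar(.data$seq) <= max_len)
}

#' Sequentially categorize genome-mapping reads
#'
#' Assigns each genome-mapping read to exactly one category by aligning
#' its sequence against the category reference sets in the configured
#' order; a read is claimed by the first category it maps to within the
#' category mismatch bound (`te_mm`), and only still-unassigned reads move
#' on to the next reference. Reads matching no category are `"other"`.
#' Categories without a reference set (e.g. no snRNA annotation) are
#' skipped and count zero.
#'
#' @param reads Tibble of genome-mapping reads (columns `read_id`, `seq`).
#' @param refs Reference tibble covering any of the categories in
#'   `params$category_order` (row-bound [read_fasta()] outputs).
#' @param params An [srna_params()].
#' @return Tibble `read_id`, `category` of class `srna_categories`, with
#'   attribute `counts` (named per-category totals incl. `other`).
#' @export
categorize <- function(reads, refs, params = srna_params()) {
  assigned <- tibble(read_id = character(0), category = character(0))
  remaining <- reads
  for (cat in params$category_order) {
    cat_refs <- dplyr::filter(refs, .data$category == !!cat)
    if (nrow(cat_refs) == 0 || nrow(remaining) == 0) next
    idx <- srna_index(cat_refs, stage_seed_len(params, params$te_mm))
    hits <- align_reads(remaining, idx, params$te_mm)
    claimed <- unique(hits$read_id)
    if (length(claimed)) {
      assigned <- dplyr::bind_rows(
        assigned, tibble(read_id = claimed, category = cat))
      remaining <- dplyr::filter(remaining, !.data$read_id %in% claimed)
    }
  }
  if (nrow(remaining)) {
    assigned <- dplyr::bind_rows(
      assigned, tibble(read_id = remaining$read_id, category = "other"))
  }
  out <- dplyr::left_join(dplyr::select(reads, "read_id"), assigned, by = "read_id")
  counts <- table(factor(out$category, levels = CATEGORY_LEVELS))
  structure(out, class = c("srna_categories", class(out)),
            counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Extract the four analysis subgroups
#'
#' From the exclusive category assignment, derives the subgroup
#' memberships used for all downstream quantification: *bonafide* reads
#' are the genome-mappers minus those assigned to miRNA, rRNA, tRNA or
#' snRNA (transcript-, TE- and unannotated reads are bonafide); the
#' *miRNA* subgroup is the miRNA-assigned reads; *siRNAs* and *piRNAs*
#' are bonafide reads inside their respective length windows.
#'
#' @param assignment Result of [categorize()].
#' @param reads Read tibble supplying sequences (for lengths).
#' @param params An [srna_params()].
#' @return Tibble `read_id`, `length`, `category`, plus logical columns
#'   `bonafide`, `mirna`, `sirna`, `pirna`.
#' @export
extract_subgroups <- function(assignment, reads, params = srna_params()) {
  dplyr::left_join(assignment,
                   dplyr::transmute(reads, .data$read_id, length = nchar(.data$seq)),
                   by = "read_id") |>
    dplyr::mutate(
      bonafide = !.data$category %in% c("miRNA", "rRNA", "tRNA", "snRNA"),
      mirna = .data$category == "miRNA",
      sirna = .data$bonafide & .data$length >= params$sirna_min &
        .data$length <= params$sirna_max,
      pirna = .data$bonafide & .data$length >= params$pirna_min &
        .data$length <= params$pirna_max
    ) |>
    dplyr::select("read_id", "length", "category",
                  "bonafide", "mirna", "sirna", "pirna")
}

#' Category percentages of genome-mapping reads
#'
#' Percentage of genome-mappers per category, relative to the total number
#' of genome-mapping reads (the numbers behind the classification pie
#' chart).
#'
#' @param assignment Result of [categorize()].
#' @return Tibble `category`, `count`, `percent` (percent sums to 100).
#' @export
pie_fractions <- function(assignment) {
  total <- nrow(assignment)
  if (total == 0) stop("no genome-mapping reads to summarise", call. = FALSE)
  counts <- attr(assignment, "counts")
  tibble(category = names(counts), count = unname(counts),
         percent = 100 * unname(counts) / total)
}
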