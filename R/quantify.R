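#' Reads per kilobase per million mappers
#'
#' @param count Read count for the feature.
#' @param feature_len Feature length in nt (> 0).
#' @param total_mappers Library-level mapper total used as the
#'   per-million denominator (> 0).
#' @return `count / ((feature_len/1000) * (total_mappers/1e6))`.
#' @export
rpkm <- function(count, feature_len, total_mappers) {
  if (any(feature_len <= 0)) stop("feature_len must be > 0", call. = FALSE)
  if (any(total_mappers <= 0)) stop("total_mappers must be > 0", call. = FALSE)
  count / ((feature_len / 1000) * (total_mappers / 1e6))
}

#' Reads per million of a subgroup
#'
#' Normalizes a count against a subgroup total (piRNAs, miRNAs or bonafide
#' reads). A zero subgroup total yields `NA`.
#'
#' @param count Read count.
#' @param subgroup_total Subgroup size in reads.
#' @return `1e6 * count / subgroup_total`, or `NA` where
#'   `subgroup_total == 0`.
#' @export
per_million <- function(count, subgroup_total) {
  ifelse(subgroup_total > 0, 1e6 * count / subgroup_total, NA_real_)
}

#' Count placed reads per feature
#'
#' Tallies placements per feature: `count_all` counts every placed read
#' once per placement (so in `"all"` placement mode a multi-mapper
#' increments every feature it maps to, while in `"random_one"` mode it
#' increments exactly one), `count_unique` restricts to genome-unique
#' reads, and sense/antisense totals are kept separately.
#'
#' @param placements Alignment-hit tibble on one reference set.
#' @param refs Reference tibble of that set; every feature appears in the
#'   output even with zero counts.
#' @param uniqueness Tibble from [classify_uniqueness()] (genomic), used
#'   for `count_unique`; reads absent from it count as non-unique.
#' @return Tibble `feature_name`, `feature_len`, `count_all`,
#'   `count_unique`, `count_sense`, `count_antisense`.
#' @export
count_features <- function(placements, refs, uniqueness = NULL) {
  unknown <- setdiff(placements$ref_name, refs$name)
  if (length(unknown)) {
    stop("placement on feature absent from reference set: ", unknown[1],
         call. = FALSE)
  }
  uniq_ids <- if (is.null(uniqueness)) character(0) else
    uniqueness$read_id[uniqueness$status == "unique"]
  per <- placements |>
    dplyr::group_by(feature_name = .data$ref_name) |>
    dplyr::summarise(
      count_all = dplyr::n(),
      count_unique = sum(.data$read_id %in% uniq_ids),
      count_sense = sum(.data$strand == "+"),
      count_antisense = sum(.data$strand == "-"),
      .groups = "drop"
    )
  tibble(feature_name = refs$name, feature_len = refs$length) |>
    dplyr::left_join(per, by = "feature_name") |>
    dplyr::mutate(dplyr::across(
      dplyr::starts_with("count_"), ~ dplyr::coalesce(.x, 0L)))
}

#' 1U / 10A nucleotide bias per feature and strand
#'
#' For each feature, among the reads placed on it, computes the percentage
#' of reads whose first base is `U` (stored as `T`) and whose tenth base
#' is `A`, separately for sense (plus-strand) and antisense (minus-strand)
#' placements. Positions are counted on the read in its own 5'-to-3'
#' orientation: a uridine at position 1 marks primary piRNAs and an
#' adenine at position 10 marks ping-pong secondary piRNAs. Reads shorter
#' than 10 nt are excluded from the 10A denominator; a strand with no
#' reads yields `NA` percentages.
#'
#' @param placements Alignment-hit tibble on one reference set.
#' @param reads Read tibble supplying sequences.
#' @param refs Reference tibble (features with no placements get `NA`s).
#' @return Tibble `feature_name`, `pct_1U_sense`, `pct_10A_sense`,
#'   `pct_1U_antisense`, `pct_10A_antisense`.
#' @export
nucleotide_bias <- function(placements, reads, refs) {
  pl <- dplyr::left_join(placements,
                         dplyr::select(reads, "read_id", "seq"), by = "read_id")
  if (anyNA(pl$seq)) stop("placement for read without sequence", call. = FALSE)
  pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  per <- pl |>
    dplyr::group_by(feature_name = .data$ref_name) |>
    dplyr::summarise(
      pct_1U_sense = pct(substr(.data$seq[.data$strand == "+"], 1, 1) == "T"),
      pct_10A_sense = pct(substr(
        .data$seq[.data$strand == "+" & nchar(.data$seq) >= 10], 10, 10) == "A"),
      pct_1U_antisense = pct(substr(.data$seq[.data$strand == "-"], 1, 1) == "T"),
      pct_10A_antisense = pct(substr(
        .data$seq[.data$strand == "-" & nchar(.data$seq) >= 10], 10, 10) == "A"),
      .groups = "drop"
    )
  dplyr::left_join(tibble(feature_name = refs$name), per, by = "feature_name")
}

#' Full per-feature count table with normalization and bias
#'
#' Assembles the per-feature table reported for each subgroup x reference
#' set: raw all-mapper and genome-unique counts, RPKM (all-mapper counts
#' against the genome-mapper total, unique counts against the
#' genome-unique total), reads per million of the piRNA, miRNA and
#' bonafide subgroups, and the 1U/10A percentages per strand.
#'
#' @param placements Alignment-hit tibble of one subgroup on one
#'   reference set.
#' @param reads Read tibble supplying sequences.
#' @param refs Reference tibble for that set.
#' @param uniqueness Genomic uniqueness tibble ([classify_uniqueness()]).
#' @param total_mappers,total_unique Genome-mapper totals used as RPKM
#'   denominators.
#' @param subgroup_totals Named numeric vector with elements `pirna`,
#'   `mirna`, `bonafide` (sizes of those subgroups).
#' @return Tibble with one row per feature.
#' @export
feature_table <- function(placements, reads, refs, uniqueness,
                          total_mappers, total_unique,
                          subgroup_totals = c(pirna = 0, mirna = 0, bonafide = 0)) {
  counts <- count_features(placements, refs, uniqueness)
  bias <- nucleotide_bias(placements, reads, refs)
  counts |>
    dplyr::mutate(
      rpkm_all = rpkm(.data$count_all, .data$feature_len, total_mappers),
      rpkm_unique = if (total_unique > 0)
        rpkm(.data$count_unique, .data$feature_len, total_unique) else NA_real_,
      per_million_pirna = per_million(.data$count_all, subgroup_totals[["pirna"]]),
      per_million_mirna = per_million(.data$count_all, subgroup_totals[["mirna"]]),
      per_million_bonafide = per_million(.data$count_all, subgroup_totals[["bonafide"]])
    ) |>
    dplyr::left_join(bias, by = "feature_name")
}

#' Mismatch-stratified TE tables
#'
#' Splits TE placements into the three reported strata — `exact`
#' (0 mismatches), `all` (0..k_max) and `imperfect` (1..k_max) — and
#' counts each with [count_features()]. Per feature,
#' `exact + imperfect = all`.
#'
#' @param placements Alignment-hit tibble on the TE reference set, with
#'   recorded mismatch counts.
#' @param refs TE reference tibble.
#' @param k_max User-selected maximal mismatch number; a placement
#'   exceeding it is an error.
#' @param uniqueness Optional genomic uniqueness tibble.
#' @return Named list of three count tibbles: `exact`, `all`, `imperfect`.
#' @export
stratify_te <- function(placements, refs, k_max, uniqueness = NULL) {
  if (any(placements$mismatches > k_max)) {
    stop("placement with more than k_max mismatches", call. = FALSE)
  }
  list(
    exact = count_features(
      dplyr::filter(placements, .data$mismatches == 0L), refs, uniqueness),
    all = count_features(placements, refs, uniqueness),
    imperfect = count_features(
      dplyr::filter(placements, .data$mismatches >= 1L), refs, uniqueness)
  )
}

#' Length distribution of mapped reads
#'
#' Histogram of read length over genome-mapping reads, used to check that
#' the library shows the expected size structure (e.g. a miRNA peak at
#' 22 nt and a piRNA population at 23-29 nt).
#'
#' @param placements Genomic placements (one row per placed read, e.g.
#'   after [place_reads()]) or any tibble with `read_id` and `read_len`.
#' @return Tibble `length`, `count`; counts sum to the number of distinct
#'   placed reads.
#' @export
length_distribution <- function(placements) {
  placements |>
    dplyr::distinct(.data$read_id, .data$read_len) |>
    dplyr::count(length = .data$read_len, name = "count") |>
    dplyr::arrange(.data$length)
}
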