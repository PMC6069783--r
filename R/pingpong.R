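#' Per-position 5' end counts on one feature
#'
#' Accumulates the 5'-end positions of placements on a single feature,
#' one count vector per strand. A plus-strand read's 5' end is its start;
#' a minus-strand read's 5' end is `start + read_len - 1`. Counts carry
#' read multiplicity.
#'
#' @param placements Alignment-hit tibble restricted to one feature.
#' @param feature_len Length of the feature in nt.
#' @return List with numeric vectors `plus` and `minus` of length
#'   `feature_len` (index i = 0-based position i-1).
#' @export
five_prime_profiles <- function(placements, feature_len) {
  if (length(unique(placements$ref_name)) > 1) {
    stop("placements span more than one feature", call. = FALSE)
  }
  validate_strand(placements$strand)
  five <- ifelse(placements$strand == "+", placements$start,
                 placements$start + placements$read_len - 1L)
  if (any(five < 0 | five >= feature_len)) {
    stop("5' end outside the feature", call. = FALSE)
  }
  prof <- function(pos) {
    tabulate(pos + 1L, nbins = feature_len)
  }
  list(plus = prof(five[placements$strand == "+"]),
       minus = prof(five[placements$strand == "-"]))
}

#' Opposite-strand 5'-overlap spectrum
#'
#' Counts, for each overlap size s = 1..S, the number of ordered
#' (plus-read, minus-read) pairs whose 5' ends span exactly s overlapping
#' nucleotides: a plus 5' end at p and a minus 5' end at q = p + s - 1
#' (both ends inside the duplex, so s = 10 is the classical ping-pong
#' configuration q = p + 9). Pairs are counted with read multiplicity via
#' the profile product `N_s = sum_p plus[p] * minus[p + s - 1]`.
#'
#' @param plus_profile,minus_profile Per-position 5'-end count vectors
#'   over the same feature (from [five_prime_profiles()]).
#' @param S Maximum overlap size evaluated; by convention the minimum
#'   piRNA read length (default 23).
#' @return Tibble `overlap` (1..S), `n_pairs`.
#' @export
overlap_spectrum <- function(plus_profile, minus_profile, S = 23L) {
  S <- as.integer(S)
  if (S < 1L) stop("S must be >= 1", call. = FALSE)
  L <- length(plus_profile)
  stopifnot(length(minus_profile) == L)
  n <- vapply(seq_len(S), function(s) {
    if (s > L) return(0)
    sum(plus_profile[seq_len(L - s + 1L)] * minus_profile[s:L])
  }, numeric(1))
  tibble(overlap = seq_len(S), n_pairs = n)
}

#' Ping-pong z-score statistics of an overlap spectrum
#'
#' Tests whether the 10-nt overlap count stands out of the overlap-size
#' spectrum under a normal model: with counts N_1..N_S, the mean is
#' `overlap_sum / S`, sigma is the population standard deviation of all S
#' counts (including N_10), `z = (N_10 - mean) / sigma`, and the p-value
#' is the one-sided upper-tail normal probability `1 - pnorm(z)`. A
#' degenerate spectrum (sigma = 0, e.g. no placements at all) yields `NA`
#' for z and p.
#'
#' @param spectrum Tibble from [overlap_spectrum()] with S >= 10 rows.
#' @return One-row tibble `overlap_sum`, `ten_sum`, `mean`, `sd`, `z`, `p`.
#' @export
pingpong_stats <- function(spectrum) {
  n <- spectrum$n_pairs
  S <- length(n)
  if (S < 10L) stop("spectrum must cover overlaps up to at least 10", call. = FALSE)
  total <- sum(n)
  mu <- total / S
  sigma <- sqrt(sum((n - mu)^2) / S)
  if (sigma == 0) {
    z <- NA_real_; p <- NA_real_
  } else {
    z <- (n[10] - mu) / sigma
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  tibble(overlap_sum = total, ten_sum = n[10], mean = mu, sd = sigma,
         z = z, p = p)
}

#' Ping-pong statistics from published summary values
#'
#' Recomputes the derived ping-pong statistics from the summary numbers
#' reported in a stats table (the overlap sum, the 10-nt overlap count
#' and the standard deviation), using the same conventions as
#' [pingpong_stats()]: `mean = overlap_sum / S`,
#' `z = (ten_sum - mean) / sigma`, `p = 1 - pnorm(z)`. Useful to check a
#' reported table for internal consistency.
#'
#' @param overlap_sum Sum of all overlap counts N_1..N_S.
#' @param ten_sum The 10-nt overlap count N_10.
#' @param sigma Population standard deviation of the S counts.
#' @param S Number of overlap sizes (default 23).
#' @return One-row tibble `mean`, `z`, `p`.
#' @export
pingpong_stats_from_summary <- function(overlap_sum, ten_sum, sigma, S = 23L) {
  mu <- overlap_sum / S
  z <- (ten_sum - mu) / sigma
  tibble(mean = mu, z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Overlap histogram as percentages
#'
#' @param spectrum Tibble from [overlap_spectrum()].
#' @return Tibble `overlap`, `percent` with `sum(percent) == 100`; all
#'   `NA` when the spectrum is empty.
#' @export
overlap_histogram <- function(spectrum) {
  total <- sum(spectrum$n_pairs)
  tibble(overlap = spectrum$overlap,
         percent = if (total > 0) 100 * spectrum$n_pairs / total else
           rep(NA_real_, nrow(spectrum)))
}

#' Reads with and without a ping-pong partner
#'
#' Partitions the placed reads of one feature by strand and by whether an
#' opposite-strand placement forms a 10-nt 5'-overlap with them: a
#' plus-strand read with 5' end at p has a partner iff some minus-strand
#' 5' end sits at p + 9, and vice versa (positions outside the feature
#' count as empty).
#'
#' @param placements Alignment-hit tibble restricted to one feature.
#' @param feature_len Feature length in nt.
#' @return List of four read-id character vectors: `sense_with`,
#'   `sense_without`, `antisense_with`, `antisense_without`.
#' @export
partner_lists <- function(placements, feature_len) {
  prof <- five_prime_profiles(placements, feature_len)
  five <- ifelse(placements$strand == "+", placements$start,
                 placements$start + placements$read_len - 1L)
  at <- function(profile, pos) {
    ok <- pos >= 0L & pos < feature_len
    out <- rep(FALSE, length(pos))
    out[ok] <- profile[pos[ok] + 1L] > 0
    out
  }
  plus <- placements$strand == "+"
  has_partner <- logical(nrow(placements))
  has_partner[plus] <- at(prof$minus, five[plus] + 9L)
  has_partner[!plus] <- at(prof$plus, five[!plus] - 9L)
  list(
    sense_with = placements$read_id[plus & has_partner],
    sense_without = placements$read_id[plus & !has_partner],
    antisense_with = placements$read_id[!plus & has_partner],
    antisense_without = placements$read_id[!plus & !has_partner]
  )
}

#' Ping-pong signature analysis across features
#'
#' Runs the full ping-pong analysis per feature on a set of placements
#' (canonically: TE placements of the piRNA subgroup in the 0..k_max
#' mismatch stratum): 5' profiles, overlap spectrum up to
#' `S = pirna_min`, z-score statistics, percentage histogram and partner
#' lists. Features with no opposite-strand overlap signal at all are kept
#' with `NA` statistics.
#'
#' @param placements Alignment-hit tibble on the TE reference set.
#' @param refs TE reference tibble.
#' @param S Maximum overlap size (default 23, the default minimum piRNA
#'   length).
#' @return Object of class `srna_pingpong`: a list with `stats` (one row
#'   per feature), `spectra`, `histograms` and `partners` (named lists).
#' @export
pingpong_analysis <- function(placements, refs, S = 23L) {
  features <- refs$name
  spectra <- histograms <- partners <- stats::setNames(
    vector("list", length(features)), features)
  rows <- vector("list", length(features))
  for (i in seq_along(features)) {
    f <- features[i]
    pl <- dplyr::filter(placements, .data$ref_name == !!f)
    prof <- five_prime_profiles(pl, refs$length[i])
    sp <- overlap_spectrum(prof$plus, prof$minus, S)
    spectra[[f]] <- sp
    histograms[[f]] <- overlap_histogram(sp)
    partners[[f]] <- partner_lists(pl, refs$length[i])
    rows[[i]] <- dplyr::bind_cols(tibble(ID = f), pingpong_stats(sp))
  }
  structure(list(stats = dplyr::bind_rows(rows), spectra = spectra,
                 histograms = histograms, partners = partners, S = S),
            class = "srna_pingpong")
}

#' Ping-pong statistics table with report column names
#'
#' Renders the per-feature statistics with the column set used in the
#' report tables: ID, overlap sum, ten overlap sum, mean, standard
#' deviation, z-score, p-value.
#'
#' @param x An `srna_pingpong` object.
#' @return Tibble with the seven report columns.
#' @export
pingpong_table <- function(x) {
  stopifnot(inherits(x, "srna_pingpong"))
  stats::setNames(
    x$stats,
    c("ID", "overlap sum", "ten overlap sum", "mean", "standard deviation",
      "z-score", "p-value"))
}

#' @export
print.srna_pingpong <- function(x, ...) {
  cat("<srna_pingpong> ", nrow(x$stats), " feature(s), overlaps 1..",
      x$S, "\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-feature ping-pong statistics
#'
#' @param x An `srna_pingpong` object.
#' @param ... Unused.
#' @return Tibble with one row per feature: `feature`, `overlap_sum`,
#'   `ten_sum`, `mean`, `sd`, `z`, `p`.
#' @exportS3Method generics::tidy
tidy.srna_pingpong <- function(x, ...) {
  dplyr::rename(x$stats, feature = "ID")
}

#' One-row summary of a ping-pong analysis
#'
#' @param x An `srna_pingpong` object.
#' @param ... Unused.
#' @return Tibble with `n_features`, `n_scored` (features with a defined
#'   z), `n_signature` (z > 1.96), `max_z`, `top_feature`.
#' @exportS3Method generics::glance
glance.srna_pingpong <- function(x, ...) {
  st <- x$stats
  scored <- !is.na(st$z)
  tibble(
    n_features = nrow(st),
    n_scored = sum(scored),
    n_signature = sum(st$z[scored] > stats::qnorm(0.975)),
    max_z = if (any(scored)) max(st$z[scored]) else NA_real_,
    top_feature = if (any(scored)) st$ID[which.max(ifelse(scored, st$z, -Inf))]
      else NA_character_
  )
}
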