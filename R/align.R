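#' Build a k-mer alignment index over a reference set
#'
#' Hashes every plus-strand k-mer position of every reference sequence.
#' Together with pigeonhole seeding in [align_reads()] this supports
#' exhaustive ungapped k-mismatch placement: any placement with at most
#' `max_mm` substitutions contains at least one of `max_mm + 1`
#' non-overlapping exact seeds, so looking all of them up and verifying
#' candidates by full comparison finds every placement. Minus-strand
#' placements are found by seeding the reverse complement of the read, so
#' the single plus-strand map serves both strands.
#'
#' @param refs Reference tibble from [read_fasta()] (or several row-bound
#'   categories; `name` must be unique).
#' @param seed_len Seed (k-mer) length in nt, `>= 4`. Completeness for a
#'   read of length L at `max_mm` mismatches requires
#'   `(max_mm + 1) * seed_len <= L`; reads failing that are aligned by an
#'   exhaustive window scan instead.
#' @return An object of class `srna_index`.
#' @export
srna_index <- function(refs, seed_len = 10L) {
  if (is.null(refs) || nrow(refs) == 0) {
    stop("cannot index an empty reference set", call. = FALSE)
  }
  if (anyDuplicated(refs$name)) stop("duplicate reference names", call. = FALSE)
  seed_len <- as.integer(seed_len)
  if (seed_len < 4L) stop("seed_len must be >= 4", call. = FALSE)
  short <- refs$length < seed_len
  if (any(short)) {
    warning("excluding ", sum(short), " reference(s) shorter than seed_len ",
            "from the index", call. = FALSE)
  }
  map <- new.env(hash = TRUE, parent = emptyenv())
  for (i in which(!short)) {
    L <- refs$length[i]
    starts <- seq_len(L - seed_len + 1L)
    kmers <- substring(refs$seq[i], starts, starts + seed_len - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    occ <- split(starts[keep] - 1L, kmers[keep])  # 0-based seed positions
    for (km in names(occ)) {
      map[[km]] <- rbind(map[[km]], cbind(i, occ[[km]]))
    }
  }
  structure(
    list(refs = refs, seed_len = seed_len,
         ref_int = lapply(refs$seq, utf8ToInt), map = map),
    class = "srna_index"
  )
}

#' @export
print.srna_index <- function(x, ...) {
  cat("<srna_index> ", nrow(x$refs), " reference(s), ",
      sum(x$refs$length), " nt, seed_len ", x$seed_len, "\n", sep = "")
  invisible(x)
}

INT_N <- utf8ToInt("N")

# Exhaustive window scan of one query (already on the reference's plus
# strand) over one reference integer vector; returns 0-based starts and
# mismatch counts of all windows with <= max_mm mismatches.
scan_windows <- function(q, ref, max_mm) {
  L <- length(q)
  nw <- length(ref) - L + 1L
  if (nw < 1L) return(list(start = integer(0), mm = integer(0)))
  mm <- integer(nw)
  for (j in seq_len(L)) {
    rj <- ref[j:(j + nw - 1L)]
    mm <- mm + (rj != q[j] | rj == INT_N | q[j] == INT_N)
  }
  keep <- which(mm <= max_mm)
  list(start = keep - 1L, mm = mm[keep])
}

# Candidate starts for one oriented query from pigeonhole seed lookups.
pigeonhole_candidates <- function(qseq, index, max_mm) {
  L <- nchar(qseq)
  k <- index$seed_len
  nseed <- max_mm + 1L
  offs <- floor((seq_len(nseed) - 1L) * L / nseed)  # 0-based block starts
  cand <- NULL
  for (o in offs) {
    seed <- substr(qseq, o + 1L, o + k)
    if (grepl("N", seed, fixed = TRUE)) next
    occ <- index$map[[seed]]
    if (is.null(occ)) next
    cand <- rbind(cand, cbind(occ[, 1L], occ[, 2L] - o))
  }
  if (is.null(cand)) return(cand)
  unique(cand[cand[, 2L] >= 0L, , drop = FALSE])
}

# One read, both strands; returns plain vectors (ridx/start/strand/mm)
# so the caller can assemble a single tibble for the whole read set.
align_one <- function(seq, rc, index, max_mm) {
  L <- nchar(seq)
  queries <- c(`+` = seq, `-` = rc)
  use_seeds <- (max_mm + 1L) * index$seed_len <= L
  starts <- mm <- ridx <- integer(0)
  strands <- character(0)
  for (s in 1:2) {
    qint <- utf8ToInt(queries[[s]])
    if (use_seeds) {
      cand <- pigeonhole_candidates(queries[[s]], index, max_mm)
      if (is.null(cand) || nrow(cand) == 0L) next
      cand <- cand[cand[, 2L] + L <= index$refs$length[cand[, 1L]], ,
                   drop = FALSE]
      if (nrow(cand) == 0L) next
      d <- vapply(seq_len(nrow(cand)), function(r) {
        hamming_int(qint, index$ref_int[[cand[r, 1L]]], cand[r, 2L])
      }, integer(1))
      keep <- d <= max_mm
      hs <- cand[keep, 2L]; hmm <- d[keep]; hi <- cand[keep, 1L]
    } else {
      hs <- hmm <- hi <- integer(0)
      for (i in seq_len(nrow(index$refs))) {
        hit <- scan_windows(qint, index$ref_int[[i]], max_mm)
        hs <- c(hs, hit$start); hmm <- c(hmm, hit$mm)
        hi <- c(hi, rep(i, length(hit$start)))
      }
    }
    if (length(hs)) {
      starts <- c(starts, hs); mm <- c(mm, hmm); ridx <- c(ridx, hi)
      strands <- c(strands, rep(names(queries)[s], length(hs)))
    }
  }
  list(ridx = ridx, start = starts, strand = strands, mm = mm)
}

hamming_int <- function(q, ref, start0) {
  w <- ref[(start0 + 1L):(start0 + length(q))]
  sum(w != q | w == INT_N | q == INT_N)
}

#' Align reads: exhaustive ungapped k-mismatch placement
#'
#' Returns every ungapped placement of every read on either strand of the
#' indexed references with at most `max_mm` substitutions. `N` in the read
#' or the reference always counts as a mismatch. Reads shorter than the
#' index seed length yield no hits (with a warning).
#'
#' @param reads Read tibble from [read_fastq()] (columns `read_id`, `seq`).
#' @param index An [srna_index()].
#' @param max_mm Maximum number of substitutions, `>= 0`.
#' @return Alignment-hit tibble: `read_id`, `ref_name`, `start` (0-based),
#'   `strand` (`"+"`/`"-"`), `mismatches`, `read_len`.
#' @export
align_reads <- function(reads, index, max_mm = 0L) {
  stopifnot(inherits(index, "srna_index"), max_mm >= 0)
  max_mm <- as.integer(max_mm)
  too_short <- nchar(reads$seq) < index$seed_len
  if (any(too_short)) {
    warning(sum(too_short), " read(s) shorter than seed_len left unaligned",
            call. = FALSE)
  }
  keep <- which(!too_short)
  if (!length(keep)) return(empty_hits())
  rc <- revcomp(reads$seq[keep])
  res <- purrr::map(seq_along(keep), function(j) {
    i <- keep[j]
    align_one(reads$seq[i], rc[j], index, max_mm)
  })
  nhit <- vapply(res, function(r) length(r$start), integer(1))
  if (sum(nhit) == 0) return(empty_hits())
  ridx <- unlist(lapply(res, `[[`, "ridx"), use.names = FALSE)
  tibble(
    read_id = rep(reads$read_id[keep], nhit),
    ref_name = index$refs$name[ridx],
    start = unlist(lapply(res, `[[`, "start"), use.names = FALSE),
    strand = unlist(lapply(res, `[[`, "strand"), use.names = FALSE),
    mismatches = unlist(lapply(res, `[[`, "mm"), use.names = FALSE),
    read_len = rep(nchar(reads$seq[keep]), nhit)
  )
}

#' Classify genomic mapping uniqueness of reads
#'
#' Flags each read as a genome-unique mapper (exactly one placement within
#' the mismatch bound), a multi-mapper (two or more) or unmapped (none).
#'
#' @param hits Alignment-hit tibble of genomic placements, produced with a
#'   single `max_mm` bound (all placements, not one sampled placement).
#' @param read_ids Character vector of all read ids that were aligned
#'   (defaults to the ids present in `hits`, in which case no read can be
#'   flagged unmapped).
#' @return Tibble `read_id`, `n_hits`, `status` with
#'   `status %in% c("unique", "multi", "unmapped")`.
#' @export
classify_uniqueness <- function(hits, read_ids = unique(hits$read_id)) {
  counts <- dplyr::count(hits, .data$read_id, name = "n_hits")
  tibble(read_id = read_ids) |>
    dplyr::left_join(counts, by = "read_id") |>
    dplyr::mutate(
      n_hits = dplyr::coalesce(.data$n_hits, 0L),
      status = dplyr::case_when(
        .data$n_hits == 1L ~ "unique",
        .data$n_hits >= 2L ~ "multi",
        TRUE ~ "unmapped"
      )
    )
}

#' Resolve multi-mapper placements with a deterministic policy
#'
#' In `"random_one"` mode each read keeps exactly one placement, drawn
#' uniformly among its minimum-mismatch placements with a seeded generator
#' (candidates are first ordered by reference name, start and strand so
#' runs are reproducible across platforms); this emulates the
#' one-placement-per-read reporting of common read mappers. In `"all"`
#' mode every placement is kept, for exhaustive density profiling.
#'
#' @param hits Alignment-hit tibble.
#' @param mode `"random_one"` or `"all"`.
#' @param seed Integer seed for the placement draw.
#' @return Alignment-hit tibble, at most one row per read in
#'   `"random_one"` mode.
#' @export
place_reads <- function(hits, mode = c("random_one", "all"), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "all" || nrow(hits) == 0) return(hits)
  grp <- factor(hits$read_id, levels = unique(hits$read_id))
  min_mm <- stats::ave(hits$mismatches, grp, FUN = min)
  best <- hits[hits$mismatches == min_mm, , drop = FALSE]
  grp <- factor(best$read_id, levels = unique(best$read_id))
  ord <- order(as.integer(grp), best$ref_name, best$start, best$strand)
  best <- best[ord, , drop = FALSE]
  sizes <- tabulate(grp)
  offset <- cumsum(c(0L, sizes[-length(sizes)]))
  withr::with_seed(as.integer(seed), {
    pick <- vapply(sizes, function(n) sample.int(n, 1L), integer(1))
  })
  best[offset + pick, , drop = FALSE]
}
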