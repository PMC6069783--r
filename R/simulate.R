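#' Parameters for the synthetic small RNA-seq generator
#'
#' Defines a fully synthetic study: reference sequences for every
#' category, embedded verbatim in a genome of several contigs, and a read
#' population with planted composition, length structure, 1U/10A bias,
#' ping-pong pairs, optional duplicated locus and unmappable noise. The
#' default composition mirrors a TE-dominated ovarian small RNA library
#' (TE-derived reads the largest class, a substantial miRNA population at
#' 22 nt, a piRNA-sized 23-29 nt TE population, minor housekeeping RNA
#' contamination) so that every downstream stage sees a realistic mix.
#'
#' @param seed Integer seed; the whole generation is deterministic given
#'   the parameter set.
#' @param n_reads Total number of reads to emit.
#' @param n_contigs Number of genome contigs.
#' @param spacer_len Length of the random spacer between embedded
#'   features (also the source of `other` reads).
#' @param n_te,te_len Number of TE references and their length range.
#' @param n_transcript,transcript_len Transcript references.
#' @param n_mirna,mirna_len Mature miRNA references (each read from this
#'   class is a full-length mature sequence).
#' @param n_rrna,rrna_len,n_trna,trna_len,n_snrna,snrna_len Housekeeping
#'   RNA references.
#' @param composition Named fractions over
#'   `TE, miRNA, transcript, rRNA, tRNA, snRNA, other, noise`; must sum
#'   to at most 1 (the remainder is added to noise).
#' @param te_sirna_fraction Fraction of TE-derived reads emitted at the
#'   siRNA length (21 nt); the rest are piRNA-sized.
#' @param pingpong_fraction Fraction of TE piRNA-sized reads emitted as
#'   planted ping-pong pairs (a plus-strand read with 5' end at p paired
#'   with a minus-strand read whose 5' end is at p + 9).
#' @param bias_1U Probability that a sense TE read starts on a genomic T
#'   (so its first base is U in RNA space).
#' @param bias_10A Probability that an antisense TE read carries A at
#'   position 10. For planted pairs this is not drawn separately: the
#'   partner is the reverse complement of the genomic window, so its 10A
#'   state is the complement of the sense partner's 1U base, as in
#'   ping-pong biology.
#' @param length_window Length range of transcript/housekeeping/other
#'   reads.
#' @param mirna_read_len,sirna_len,pirna_window Class length models.
#' @param duplicate_te If `TRUE`, a second copy of the first TE is
#'   embedded in the genome, making its reads genomic multi-mappers.
#' @return A list of class `srna_sim_params`.
#' @export
srna_sim_params <- function(
    seed = 1L, n_reads = 2000L, n_contigs = 2L, spacer_len = 300L,
    n_te = 3L, te_len = c(600L, 900L),
    n_transcript = 3L, transcript_len = c(400L, 600L),
    n_mirna = 5L, mirna_len = 22L,
    n_rrna = 2L, rrna_len = c(120L, 160L),
    n_trna = 4L, trna_len = c(70L, 90L),
    n_snrna = 2L, snrna_len = c(100L, 140L),
    composition = c(TE = 0.46, miRNA = 0.24, transcript = 0.06,
                    rRNA = 0.05, tRNA = 0.04, snRNA = 0.02,
                    other = 0.08, noise = 0.05),
    te_sirna_fraction = 0.2, pingpong_fraction = 0.5,
    bias_1U = 0.8, bias_10A = 0.8,
    length_window = c(18L, 29L), mirna_read_len = 22L,
    sirna_len = 21L, pirna_window = c(23L, 29L),
    duplicate_te = FALSE) {
  need <- c("TE", "miRNA", "transcript", "rRNA", "tRNA", "snRNA", "other", "noise")
  stopifnot(all(need %in% names(composition)),
            all(composition >= 0), sum(composition) <= 1 + 1e-9,
            pingpong_fraction >= 0, pingpong_fraction <= 1,
            bias_1U >= 0, bias_1U <= 1, bias_10A >= 0, bias_10A <= 1)
  composition[["noise"]] <- composition[["noise"]] + max(0, 1 - sum(composition))
  structure(as.list(environment()), class = "srna_sim_params")
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rand_seqs <- function(n, len_range, prefix) {
  lens <- if (length(len_range) == 1) rep(len_range, n) else
    sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  tibble(name = sprintf("%s%d", prefix, seq_len(n)),
         seq = vapply(lens, rand_seq, character(1)), length = lens)
}

#' Simulate the reference sequence set
#'
#' Generates random reference sequences for every category and embeds all
#' of them verbatim in the genome contigs (separated by random spacers),
#' so every category-derived read is a genome-mapper with zero
#' mismatches. Deterministic given the parameter seed.
#'
#' @param params An [srna_sim_params()].
#' @return List with tibbles `genome`, `features` (all category
#'   references, [read_fasta()] layout) and `spacers` (the inter-feature
#'   background used for `other` reads).
#' @export
simulate_references <- function(params) {
  stopifnot(inherits(params, "srna_sim_params"))
  withr::with_seed(params$seed, {
    feats <- dplyr::bind_rows(
      dplyr::mutate(rand_seqs(params$n_te, params$te_len, "TE"), category = "TE"),
      dplyr::mutate(rand_seqs(params$n_transcript, params$transcript_len, "TRX"),
                    category = "transcript"),
      dplyr::mutate(rand_seqs(params$n_mirna, params$mirna_len, "MIR"),
                    category = "miRNA"),
      dplyr::mutate(rand_seqs(params$n_rrna, params$rrna_len, "RRNA"),
                    category = "rRNA"),
      dplyr::mutate(rand_seqs(params$n_trna, params$trna_len, "TRNA"),
                    category = "tRNA"),
      dplyr::mutate(rand_seqs(params$n_snrna, params$snrna_len, "SNRNA"),
                    category = "snRNA")
    )
    embed <- feats[sample.int(nrow(feats)), ]
    if (params$duplicate_te) {
      embed <- dplyr::bind_rows(embed, dplyr::filter(feats, .data$name == "TE1"))
    }
    contig_of <- rep(seq_len(params$n_contigs), length.out = nrow(embed))
    spacers <- list()
    genome <- character(params$n_contigs)
    for (ci in seq_len(params$n_contigs)) {
      parts <- character(0)
      for (fi in which(contig_of == ci)) {
        sp <- rand_seq(params$spacer_len)
        spacers[[length(spacers) + 1L]] <- sp
        parts <- c(parts, sp, embed$seq[fi])
      }
      sp <- rand_seq(params$spacer_len)
      spacers[[length(spacers) + 1L]] <- sp
      genome[ci] <- paste(c(parts, sp), collapse = "")
    }
    list(
      genome = tibble(category = "genome",
                      name = sprintf("chr%d", seq_len(params$n_contigs)),
                      seq = genome, length = nchar(genome)),
      features = dplyr::select(feats, "category", "name", "seq", "length"),
      spacers = tibble(name = sprintf("spacer%d", seq_along(spacers)),
                       seq = unlist(spacers),
                       length = nchar(unlist(spacers)))
    )
  })
}

# Draw one 0-based position in [lo, hi] whose genomic base satisfies (or
# avoids) the biased identity; falls back to an unconstrained draw when
# no position qualifies.
draw_biased_pos <- function(seq_chars, lo, hi, base, want) {
  cand <- lo:hi
  ok <- (seq_chars[cand + 1L] == base) == want
  pool <- cand[ok]
  if (!length(pool)) pool <- cand
  pool[sample.int(length(pool), 1L)]
}

#' Simulate reads with a ground-truth manifest
#'
#' Emits the synthetic FASTQ read population from the simulated
#' references: TE-derived siRNA- and piRNA-sized reads (sense and
#' antisense, with planted ping-pong pairs and 1U/10A bias imposed by
#' biased choice of the source position, so reads remain exact genomic
#' matches), full-length mature miRNA reads, transcript and housekeeping
#' RNA fragments, background (`other`) reads from the spacers, and
#' unmappable noise reads (rejection-sampled to have more than 3
#' mismatches against every genomic window). The manifest records the
#' truth for every read.
#'
#' @param params An [srna_sim_params()].
#' @param refs Result of [simulate_references()] under the same params.
#' @return List with `reads` (FASTQ-layout tibble, shuffled order) and
#'   `manifest` (tibble: `read_id`, `category`, `feature`, `strand`,
#'   `start`, `five_prime`, `length`, `pair_id`, `base1`, `base10`).
#' @export
simulate_reads <- function(params, refs) {
  stopifnot(inherits(params, "srna_sim_params"))
  withr::with_seed(params$seed + 1L, {
    comp <- params$composition
    classes <- c("TE", "miRNA", "transcript", "rRNA", "tRNA", "snRNA",
                 "other", "noise")
    n_cls <- diff(round(cumsum(c(0, comp[classes])) * params$n_reads))
    names(n_cls) <- classes
    out <- list()

    te <- dplyr::filter(refs$features, .data$category == "TE")
    te_chars <- lapply(te$seq, function(s) strsplit(s, "")[[1]])
    n_te_reads <- n_cls[["TE"]]
    n_sirna <- round(params$te_sirna_fraction * n_te_reads)
    n_pirna <- n_te_reads - n_sirna
    n_pairs <- floor(params$pingpong_fraction * n_pirna / 2)
    n_free <- n_pirna - 2L * n_pairs
    pw <- params$pirna_window

    # planted ping-pong pairs
    if (n_pairs > 0) {
      pair_rows <- purrr::map(seq_len(n_pairs), function(k) {
        ti <- sample.int(nrow(te), 1L)
        L1 <- sample(pw[1]:pw[2], 1L)
        L2 <- sample(pw[1]:pw[2], 1L)
        lo <- max(0L, L2 - 10L)
        hi <- te$length[ti] - max(L1, 10L)
        p <- draw_biased_pos(te_chars[[ti]], lo, hi, "T",
                             stats::runif(1) < params$bias_1U)
        q <- p + 9L
        sense <- substr(te$seq[ti], p + 1L, p + L1)
        anti <- revcomp(substr(te$seq[ti], q - L2 + 2L, q + 1L))
        tibble(category = "TE", feature = te$name[ti],
               strand = c("+", "-"), start = c(p, q - L2 + 1L),
               five_prime = c(p, q), length = c(L1, L2),
               pair_id = k, seq = c(sense, anti))
      })
      out$pairs <- dplyr::bind_rows(pair_rows)
    }

    # unpaired TE reads (sense with 1U bias, antisense with 10A bias)
    unpaired_te <- function(n, lens, pair_na = NA_integer_) {
      if (n == 0) return(NULL)
      purrr::map(seq_len(n), function(k) {
        ti <- sample.int(nrow(te), 1L)
        L <- if (length(lens) == 1) lens else sample(lens[1]:lens[2], 1L)
        if (stats::runif(1) < 0.5) {
          p <- draw_biased_pos(te_chars[[ti]], 0L, te$length[ti] - L, "T",
                               stats::runif(1) < params$bias_1U)
          tibble(category = "TE", feature = te$name[ti], strand = "+",
                 start = p, five_prime = p, length = L, pair_id = pair_na,
                 seq = substr(te$seq[ti], p + 1L, p + L))
        } else {
          # antisense: read base 10 is the complement of the genomic base
          # 9 nt left of the 5' end, so bias that base
          r <- draw_biased_pos(te_chars[[ti]], L - 10L, te$length[ti] - 10L, "T",
                               stats::runif(1) < params$bias_10A)
          q <- r + 9L
          tibble(category = "TE", feature = te$name[ti], strand = "-",
                 start = q - L + 1L, five_prime = q, length = L,
                 pair_id = pair_na,
                 seq = revcomp(substr(te$seq[ti], q - L + 2L, q + 1L)))
        }
      }) |> dplyr::bind_rows()
    }
    out$free_pirna <- unpaired_te(n_free, pw)
    out$sirna <- unpaired_te(n_sirna, params$sirna_len)

    # fragments from a reference tibble, sense strand, uniform window.
    # Short fragments (~18 nt) can collide with another category's
    # reference within the 3-mismatch category bound by chance, which
    # would make the planted category ambiguous; such draws are rejected
    # against the conflicting references and resampled.
    fragments <- function(src, n, category) {
      if (n == 0 || nrow(src) == 0) return(NULL)
      conflicts <- lapply(
        refs$features$seq[refs$features$category != category], utf8ToInt)
      clean <- function(s) {
        for (q in list(utf8ToInt(s), utf8ToInt(revcomp(s)))) {
          for (ref in conflicts) {
            if (length(scan_windows(q, ref, 3L)$start)) return(FALSE)
          }
        }
        TRUE
      }
      purrr::map(seq_len(n), function(k) {
        repeat {
          i <- sample.int(nrow(src), 1L)
          L <- min(sample(params$length_window[1]:params$length_window[2], 1L),
                   src$length[i])
          p <- sample.int(src$length[i] - L + 1L, 1L) - 1L
          s <- substr(src$seq[i], p + 1L, p + L)
          if (clean(s)) break
        }
        tibble(category = category, feature = src$name[i], strand = "+",
               start = p, five_prime = p, length = L, pair_id = NA_integer_,
               seq = s)
      }) |> dplyr::bind_rows()
    }
    mirna <- dplyr::filter(refs$features, .data$category == "miRNA")
    out$mirna <- if (n_cls[["miRNA"]] > 0) {
      idx <- sample.int(nrow(mirna), n_cls[["miRNA"]], replace = TRUE)
      tibble(category = "miRNA", feature = mirna$name[idx], strand = "+",
             start = 0L, five_prime = 0L, length = mirna$length[idx],
             pair_id = NA_integer_, seq = mirna$seq[idx])
    }
    for (cls in c("transcript", "rRNA", "tRNA", "snRNA")) {
      out[[cls]] <- fragments(
        dplyr::filter(refs$features, .data$category == !!cls), n_cls[[cls]], cls)
    }
    out$other <- fragments(refs$spacers, n_cls[["other"]], "other")

    # noise: rejection-sampled to stay unmappable at up to 3 mismatches
    if (n_cls[["noise"]] > 0) {
      genome_int <- lapply(refs$genome$seq, utf8ToInt)
      noise_seq <- character(n_cls[["noise"]])
      for (k in seq_len(n_cls[["noise"]])) {
        repeat {
          s <- rand_seq(sample(params$length_window[1]:params$length_window[2], 1L))
          hits <- 0L
          for (g in genome_int) {
            for (q in list(utf8ToInt(s), utf8ToInt(revcomp(s)))) {
              hits <- hits + length(scan_windows(q, g, 3L)$start)
            }
          }
          if (hits == 0L) break
        }
        noise_seq[k] <- s
      }
      out$noise <- tibble(category = "noise", feature = NA_character_,
                          strand = NA_character_, start = NA_integer_,
                          five_prime = NA_integer_, length = nchar(noise_seq),
                          pair_id = NA_integer_, seq = noise_seq)
    }

    manifest <- dplyr::bind_rows(out)
    manifest <- manifest[sample.int(nrow(manifest)), ]
    manifest$read_id <- sprintf("r%06d", seq_len(nrow(manifest)))
    manifest$base1 <- substr(manifest$seq, 1, 1)
    manifest$base10 <- substr(manifest$seq, 10, 10)
    reads <- tibble(read_id = manifest$read_id, seq = manifest$seq,
                    qual = strrep("I", manifest$length))
    list(reads = reads,
         manifest = dplyr::select(manifest, "read_id", "category", "feature",
                                  "strand", "start", "five_prime", "length",
                                  "pair_id", "base1", "base10"))
  })
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: references plus reads plus manifest.
#'
#' @param params An [srna_sim_params()].
#' @return List `params`, `refs`, `reads`, `manifest`.
#' @export
srna_simulate <- function(params = srna_sim_params()) {
  refs <- simulate_references(params)
  rd <- simulate_reads(params, refs)
  list(params = params, refs = refs, reads = rd$reads, manifest = rd$manifest)
}

#' Write a simulated dataset to disk
#'
#' Writes the FASTQ, the genome and per-category FASTAs, and the manifest
#' TSV into a directory.
#'
#' @param sim Result of [srna_simulate()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fastq = file.path(dir, "reads.fastq"),
    genome = file.path(dir, "genome.fasta"),
    manifest = file.path(dir, "manifest.tsv")
  )
  write_fastq(sim$reads, paths[["fastq"]])
  write_fasta(sim$refs$genome, paths[["genome"]])
  write_table(sim$manifest, paths[["manifest"]])
  for (cls in unique(sim$refs$features$category)) {
    p <- file.path(dir, paste0(tolower(cls), ".fasta"))
    write_fasta(dplyr::filter(sim$refs$features, .data$category == !!cls), p)
    paths[[cls]] <- p
  }
  invisible(paths)
}

#' Expected overlap spectrum of the planted reads
#'
#' Brute-force expectation from the manifest: for one TE, enumerates all
#' ordered (plus, minus) pairs among the planted reads and counts their
#' 5'-to-5' spans. This is what [overlap_spectrum()] must reproduce on
#' the simulated data (planted pairs plus incidental cross-pairs).
#'
#' @param manifest Manifest tibble from [simulate_reads()].
#' @param feature TE name.
#' @param S Maximum overlap size.
#' @return Tibble `overlap`, `n_pairs`.
#' @export
manifest_spectrum <- function(manifest, feature, S = 23L) {
  m <- dplyr::filter(manifest, .data$feature == !!feature)
  p5 <- m$five_prime[m$strand == "+"]
  q5 <- m$five_prime[m$strand == "-"]
  counts <- integer(S)
  for (p in p5) {
    s <- q5 - p + 1L
    s <- s[s >= 1L & s <= S]
    if (length(s)) counts <- counts + tabulate(s, nbins = S)
  }
  tibble(overlap = seq_len(S), n_pairs = as.numeric(counts))
}
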