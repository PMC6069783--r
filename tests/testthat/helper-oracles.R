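# Independent oracles used across tests. These deliberately avoid the
# package's internal machinery: character-level window comparison for
# alignment, explicit pair enumeration for the overlap spectrum.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Sliding-window Hamming scan over both strands of every reference.
# N never matches any base.
oracle_align <- function(reads, refs, max_mm) {
  ref_chars <- lapply(refs$seq, function(s) strsplit(s, "")[[1]])
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    L <- nchar(reads$seq[i])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") reads$seq[i] else oracle_revcomp(reads$seq[i])
      qc <- strsplit(q, "")[[1]]
      for (j in seq_len(nrow(refs))) {
        rc <- ref_chars[[j]]
        if (length(rc) < L) next
        for (st in 0:(length(rc) - L)) {
          w <- rc[(st + 1):(st + L)]
          mm <- sum(w != qc | w == "N" | qc == "N")
          if (mm <= max_mm) {
            rows[[length(rows) + 1L]] <- data.frame(
              read_id = reads$read_id[i], ref_name = refs$name[j],
              start = st, strand = strand, mismatches = mm, read_len = L,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    data.frame(read_id = character(0), ref_name = character(0),
               start = integer(0), strand = character(0),
               mismatches = integer(0), read_len = integer(0))
  tibble::as_tibble(out)
}

# Canonical sort so hit sets can be compared as data frames.
sort_hits <- function(h) {
  dplyr::arrange(tibble::as_tibble(h)[, c("read_id", "ref_name", "start",
                                          "strand", "mismatches", "read_len")],
                 read_id, ref_name, start, strand)
}

# Explicit ordered-pair enumeration of the 5'-overlap spectrum.
oracle_spectrum <- function(five_plus, five_minus, S) {
  counts <- numeric(S)
  for (p in five_plus) {
    for (q in five_minus) {
      s <- q - p + 1
      if (s >= 1 && s <= S) counts[s] <- counts[s] + 1
    }
  }
  tibble::tibble(overlap = seq_len(S), n_pairs = counts)
}

empty_te_placements <- function() {
  tibble::tibble(read_id = character(0), ref_name = character(0),
                 start = integer(0), strand = character(0),
                 mismatches = integer(0), read_len = integer(0))
}

random_reads <- function(n, len_range = c(18L, 29L), prefix = "r") {
  pool <- seq(len_range[1], len_range[2])
  lens <- pool[sample.int(length(pool), n, replace = TRUE)]
  tibble::tibble(
    read_id = sprintf("%s%04d", prefix, seq_len(n)),
    seq = vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)),
    qual = strrep("I", lens))
}

random_refs <- function(n, len, prefix = "ref", category = "genome") {
  tibble::tibble(
    category = category,
    name = sprintf("%s%d", prefix, seq_len(n)),
    seq = vapply(rep(len, n), function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)),
    length = rep(len, n))
}

# The standard mixed fixture and its pipeline run, computed once per
# test session and shared across files.
.fixture_cache <- new.env(parent = emptyenv())

standard_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- srna_simulate(srna_sim_params(seed = 101L,
                                                        n_reads = 1200L))
  }
  .fixture_cache$sim
}

standard_run <- function() {
  if (is.null(.fixture_cache$run)) {
    sim <- standard_sim()
    dir <- file.path(tempdir(), "srnakit-standard-sim")
    paths <- write_simulation(sim, dir)
    cfg <- srna_config(paths[["fastq"]], paths[["genome"]], paths[["TE"]],
                       paths[["transcript"]], paths[["miRNA"]],
                       paths[["rRNA"]], paths[["tRNA"]], paths[["snRNA"]])
    .fixture_cache$run <- run_pipeline(cfg)
  }
  .fixture_cache$run
}

# Subgroup expectations derived from the manifest alone.
manifest_expectations <- function(manifest, params = srna_params()) {
  m <- dplyr::filter(manifest, category != "noise")
  bona <- !m$category %in% c("miRNA", "rRNA", "tRNA", "snRNA")
  list(
    category_counts = table(m$category),
    n_mappers = nrow(m),
    bonafide = sum(bona),
    mirna = sum(m$category == "miRNA"),
    sirna = sum(bona & m$length >= params$sirna_min &
                  m$length <= params$sirna_max),
    pirna = sum(bona & m$length >= params$pirna_min &
                  m$length <= params$pirna_max))
}
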