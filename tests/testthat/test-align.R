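test_that("index records L - k + 1 plus-strand seed positions", {
  withr::local_seed(10)
  refs <- random_refs(1, 100)
  idx <- srna_index(refs, 10)
  n_pos <- sum(vapply(ls(idx$map), function(k) nrow(idx$map[[k]]), integer(1)))
  expect_equal(n_pos, 91L)
  expect_error(srna_index(refs[0, ]), "empty")
})

test_that("seed lookup agrees with a naive string scan", {
  withr::local_seed(11)
  refs <- tibble::tibble(category = "genome", name = "rep",
                         seq = strrep("ACGT", 25), length = 100L)
  idx <- srna_index(refs, 12)
  kmer <- "ACGTACGTACGT"
  occ <- idx$map[[kmer]]
  naive <- which(vapply(1:(100 - 12 + 1), function(i)
    substr(refs$seq, i, i + 11) == kmer, logical(1))) - 1L
  expect_equal(sort(occ[, 2]), sort(naive))
})

test_that("planted exact and reverse-complement matches are found", {
  withr::local_seed(12)
  refs <- random_refs(1, 300, prefix = "chr")
  reads <- tibble::tibble(
    read_id = c("fwd", "rev"),
    seq = c(substr(refs$seq, 11, 32),
            oracle_revcomp(substr(refs$seq, 101, 124))),
    qual = strrep("I", c(22, 24)))
  hits <- align_reads(reads, srna_index(refs, 10), max_mm = 0)
  fwd <- hits[hits$read_id == "fwd", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$start, 10L)
  expect_equal(fwd$strand, "+")
  expect_equal(fwd$mismatches, 0L)
  rev <- hits[hits$read_id == "rev", ]
  expect_equal(rev$start, 100L)
  expect_equal(rev$strand, "-")
})

test_that("align matches the brute-force Hamming scan for mm 0..3", {
  withr::local_seed(13)
  genome <- random_refs(1, 2000, prefix = "chr")
  reads <- random_reads(200, c(22L, 22L))
  # plant a mixture: exact, 1-3 mismatches, and reverse-complement copies
  for (i in 1:120) {
    st <- sample.int(2000 - 22, 1)
    s <- substr(genome$seq, st, st + 21)
    nmut <- i %% 4
    if (nmut > 0) {
      pos <- sample.int(22, nmut)
      ch <- strsplit(s, "")[[1]]
      ch[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      s <- paste(ch, collapse = "")
    }
    if (i %% 5 == 0) s <- oracle_revcomp(s)
    reads$seq[i] <- s
  }
  for (mm in 0:3) {
    idx <- srna_index(genome, max(4L, 22L %/% (mm + 1L)))
    expect_equal(sort_hits(align_reads(reads, idx, mm)),
                 sort_hits(oracle_align(reads, genome, mm)),
                 info = paste("max_mm =", mm))
  }
})

test_that("N counts as a mismatch in read and reference", {
  refs <- tibble::tibble(category = "genome", name = "c",
                         seq = paste0(strrep("A", 10), "N", strrep("A", 9)),
                         length = 20L)
  reads <- tibble::tibble(read_id = c("a", "b"),
                          seq = c(strrep("A", 20),
                                  paste0(strrep("A", 5), "N", strrep("A", 14))),
                          qual = strrep("I", 20))
  hits <- align_reads(reads, srna_index(refs, 4), max_mm = 0)
  expect_equal(nrow(hits), 0L)
  hits2 <- align_reads(reads, srna_index(refs, 4), max_mm = 2)
  expect_equal(hits2$mismatches[hits2$read_id == "a"], 1L)  # ref N
  expect_equal(hits2$mismatches[hits2$read_id == "b"], 2L)  # ref N + read N
})

test_that("uniqueness classification partitions reads", {
  withr::local_seed(14)
  # genome with a duplicated locus: reads from it are multi-mappers
  core <- paste(sample(c("A", "C", "G", "T"), 900, replace = TRUE), collapse = "")
  dup <- substr(core, 101, 200)
  genome <- tibble::tibble(category = "genome", name = "chr1",
                           seq = paste0(core, dup), length = 1000L)
  reads <- tibble::tibble(
    read_id = c("dup1", "dup2", "flank", "none"),
    seq = c(substr(core, 110, 131), substr(core, 150, 173),
            substr(core, 501, 522), strrep("T", 22)),
    qual = strrep("I", c(22, 24, 22, 22)))
  hits <- align_reads(reads, srna_index(genome, 10), max_mm = 0)
  u <- classify_uniqueness(hits, reads$read_id)
  expect_equal(u$status[u$read_id == "dup1"], "multi")
  expect_equal(u$status[u$read_id == "dup2"], "multi")
  expect_equal(u$status[u$read_id == "flank"], "unique")
  expect_equal(u$status[u$read_id == "none"], "unmapped")
  expect_equal(sort(unique(u$status)), c("multi", "unique", "unmapped"))
  expect_equal(nrow(u), 4L)
})

test_that("placement policy is deterministic and samples loci uniformly", {
  withr::local_seed(15)
  locus <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  spacer <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  genome <- tibble::tibble(category = "genome", name = "chr1",
                           seq = paste0(locus, spacer, locus),
                           length = 400L)
  n <- 10000L
  starts <- sample.int(100 - 22 + 1, n, replace = TRUE)
  reads <- tibble::tibble(read_id = sprintf("m%05d", 1:n),
                          seq = substring(locus, starts, starts + 21),
                          qual = strrep("I", 22))
  hits <- align_reads(reads, srna_index(genome, 10), max_mm = 0)
  expect_true(all(dplyr::count(hits, read_id)$n == 2L))

  p1 <- place_reads(hits, "random_one", seed = 99)
  p2 <- place_reads(hits, "random_one", seed = 99)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), n)

  # unique read keeps its single hit under any policy
  single <- hits[hits$read_id == "m00001", ][1, ]
  expect_equal(nrow(place_reads(single, "random_one", seed = 1)), 1L)

  # binomial check: share of first locus within 5 sigma of 50%
  first_locus <- sum(p1$start < 100)
  expect_lt(abs(first_locus - n / 2), 5 * sqrt(n * 0.25))

  expect_equal(nrow(place_reads(hits, "all")), nrow(hits))
})

test_that("short reads fall back gracefully", {
  withr::local_seed(16)
  refs <- random_refs(1, 200)
  reads <- tibble::tibble(read_id = "tiny", seq = "ACGTA", qual = "IIIII")
  expect_warning(hits <- align_reads(reads, srna_index(refs, 10), 0),
                 "shorter than seed_len")
  expect_equal(nrow(hits), 0L)
})
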