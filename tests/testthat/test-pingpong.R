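placement <- function(id, start, strand, len = 25L, ref = "TE1") {
  tibble::tibble(read_id = id, ref_name = ref, start = as.integer(start),
                 strand = strand, mismatches = 0L, read_len = as.integer(len))
}

test_that("5' profiles place plus at start and minus at the right end", {
  p <- five_prime_profiles(placement("a", 0, "+"), 100)
  expect_equal(p$plus[1], 1)
  expect_equal(sum(p$plus), 1)
  m <- five_prime_profiles(placement("b", 0, "-"), 100)
  expect_equal(m$minus[25], 1)  # 5' of a 25-nt minus read at start 0 is pos 24
  # random placements equal direct accumulation
  withr::local_seed(40)
  pl <- dplyr::bind_rows(lapply(1:50, function(i)
    placement(paste0("r", i), sample(0:70, 1),
              sample(c("+", "-"), 1), sample(23:29, 1))))
  prof <- five_prime_profiles(pl, 100)
  five <- ifelse(pl$strand == "+", pl$start, pl$start + pl$read_len - 1L)
  for (pos in 0:99) {
    expect_equal(prof$plus[pos + 1], sum(five[pl$strand == "+"] == pos))
    expect_equal(prof$minus[pos + 1], sum(five[pl$strand == "-"] == pos))
  }
})

test_that("overlap spectrum counts 5'-to-5' spans", {
  # plus 5' at 20, minus 5' at 29: the classical 10-nt configuration
  pl <- dplyr::bind_rows(placement("p", 20, "+"),
                         placement("m", 29 - 24, "-"))
  prof <- five_prime_profiles(pl, 100)
  sp <- overlap_spectrum(prof$plus, prof$minus, 23)
  expect_equal(sp$n_pairs[10], 1)
  expect_equal(sum(sp$n_pairs), 1)
  # coincident 5' ends = 1-nt overlap
  pl2 <- dplyr::bind_rows(placement("p", 30, "+"),
                          placement("m", 30 - 24, "-"))
  prof2 <- five_prime_profiles(pl2, 100)
  sp2 <- overlap_spectrum(prof2$plus, prof2$minus, 23)
  expect_equal(sp2$n_pairs[1], 1)
  expect_equal(sum(sp2$n_pairs), 1)
  expect_error(overlap_spectrum(prof2$plus, prof2$minus, 0), "S must be")
})

test_that("spectrum equals brute-force pair enumeration on random data", {
  withr::local_seed(41)
  for (rep in 1:20) {
    L <- 150L
    n <- sample(10:50, 1)
    five_plus <- sample(0:(L - 1), n, replace = TRUE)
    five_minus <- sample(0:(L - 1), n, replace = TRUE)
    plus_prof <- tabulate(five_plus + 1L, nbins = L)
    minus_prof <- tabulate(five_minus + 1L, nbins = L)
    expect_equal(overlap_spectrum(plus_prof, minus_prof, 23),
                 oracle_spectrum(five_plus, five_minus, 23))
  }
})

test_that("z-score statistics use mean = sum/S and upper-tail p", {
  # uniform-except-10 spectrum: mu = 2, sigma = sqrt(22), z = sqrt(22)
  sp <- tibble::tibble(overlap = 1:23, n_pairs = c(rep(1, 9), 24, rep(1, 13)))
  st <- pingpong_stats(sp)
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(506 / 23))
  expect_equal(st$z, sqrt(22))
  expect_equal(st$p, stats::pnorm(sqrt(22), lower.tail = FALSE))
  expect_equal(st$overlap_sum, 46)
  expect_equal(st$ten_sum, 24)
  # degenerate spectrum -> NA
  st0 <- pingpong_stats(tibble::tibble(overlap = 1:23, n_pairs = rep(0, 23)))
  expect_true(is.na(st0$z) && is.na(st0$p))
  # scale invariance of z
  sp2 <- dplyr::mutate(sp, n_pairs = n_pairs * 17)
  expect_equal(pingpong_stats(sp2)$z, st$z)
})

test_that("overlap histogram converts counts to percentages", {
  sp <- tibble::tibble(overlap = 1:23, n_pairs = c(rep(0, 9), 1, rep(0, 13)))
  h <- overlap_histogram(sp)
  expect_equal(h$percent[10], 100)
  u <- overlap_histogram(tibble::tibble(overlap = 1:23, n_pairs = rep(2, 23)))
  expect_equal(u$percent, rep(100 / 23, 23))
  z <- overlap_histogram(tibble::tibble(overlap = 1:23, n_pairs = rep(0, 23)))
  expect_true(all(is.na(z$percent)))
})

test_that("partner lists split reads by 10-nt overlap partnership", {
  pl <- dplyr::bind_rows(
    placement("p1", 20, "+"),            # 5' at 20
    placement("m1", 29 - 24, "-"),       # 5' at 29: partner of p1
    placement("p2", 60, "+"))            # lone
  pls <- partner_lists(pl, 100)
  expect_equal(pls$sense_with, "p1")
  expect_equal(pls$antisense_with, "m1")
  expect_equal(pls$sense_without, "p2")
  expect_equal(pls$antisense_without, character(0))
  # random placements vs explicit pair scan
  withr::local_seed(42)
  pl2 <- dplyr::bind_rows(lapply(1:60, function(i)
    placement(paste0("r", i), sample(0:70, 1), sample(c("+", "-"), 1))))
  pls2 <- partner_lists(pl2, 100)
  five <- ifelse(pl2$strand == "+", pl2$start, pl2$start + pl2$read_len - 1L)
  for (i in seq_len(nrow(pl2))) {
    opp <- pl2$strand != pl2$strand[i]
    expected <- if (pl2$strand[i] == "+") any(five[opp] == five[i] + 9)
                else any(five[opp] == five[i] - 9)
    in_with <- pl2$read_id[i] %in% c(pls2$sense_with, pls2$antisense_with)
    expect_equal(in_with, expected, info = pl2$read_id[i])
  }
  # partition property
  expect_setequal(c(pls2$sense_with, pls2$sense_without),
                  pl2$read_id[pl2$strand == "+"])
})

test_that("summary recomputation reproduces stats from sum, N10 and sigma", {
  sp <- tibble::tibble(overlap = 1:23,
                       n_pairs = c(rep(1, 9), 24, rep(1, 13)))
  st <- pingpong_stats(sp)
  re <- pingpong_stats_from_summary(st$overlap_sum, st$ten_sum, st$sd)
  expect_equal(re$mean, st$mean)
  expect_equal(re$z, st$z)
  expect_equal(re$p, st$p)
})

test_that("per-feature analysis keeps silent features with NA stats", {
  withr::local_seed(43)
  refs <- random_refs(2, 200, prefix = "TE", category = "TE")
  pl <- dplyr::bind_rows(placement("p1", 20, "+"),
                         placement("m1", 29 - 24, "-"))
  pp <- pingpong_analysis(pl, refs, S = 23)
  expect_equal(nrow(pp$stats), 2L)
  expect_true(is.na(pp$stats$z[pp$stats$ID == "TE2"]))
  expect_equal(pp$stats$ten_sum[pp$stats$ID == "TE1"], 1)
  td <- tidy(pp)
  expect_true(all(c("feature", "z", "p") %in% names(td)))
  gl <- glance(pp)
  expect_equal(gl$n_features, 2L)
  expect_equal(gl$n_scored, 1L)
})
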