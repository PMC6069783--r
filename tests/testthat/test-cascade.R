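test_that("length filter is inclusive on both bounds", {
  reads <- tibble::tibble(read_id = sprintf("r%d", 1:4),
                          seq = strrep("A", c(17, 18, 29, 30)),
                          qual = strrep("I", c(17, 18, 29, 30)))
  kept <- filter_by_length(reads, 18, 29)
  expect_equal(nchar(kept$seq), c(18, 29))
  # a wider window (18-32) keeps a 32-nt read
  wide <- filter_by_length(tibble::tibble(read_id = "x", seq = strrep("A", 32),
                                          qual = strrep("I", 32)), 18, 32)
  expect_equal(nrow(wide), 1L)
  # random mix equals the direct filter
  withr::local_seed(20)
  mix <- random_reads(200, c(15L, 35L))
  expect_equal(filter_by_length(mix, 18, 29)$read_id,
               mix$read_id[nchar(mix$seq) >= 18 & nchar(mix$seq) <= 29])
})

make_disjoint_refs <- function() {
  withr::local_seed(21, .local_envir = parent.frame())
  dplyr::bind_rows(
    random_refs(1, 200, prefix = "MIR", category = "miRNA"),
    random_refs(1, 200, prefix = "TEJ", category = "TE"),
    random_refs(1, 200, prefix = "TRX", category = "transcript"),
    random_refs(1, 200, prefix = "RR", category = "rRNA"))
}

test_that("first matching category claims the read; rest are other", {
  refs <- make_disjoint_refs()
  shared <- substr(refs$seq[refs$category == "miRNA"], 1, 22)
  te_refs <- refs$category == "TE"
  # plant the miRNA read inside the TE reference too: order must decide
  refs$seq[te_refs] <- paste0(shared, substr(refs$seq[te_refs], 23, 200))
  reads <- tibble::tibble(
    read_id = c("both", "teonly", "none"),
    seq = c(shared, substr(refs$seq[te_refs], 101, 122), strrep("T", 22)),
    qual = strrep("I", 22))
  a <- categorize(reads, refs, srna_params())
  expect_equal(a$category[a$read_id == "both"], "miRNA")
  expect_equal(a$category[a$read_id == "teonly"], "TE")
  expect_equal(a$category[a$read_id == "none"], "other")
})

test_that("missing reference categories are skipped with zero counts", {
  refs <- make_disjoint_refs()
  refs <- dplyr::filter(refs, !category %in% c("rRNA", "tRNA", "snRNA"))
  reads <- tibble::tibble(read_id = "m1",
                          seq = substr(refs$seq[refs$category == "miRNA"], 1, 22),
                          qual = strrep("I", 22))
  a <- categorize(reads, refs, srna_params())
  counts <- attr(a, "counts")
  expect_equal(counts[["rRNA"]], 0L)
  expect_equal(counts[["miRNA"]], 1L)
})

test_that("reads matching a single category are order-invariant", {
  refs <- make_disjoint_refs()
  reads <- tibble::tibble(
    read_id = c("m", "t", "x", "r"),
    seq = c(substr(refs$seq[refs$category == "miRNA"], 11, 32),
            substr(refs$seq[refs$category == "TE"], 11, 32),
            substr(refs$seq[refs$category == "transcript"], 11, 32),
            substr(refs$seq[refs$category == "rRNA"], 11, 32)),
    qual = strrep("I", 22))
  a1 <- categorize(reads, refs, srna_params())
  a2 <- categorize(reads, refs,
                   srna_params(category_order = c("TE", "transcript", "snRNA",
                                                  "tRNA", "miRNA", "rRNA")))
  expect_equal(a1$category, a2$category)
  expect_error(srna_params(category_order = c("rRNA", "lncRNA")), "unknown")
})

test_that("subgroup extraction follows category and length windows", {
  assignment <- tibble::tibble(
    read_id = c("te21", "oth25", "mir22", "rr20"),
    category = c("TE", "other", "miRNA", "rRNA"))
  attr(assignment, "counts") <- c(miRNA = 1L, rRNA = 1L, tRNA = 0L, snRNA = 0L,
                                  transcript = 0L, TE = 1L, other = 1L)
  reads <- tibble::tibble(read_id = assignment$read_id,
                          seq = strrep("A", c(21, 25, 22, 20)),
                          qual = strrep("I", c(21, 25, 22, 20)))
  sg <- extract_subgroups(assignment, reads, srna_params())
  expect_equal(sg$bonafide, c(TRUE, TRUE, FALSE, FALSE))
  te21 <- sg[sg$read_id == "te21", ]
  expect_true(te21$sirna); expect_false(te21$pirna)
  oth25 <- sg[sg$read_id == "oth25", ]
  expect_true(oth25$bonafide); expect_true(oth25$pirna); expect_false(oth25$sirna)
  expect_false(any(sg$sirna & sg$pirna))  # disjoint windows
})

test_that("narrowing the length window never grows a subgroup", {
  sim <- standard_sim()
  run <- standard_run()
  sg_wide <- extract_subgroups(run$assignment, run$selected,
                               srna_params(pirna_min = 23, pirna_max = 29))
  sg_narrow <- extract_subgroups(run$assignment, run$selected,
                                 srna_params(pirna_min = 24, pirna_max = 28))
  expect_lte(sum(sg_narrow$pirna), sum(sg_wide$pirna))
  expect_equal(sum(sg_narrow$bonafide), sum(sg_wide$bonafide))
})

test_that("pie percentages are count/total and sum to 100", {
  a <- tibble::tibble(read_id = sprintf("r%d", 1:100),
                      category = rep(c("TE", "miRNA", "transcript", "other"),
                                     c(46, 24, 6, 24)))
  attr(a, "counts") <- c(miRNA = 24L, rRNA = 0L, tRNA = 0L, snRNA = 0L,
                         transcript = 6L, TE = 46L, other = 24L)
  pf <- pie_fractions(a)
  expect_equal(pf$percent[pf$category == "TE"], 46)
  expect_equal(pf$percent[pf$category == "miRNA"], 24)
  expect_equal(pf$percent[pf$category == "transcript"], 6)
  expect_equal(sum(pf$percent), 100)
  expect_error(pie_fractions(a[0, ]), "no genome-mapping reads")
})
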