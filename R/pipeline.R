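#' Run configuration
#'
#' Validates paths and parameters for a pipeline run. rRNA, tRNA and
#' snRNA references are optional; the corresponding classification stages
#' are simply skipped when absent.
#'
#' @param fastq Character vector of FASTQ paths (each library is
#'   processed independently with identical parameters).
#' @param genome,te,transcripts,mirna Required reference FASTA paths.
#' @param rrna,trna,snrna Optional reference FASTA paths.
#' @param params An [srna_params()].
#' @param outdir Output directory, or `NULL` to keep results in memory
#'   only.
#' @return A list of class `srna_config`.
#' @export
srna_config <- function(fastq, genome, te, transcripts, mirna,
                        rrna = NULL, trna = NULL, snrna = NULL,
                        params = srna_params(), outdir = NULL) {
  required <- c(fastq, genome, te, transcripts, mirna, rrna, trna, snrna)
  missing <- required[!file.exists(required)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(inherits(params, "srna_params"))
  structure(list(fastq = fastq, genome = genome, te = te,
                 transcripts = transcripts, mirna = mirna, rrna = rrna,
                 trna = trna, snrna = snrna, params = params,
                 outdir = outdir),
            class = "srna_config")
}

load_references <- function(config) {
  refs <- list(
    genome = read_fasta(config$genome, "genome"),
    TE = read_fasta(config$te, "TE"),
    transcript = read_fasta(config$transcripts, "transcript"),
    miRNA = read_fasta(config$mirna, "miRNA")
  )
  if (!is.null(config$rrna)) refs$rRNA <- read_fasta(config$rrna, "rRNA")
  if (!is.null(config$trna)) refs$tRNA <- read_fasta(config$trna, "tRNA")
  if (!is.null(config$snrna)) refs$snRNA <- read_fasta(config$snrna, "snRNA")
  refs
}

subgroup_ids <- function(subgroups, which) {
  subgroups$read_id[subgroups[[which]]]
}

#' Run the full small RNA-seq analysis pipeline
#'
#' Executes, for each input library: length selection, exhaustive genomic
#' alignment with uniqueness classification and deterministic placement,
#' sequential categorization, subgroup extraction, per-feature
#' quantification of every subgroup against the TE and transcript
#' references (plus the miRNA table), mismatch-stratified TE tables,
#' 1U/10A bias, the ping-pong signature of the piRNA subgroup on TEs,
#' the length distribution, the category pie and strand-specific
#' coverage tracks. All randomness flows from
#' `params$placement_seed`; two runs with identical config are
#' bit-identical.
#'
#' @param config An [srna_config()].
#' @return For a single library an `srna_report` list; for several, a
#'   named list of them.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "srna_config"))
  refs <- load_references(config)
  if (length(config$fastq) > 1) {
    out <- lapply(config$fastq, function(fq) {
      run_library(fq, refs, config$params,
                  if (is.null(config$outdir)) NULL else
                    file.path(config$outdir, basename(fq)))
    })
    names(out) <- basename(config$fastq)
    return(out)
  }
  run_library(config$fastq, refs, config$params, config$outdir)
}

run_library <- function(fastq, refs, params, outdir) {
  reads <- read_fastq(fastq)
  selected <- filter_by_length(reads, params$min_len, params$max_len)

  gidx <- srna_index(refs$genome, stage_seed_len(params, params$genome_mm))
  ghits <- align_reads(selected, gidx, params$genome_mm)
  uniqueness <- classify_uniqueness(ghits, selected$read_id)
  gplace <- place_reads(ghits, params$placement_mode, params$placement_seed)
  mappers <- dplyr::filter(selected, .data$read_id %in% unique(ghits$read_id))
  total_mappers <- nrow(mappers)
  total_unique <- sum(uniqueness$status == "unique")

  cat_refs <- dplyr::bind_rows(refs[setdiff(names(refs), "genome")])
  assignment <- categorize(mappers, cat_refs, params)
  pie <- pie_fractions(assignment)
  subgroups <- extract_subgroups(assignment, mappers, params)
  ldist <- length_distribution(gplace)
  subgroup_totals <- c(pirna = sum(subgroups$pirna),
                       mirna = sum(subgroups$mirna),
                       bonafide = sum(subgroups$bonafide))

  # non-exclusive quantification: each subgroup against TEs and transcripts
  te_seed <- stage_seed_len(params, params$te_mm)
  bona_reads <- dplyr::filter(mappers, .data$read_id %in%
                                subgroup_ids(subgroups, "bonafide"))
  mirna_reads <- dplyr::filter(mappers, .data$read_id %in%
                                 subgroup_ids(subgroups, "mirna"))
  hit_sets <- list()
  for (set in c("TE", "transcript")) {
    idx <- srna_index(refs[[set]], te_seed)
    hits <- dplyr::bind_rows(align_reads(bona_reads, idx, params$te_mm),
                             align_reads(mirna_reads, idx, params$te_mm))
    hit_sets[[set]] <- list(
      all_hits = hits,
      placed = place_reads(hits, params$placement_mode, params$placement_seed))
  }
  mirna_idx <- srna_index(refs$miRNA, te_seed)
  mirna_hits <- align_reads(mirna_reads, mirna_idx, params$te_mm)
  mirna_placed <- place_reads(mirna_hits, params$placement_mode,
                              params$placement_seed)

  tables <- list()
  strata <- list()
  for (sg in c("bonafide", "mirna", "sirna", "pirna")) {
    ids <- subgroup_ids(subgroups, sg)
    for (set in c("TE", "transcript")) {
      pl <- dplyr::filter(hit_sets[[set]]$placed, .data$read_id %in% ids)
      tables[[sg]][[set]] <- feature_table(
        pl, mappers, refs[[set]], uniqueness, total_mappers,
        max(total_unique, 1L), subgroup_totals)
    }
    strata[[sg]] <- stratify_te(
      dplyr::filter(hit_sets$TE$placed, .data$read_id %in% ids),
      refs$TE, params$te_mm, uniqueness)
  }
  tables$mirna$miRNA <- feature_table(
    mirna_placed, mappers, refs$miRNA, uniqueness, total_mappers,
    max(total_unique, 1L), subgroup_totals)

  pp_placements <- dplyr::filter(
    hit_sets$TE$placed, .data$read_id %in% subgroup_ids(subgroups, "pirna"))
  pingpong <- pingpong_analysis(pp_placements, refs$TE, S = params$pirna_min)

  bundle <- structure(
    list(params = params, library = basename(fastq),
         totals = tibble(total_reads = nrow(reads),
                         selected = nrow(selected),
                         genome_mappers = total_mappers,
                         genome_unique = total_unique),
         reads = reads, selected = selected, genome_refs = refs$genome,
         te_refs = refs$TE,
         genome_hits = ghits, genome_placements = gplace,
         uniqueness = uniqueness, assignment = assignment, pie = pie,
         subgroups = subgroups, length_distribution = ldist,
         subgroup_totals = subgroup_totals, tables = tables,
         te_strata = strata, te_placements = hit_sets$TE,
         pingpong = pingpong),
    class = "srna_report")
  if (!is.null(outdir)) render_report(bundle, outdir)
  bundle
}

#' @export
print.srna_report <- function(x, ...) {
  cat("<srna_report> library ", x$library, "\n", sep = "")
  print(x$totals)
  invisible(x)
}

#' Tidy the per-category composition of a pipeline run
#'
#' @param x An `srna_report` object.
#' @param ... Unused.
#' @return The pie-fraction tibble (`category`, `count`, `percent`).
#' @exportS3Method generics::tidy
tidy.srna_report <- function(x, ...) x$pie

#' One-row summary of a pipeline run
#'
#' @param x An `srna_report` object.
#' @param ... Unused.
#' @return Tibble with read totals and subgroup sizes.
#' @exportS3Method generics::glance
glance.srna_report <- function(x, ...) {
  dplyr::bind_cols(
    x$totals,
    tibble(bonafide = x$subgroup_totals[["bonafide"]],
           mirna = x$subgroup_totals[["mirna"]],
           pirna = x$subgroup_totals[["pirna"]]))
}

#' Write all report files and the HTML index
#'
#' Writes the tables (TSV), bedgraphs, figures with numeric sidecars and
#' an HTML index page that reports the genome-mapper totals and links
#' every per-subgroup folder.
#'
#' @param bundle An `srna_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Path of the index page, invisibly.
#' @export
render_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "srna_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  w <- function(tab, name) {
    p <- file.path(outdir, name)
    dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
    write_table(tab, p)
    written <<- c(written, p)
    p
  }
  w(bundle$totals, "totals.tsv")
  w(bundle$length_distribution, "length_distribution.tsv")
  w(bundle$pie, "pie_fractions.tsv")
  for (sg in names(bundle$tables)) {
    for (set in names(bundle$tables[[sg]])) {
      w(bundle$tables[[sg]][[set]], file.path(sg, paste0(set, "_counts.tsv")))
    }
    for (stratum in names(bundle$te_strata[[sg]])) {
      w(bundle$te_strata[[sg]][[stratum]],
        file.path(sg, paste0("TE_", stratum, ".tsv")))
    }
  }
  w(pingpong_table(bundle$pingpong), file.path("pirna", "pingpong_stats.tsv"))
  for (f in names(bundle$pingpong$histograms)) {
    w(bundle$pingpong$histograms[[f]],
      file.path("pirna", paste0("overlap_histogram_", f, ".tsv")))
  }

  # genome bedgraphs per subgroup and strand (per-base, raw)
  for (sg in c("bonafide", "mirna", "sirna", "pirna")) {
    ids <- subgroup_ids(bundle$subgroups, sg)
    pl <- dplyr::filter(bundle$genome_placements, .data$read_id %in% ids)
    for (strand in c("+", "-")) {
      tracks <- purrr::map(seq_len(nrow(bundle$genome_refs)), function(i) {
        coverage_track(pl, bundle$genome_refs$name[i],
                       bundle$genome_refs$length[i], strand)
      })
      p <- file.path(outdir, sg, paste0(
        "genome_", ifelse(strand == "+", "plus", "minus"), ".bedgraph"))
      dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
      write_bedgraph(dplyr::bind_rows(tracks), p)
      written <- c(written, p)
    }
  }

  # figures with sidecars
  figs <- c(
    save_figure(plot_length_distribution(bundle$length_distribution),
                bundle$length_distribution, outdir, "fig_length_distribution"),
    save_figure(plot_pie(bundle$pie), bundle$pie, outdir, "fig_pie"),
    if (any(!is.na(bundle$pingpong$stats$z)))
      save_figure(autoplot(bundle$pingpong),
                  tidy(bundle$pingpong), outdir, "fig_pingpong"))
  written <- c(written, figs)

  index <- file.path(outdir, "index.html")
  rel <- substring(written, nchar(outdir) + 2L)
  html <- c(
    "<html><head><title>small RNA-seq report</title></head><body>",
    sprintf("<h1>Library %s</h1>", bundle$library),
    sprintf("<p>Genome-mappers: %d &mdash; genome-unique mappers: %d</p>",
            bundle$totals$genome_mappers, bundle$totals$genome_unique),
    "<ul>",
    sprintf('<li><a href="%s">%s</a></li>', rel, rel),
    "</ul></body></html>")
  writeLines(html, index)
  missing <- written[!file.exists(written)]
  if (length(missing)) {
    stop("report references missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(index)
}
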