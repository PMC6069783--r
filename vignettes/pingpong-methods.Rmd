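---
title: "Classifying small RNA-seq reads and scoring the piRNA ping-pong signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying small RNA-seq reads and scoring the piRNA ping-pong signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnakit)
library(dplyr)
```

## The problem

A single-end small RNA-seq library from an animal germ line is a mixture of
molecule classes: miRNAs (around 22 nt), endogenous siRNAs (21 nt), piRNAs
(23–29 nt), and fragments of housekeeping RNAs (rRNA, tRNA, snRNA). Most
questions about such a library — how much of it is transposon-derived, which
transposable elements (TEs) are targeted, whether piRNAs are being amplified
by the ping-pong cycle — require first assigning every genome-mapping read to
exactly one of these classes, and then quantifying each class against the TE
and transcript annotations. srnakit implements that workflow end to end on
tabular (tibble) data structures, with a deterministic synthetic-data
generator so that every stage is testable without external downloads.

## The classification cascade

Reads are first restricted to a length window (default 18–29 nt, both bounds
inclusive) and aligned to the genome. Genome alignment is exhaustive and
ungapped: every placement on either strand with at most `genome_mm`
substitutions (default 0) is found. Reads with exactly one genomic placement
are *genome-unique mappers*; the all-mapper and unique-mapper totals are the
denominators of all later normalization.

Genome-mapping reads are then tested sequentially against the category
references — by default rRNA, miRNA, tRNA, snRNA, transcripts, TEs — and each
read is claimed by the *first* category it maps to within the category
mismatch bound; only still-unassigned reads proceed to the next reference.
Reads matching nothing are `other`. This order matters only for reads that
match several categories; on reference sets without cross-matching sequence
the assignment is order-invariant (a property the test suite checks by
permuting the order). The relative position of transcripts versus TEs is not
canonical; we default to transcripts first, matching the convention of
listing gene products before repeats, and expose `category_order` as a
parameter.

Four subgroups drive all downstream quantification:

* **bonafide** — genome-mappers minus the miRNA/rRNA/tRNA/snRNA-assigned
  reads (TE-, transcript- and unannotated reads are bonafide);
* **miRNA** — the miRNA-assigned reads;
* **siRNA** — bonafide reads of the siRNA length (default exactly 21 nt);
* **piRNA** — bonafide reads in the piRNA window (default 23–29 nt).

Unlike the exclusive pie assignment, subgroup quantification is
*non-exclusive*: each subgroup is aligned in parallel against the TE and
transcript references with up to `te_mm` (default 3) mismatches.

## The aligner

External short-read mappers report one placement per read and their hit sets
depend on seeding heuristics. For 18–32-nt reads at low mismatch counts an
exhaustive substitution-only matcher is both feasible and provably complete,
so srnakit ships its own: every reference k-mer position is hashed
(`srna_index()`), and a read is placed by pigeonhole seeding — partitioned
into `max_mm + 1` non-overlapping blocks, any placement within the mismatch
bound must contain one exact block, so looking up each block's k-mer prefix
and verifying all candidates by full comparison yields every placement.
`N` never matches any base, in the read or the reference.

Completeness requires `(max_mm + 1) * seed_len <= read length`; the pipeline
therefore chooses a per-stage seed length
`min(seed_len, floor(min_len / (max_mm + 1)))`, never below 4 nt (an 18-nt
read at 3 mismatches uses 4-nt seeds). A read too short even for that falls
back to an exhaustive window scan, so the guarantee holds for any
configuration. The test suite checks the full hit set against an independent
sliding-window Hamming scan on random and planted fixtures for all bounds up
to 3 mismatches.

Multi-mappers are resolved by a seeded placement policy (`place_reads()`):
`random_one` draws uniformly among the minimum-mismatch placements after a
platform-independent (reference, start, strand) sort, emulating the
single-placement reporting of common mappers; `all` keeps every placement
for exhaustive TE density profiles. All randomness flows from one seed, so
two runs of the pipeline are bit-identical.

A SAM import path (`import_alignments()`) accepts alignments from an
external mapper instead; the model stays ungapped, so records with indels or
clipping are skipped with a warning.

## Counting, normalization, and the 1U/10A bias

Per feature and subgroup the package reports raw all-mapper and
genome-unique counts, RPKM, and reads per million of the piRNA, miRNA and
bonafide subgroups. RPKM is `count / ((len/1000) * (mappers/1e6))` with the
genome-mapper total as the all-mapper denominator and the genome-unique
total for unique counts; the per-million-of-subgroup columns provide the
alternative normalizations explicitly, since which denominator a reader
wants depends on the comparison being made. TE tables come in three
mismatch strata — exact (0), all (0..`te_mm`), imperfect (1..`te_mm`) — and
per feature `exact + imperfect = all` always holds.

The 1U/10A columns give, per feature and strand, the percentage of placed
reads whose first base is uridine and whose tenth base is adenine, counted
on the read in its own 5'→3' orientation (these are properties of the RNA
molecule, not of the reference): 1U marks primary piRNAs, 10A marks
ping-pong secondaries. Reads shorter than 10 nt (impossible under default
length windows) are excluded from the 10A denominator, and a strand with no
reads reports `NA` rather than 0.

## The ping-pong signature

Ping-pong amplification produces sense/antisense piRNA pairs whose 5' ends
overlap by exactly 10 nt. On each TE, srnakit accumulates per-position 5'
end counts for each strand (a minus-strand read's 5' end is
`start + read_len - 1`) and computes the overlap spectrum

N_s = Σ_p plus(p) · minus(p + s − 1),  s = 1..S,

i.e. the number of ordered opposite-strand read pairs whose 5'-to-5' span
is s nucleotides, counted with read multiplicity. S is the minimum piRNA
length (default 23). The 10-nt bin is scored against the rest of the
spectrum by a z-score:

* mean μ = (Σ_s N_s) / S;
* σ = the **population** standard deviation of the S counts, 10-nt bin
  included (divide by S, not S−1);
* z = (N_10 − μ)/σ; p = 1 − Φ(z), the one-sided upper tail.

The σ and tail conventions are pinned by an internal-consistency property:
for a spectrum with Σ N = 13, Σ N² = 31 and N_10 = 0, only the population σ
reproduces the reference value 1.01407859040788 (the sample convention gives
≈ 1.0369), and a negative z must map to p > 0.5. Degenerate spectra (σ = 0,
e.g. a TE with no placements) report `NA` rather than being dropped from the
table. Per TE the package also writes the percentage overlap histogram and
the four partner lists (sense/antisense reads with and without a 10-nt
partner).

The spectrum uses the piRNA subgroup's TE placements in the 0..`te_mm`
stratum under the configured placement policy (`random_one` by default;
whether multi-mappers should contribute one or all placements is a genuine
modelling choice, so the `all` policy is available). No collapsing of
identical sequences is applied: every read counts with its multiplicity.

## Coverage tracks

Strand-specific tracks accumulate either full read footprints (`depth`) or
5' ends (`five_prime`), optionally binned. Chromosome profiles are
normalized as binned RPKM — reads per million mappers further divided by the
bin width in kb (default 1 kb bins), which makes the per-bin unit coherent
where a literal per-base RPKM would not be. Bedgraph output is 0-based
half-open, zero runs omitted, adjacent equal values merged; for raw
per-base tracks the bedgraph mass Σ value·width equals the number of aligned
bases, an invariant the tests enforce. Figures (length histogram, category
pie, coverage profiles with plus in blue upward and minus in red downward,
overlap histograms) are rendered with ggplot2, and every figure writes its
numeric series as a TSV sidecar — the sidecar, not the image, is the test
surface.

## The synthetic-data generator

`srna_simulate()` produces a complete study: random reference sequences for
every category embedded verbatim in genome contigs (so category reads are
exact genome-mappers), and a read population with planted composition. The
defaults emulate a TE-dominated germline library: TE reads the largest
class (46%), a miRNA population at 22 nt (24%), transcripts 6%, minor
housekeeping contamination, 8% unannotated background and 5% unmappable
noise, giving the characteristic bimodal length profile (22 nt miRNA peak,
23–29 nt piRNA population). Planted ping-pong pairs place a plus-strand
read with 5' end at p and a minus-strand partner at p + 9 (default
`pingpong_fraction` 0.5 of piRNA-sized TE reads).

Two generator choices deserve note:

* **Bias by position choice, not rewriting.** The 1U/10A biases (default
  0.8) are imposed by choosing the read's source position so that the
  relevant genomic base has the desired identity, rather than rewriting
  read bases. Rewriting would introduce mismatches and silently break the
  zero-mismatch genome-mapping guarantee; position choice yields the same
  binomial expectation with no mismatch budget at all. For planted pairs,
  the antisense partner is the reverse complement of the genomic window, so
  its 10A state is automatically the complement of the sense partner's 1U
  base — exactly the coupling ping-pong biology produces.
* **Ambiguity control.** Noise reads are rejection-sampled until they have
  more than 3 mismatches against every genomic window, and short fragment
  reads (18–20 nt fragments can collide with another category's reference
  at the permissive 3-mismatch category bound by chance) are
  rejection-sampled against the conflicting references. The manifest is
  therefore exactly recoverable: category counts, subgroup sizes and per-TE
  counts from a pipeline run equal the manifest with zero error, and the
  observed 1U/10A percentages match the planted probabilities within
  binomial sampling error.

What the generator does *not* emulate: sequencing errors, quality-score
structure, TE family homology (references are independent random
sequences), and realistic expression dispersion. Passing tests on this data
therefore demonstrate the correctness of the bookkeeping and statistics,
not robustness to divergent TE copies or error-rich reads — with a real
library those effects enter through the mismatch bounds.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on fixtures
of 1200–2200 reads over ~8 kb of genome with 3 TEs; the brute-force
alignment oracle is exercised on 2 kb genomes with up to 3 mismatches, and
the overlap-spectrum oracle on 100 random fixtures of up to 100 reads per
strand. These sizes keep every oracle exhaustive while exercising each code
path (multi-mapping, both strands, all mismatch strata, planted and null
ping-pong signal). Tables are written with shortest-round-trip (≥ 15
significant digit) formatting so normalized columns re-read bit-for-bit;
percentages are plain `100 * count / total` with no rounding before output.

```{r example, eval = FALSE}
sim <- srna_simulate(srna_sim_params(seed = 1))
paths <- write_simulation(sim, "sim")
cfg <- srna_config(paths[["fastq"]], paths[["genome"]], paths[["TE"]],
                   paths[["transcript"]], paths[["miRNA"]],
                   paths[["rRNA"]], paths[["tRNA"]], paths[["snRNA"]],
                   outdir = "report")
run <- run_pipeline(cfg)
tidy(run)            # category composition
tidy(run$pingpong)   # per-TE ping-pong statistics
autoplot(run$pingpong)
```

## Known limitations

* The aligner is substitution-only by design; indel-tolerant mapping of
  divergent TE copies requires importing external alignments via SAM.
* Sequence-identical reads are never collapsed; libraries with extreme PCR
  duplication will show inflated multiplicities in the spectrum.
* The ping-pong p-value is a normal-tail approximation of the spectrum's
  internal dispersion, not a permutation test; use it as a ranking
  statistic rather than a calibrated error rate.
* Category assignment aligns read sequences to category references; it does
  not use genomic interval annotations (GFF), so overlapping annotations on
  the genome are invisible to it.
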