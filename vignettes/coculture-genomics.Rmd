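---
title: "Coculture genomics with cobin: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coculture genomics with cobin: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobin)
```

`cobin` implements the genomics arm of a two-species coculture
adaptive-evolution analysis: deciding which of two cohabiting bacterial
genomes each sequenced read pair came from, estimating the population
frequency of mutations in each species across serial transfers, annotating
their protein consequences, and quantifying species abundance by qPCR. This
vignette explains the models and the choices behind them; it states no
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The competitive assignment model

Cocultures are sequenced as a single DNA pool, so every read pair must be
attributed to one of the two genomes before variants can be called. The
pair is aligned to both genomes and summarized by its score sums `S_A`,
`S_B` (sum of the two mates' local alignment scores; an unmapped mate
contributes 0). The rule is:

* assigned to A if **(i)** it is mapped to A (at least one mate) and
  unmapped to B (both mates), or **(ii)** it is mapped to both and
  `S_B < r · S_A` with ratio threshold `r = 0.80`;
* symmetrically for B;
* otherwise excluded as *ambiguous* — in particular, a pair exactly at the
  threshold or with equal score sums is excluded, since the rule uses a
  strict inequality;
* any pair whose mapping quality in the winning genome falls below 30 is
  excluded as *low_mapq*; pairs unmapped in both genomes as
  *both_unmapped*.

Three readings of the published rule are genuinely open, and all three are
config-exposed in `assignment_config()` / `aligner_config()`:

* *What does "mapped to a genome" mean for rule (ii)?* We let one mapped
  mate suffice, with the unmapped mate contributing 0 to the sum — this
  uses the strict definitions maximally; `rule_ii_mapped = "both"` gives
  the conservative alternative.
* *Which mapq is filtered?* We use the minimum of the two mates' mapqs in
  the winning genome (conservative); `mapq_combine = "mean"` is available.
* *Does a proper-pair flag gate "mapped"?* We treat both-mates-mapped as
  the operative condition and keep the proper-pair flag informational.

The never-both property — no score configuration can satisfy the A-rule and
the B-rule simultaneously when `r ≥ 0.5` — is verified by exhaustive
enumeration in the tests.

Duplicate marking runs *after* assignment, within each assigned genome
(matching the published order of operations): among pairs sharing both
mates' 5′ coordinates and strands the highest-scoring pair is kept and the
rest are excluded as *duplicate*.

## The aligner

The original analysis used an external short-read mapper whose index
parameters (k-mer size 11, step 1) are known but whose scoring is not.
Because the assignment rule consumes score *ratios*, which are robust to
the particular scheme, we fix a BWA-like scheme — match +2, mismatch −3,
gap open −5, gap extend −2 (a gap of length L costs `5 + 2L`) — and expose
all four weights. Reads are seeded by exact k-mer hits on both strands,
hit diagonals are clustered within the DP band (default half-width 16 bp),
and the strongest clusters are extended by a full affine-gap local
(Smith–Waterman) DP over the banded genome window, with traceback for the
CIGAR. Tests pin the reported score to an independent unbanded DP oracle.

Two derived quantities matter downstream:

* **mapped**: a read is mapped only if its best score reaches
  `min_score_frac · match · read_len` (default 0.5, i.e. score 75 for a
  75-bp read). This is what lets rule (i) fire: a read from one species
  aligned to the other genome at ~75% identity almost never reaches half
  the maximal score.
* **mapq surrogate**: `min(60, 2 · (best − second_best))`, 60 with no
  second placement, 0 on an exact tie. The downstream filter only needs a
  monotone measure of placement ambiguity with the conventional 0/30/60
  landmarks; monotonicity in the score gap is tested.

Externally produced SAM (scores in the `AS` tag) can replace the internal
aligner via `read_sam()`, so the pipeline remains usable on real
alignments.

## Pooled variant calling

The experiment follows mutations through a *population* of cells, so the
quantity of interest is the proportion of reads supporting each allele,
not a diploid genotype. The published pipeline obtained this by running a
genotyping caller at ploidy 2 and reading off allele fractions; `cobin`
replaces that with a direct pooled pileup caller, because the frequency is
the object of the analysis. The pileup is CIGAR-aware (M/=/X add base
counts; I is recorded as an insertion anchored on the preceding reference
base; D as an anchored deletion whose spanned columns still count toward
depth). A call requires `depth ≥ 10`, `alt_count ≥ 2` and
`AF ≥ 0.02` — the 2% threshold of the targeted deep-sequencing screen —
and indels longer than 20 bp are not called. Frequencies are fractions
internally, rounded to 3 decimals in calls and reported as half-up-rounded
percentages in formatted output.

Two numerical details:

* **Indel denominators.** A local aligner soft-clips an indel that sits
  within a few bases of a read end, so such reads cannot express the
  event. Indel frequencies therefore use a *spanning depth*: only reads
  extending at least `indel_flank = 4` reference bases on both sides of
  the anchor count, and the same margin is applied to the indel
  observations themselves, keeping numerator and denominator consistent.
  Without this, planted insertion frequencies come back biased by about
  the fraction of edge reads (~1 percentage point under our settings).
* **Left-alignment.** Observed indels are shifted to their leftmost
  equivalent anchor (VCF normalization), so the same event observed in
  homopolymer context aggregates under one key. `normalize_indel()` is
  exported so callers can normalize planted coordinates the same way.
  There is no local reassembly or realignment beyond this.

A residual edge effect remains for SNVs: a mismatch in the last couple of
read bases is soft-clipped, so the carrying read drops out of both the
numerator and the denominator while wild-type edge reads stay — a
composition bias below one percentage point at mid frequencies under our
read length, small against the ±5-point tolerances used in the tests.

## Consequence annotation

Gene models are bacterial single-CDS intervals (no splicing, no UTRs), so
annotation is re-implemented directly rather than wrapping a general tool:
extract the CDS (reverse-complementing minus-strand genes), apply the
variant, translate, compare. SNVs are classified at codon
`ceiling(cds_offset / 3)`; indels with length change not divisible by 3
are frameshifts, others in-frame. For frameshifts the mutant CDS is
translated from the start codon *continuing into downstream genomic
sequence* (a frameshift usually destroys the original stop), and we report
the number of residues differing from wild type from the first changed
codon up to the first mutant stop, plus that stop's codon index — all by
direct translation, no heuristics. Whether such a count should include the
codon containing the indel itself is not standardized; we count from the
first codon whose *translation* differs, which includes the indel codon
exactly when its residue changes. Residues extending past the wild-type
protein's end count as changed. Variants spanning a gene boundary are
classified by the overlapped portion and flagged; a frameshift abolishing
the start codon is flagged `start_lost`. Translation uses the standard
code (residue assignments identical to bacterial table 11); stops render
as `*` and terminate the reported protein, fuzzy codons as `X`.

## qPCR quantification and MIC

A standard curve is ordinary least squares of Cq on log10 template copies
from a dilution series (≥ 3 distinct levels required); amplification
efficiency is `10^(−1/slope) − 1`, so perfect doubling corresponds to
slope `−1/log10(2) ≈ −3.321928` and efficiency 1.0 — the printed six-digit
slope is that closed form rounded. Quantification inverts the curve:
`copies = 10^((Cq − intercept)/slope)`.

Species dominance labels are `round(g/p)` formatted as "N:1" with a
thousands separator. They are computed on **raw 16S gene copies**, without
dividing by the per-genome 16S copy numbers (2 for *G. sulfurreducens*, 4
for *P. aeruginosa*): the published table's self-consistent rows only
reproduce uncorrected (e.g. 2.2E+05 / 6.6E+04 → 3:1; corrected it would be
~6.7:1). Correction is available separately via `quantify()`'s
`cell_estimate`. Several published ratios are inconsistent with their
2-significant-figure inputs (they were evidently computed from unrounded
values); the package reproduces only the consistent rows and documents the
rest rather than "fixing" them.

The MIC of a strictly-decreasing two-fold dilution series is the lowest
concentration with no growth such that all higher concentrations are also
inhibited; growth everywhere yields "> max", growth nowhere yields the
lowest tested level, and a skipped-well pattern (growth above an inhibited
level) is flagged as an anomaly without changing the rule. The assay is
invalid if the positive control fails.

## The read simulator

The simulator generates what the sequencing experiment would produce, with
full truth records. Genomes are random sequences at a target GC with
embedded non-overlapping CDS genes (ATG start, stop-free interior, stop
codon, either strand); a partner genome at a controlled nucleotide
identity comes from independent per-site substitutions
(`diverge_genome()`, default experiments use 25% divergence ≈ 75%
identity, far above the ~20% where assignment accuracy is still tested to
hold). Each species carries haplotype *groups* — sets of variants
inherited together at one population frequency; groups segregate
independently (linkage equilibrium), so two sweeping mutations with
different frequencies live in different groups, and with a single group
the model reduces to wild + one mutant haplotype, matching near-complete
selective sweeps. Read pairs are drawn species-first
(`P(A) = mixture`), then haplotype-group inclusion, then a fragment with
normal insert length (mean 300, sd 60, truncated at the read length) at a
uniform start; 75-bp mates are written 5′→3′ with independent per-base
substitution errors (default 0.002) and constant Phred-30 qualities.
Truth records carry the origin genome, haplotype-group membership, and
mate intervals projected back to wild-genome coordinates.

What it deliberately does **not** model: indel sequencing errors, quality
profiles, GC or coverage bias, chimeras, contamination, and real
homology structure between species (divergence is i.i.d., so there are no
long conserved tracts — real genomes' shared operons would produce more
ambiguous pairs than the simulation shows). Passing tests therefore
demonstrate the correctness of the algorithms under the stated generative
model, not performance guarantees on real libraries. PCR duplicates are
not simulated by default; `duplicate_rate` injects coordinate-identical
pairs only to exercise the duplicate marker.

## Problem sizes, determinism and degenerate inputs

The study-condition checks run at desk scale chosen once: binning accuracy
uses two 50-kb genomes at 75% identity with 20,000 pairs at a 99:1
mixture; frequency-trajectory recovery uses a 5–6-kb dominant genome at
~450× (tests, ±0.05 tolerance at depth ≥ 200) and ~2,500× (acceptance
script, percent-scale reporting) with planted frequencies 0.22/0.98
(insertion) and 0.83/0.99 (SNV); consequence annotation is checked on 500
random coding variants against brute-force translation. At these depths on
kilobase genomes, coincidental coordinate collisions between independent
fragments are common, and keep-best duplicate marking would preferentially
delete lower-scoring indel-carrying pairs — the standard reason duplicate
marking is skipped for high-depth targeted data — so the
frequency-recovery computations run with `dedup = FALSE`; duplicate
marking is validated separately against injected duplicates.

Every stochastic step takes an explicit integer seed and is reproducible
byte-for-byte (FASTQ, truth tables, VCF, assignment tables), which the
tests assert by rerunning identical configurations. Degenerate inputs are
errors with explicit messages rather than silent defaults: impossible gene
packing, reference-allele mismatches at planting, genomes shorter than the
read or insert model, k longer than the genome, CIGARs inconsistent with
read length, mismatched pair ids between the two genomes' alignments,
non-two-fold or non-decreasing MIC series, degenerate standard curves, and
configs providing both reads and a simulate block.

## Interfaces

Stages communicate through files in standard formats — FASTA and GFF3
(`type=CDS`, 1-based inclusive) for genomes, FASTQ (`/1`, `/2`) for reads,
SAM 1.6 with `AS` score tags for alignments, VCF 4.2 with `DP`/`AC`/`AF`
for calls, TSV for the truth table, assignment table and frequency matrix,
JSON for stats and the run manifest — so any stage can be re-run or
replaced independently. `run_pipeline()` orchestrates them under one
output directory with a per-stage structured log of counts in and out; the
exported functions, a YAML config (`read_config_yaml()`), and the
reproduction script `scripts/acceptance.R` are the package's interfaces —
no shell entry point is shipped, since the functions compose naturally in
R.

## Known limitations

* Exactly two genomes; the rule is stated n-ary-ready but v1 does not
  generalize.
* No split/chimeric alignments, no base-quality-aware scoring; quality
  strings are carried, not modeled.
* The pooled caller has no strand-bias or mapping-bias filters; at 2%
  frequency with high error rates it will admit artifacts a production
  caller would flag.
* The frequency–expression report joins proteomics log2 fold changes as
  given; no statistical test of the association is computed.
* Excluded read pairs are dropped entirely; they contribute to no depth
  anywhere downstream.
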