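---
title: "Methods: TSS-anchored mononucleotide repeat density and differential expression"
author: "repeatDensity package"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: TSS-anchored repeat density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatDensity)
```

# The question the pipeline answers

Long mononucleotide adenine/thymine tracts — poly(dA:dT) homopolymers —
near transcription start sites (TSSs) act as cis-regulatory elements:
they resist nucleosome formation and influence promoter activity. The
pipeline in this package asks whether genes that change expression
between two biological states (for example cancer-stem-cell-enriched
spheroids versus parental monolayer cells, or cells treated with a
poly-A peptide nucleic acid versus a scrambled control) carry a
different density of such tracts around their TSSs than genes whose
expression does not change.

Four computational stages implement this:

1. **Repeat scanning** — find every *intact* (perfect, maximal)
   homopolymer A or T run in a genome and keep those of 13–27 bp.
2. **TSS profiling** — around each gene's TSS, lay a window of 200
   contiguous 100-bp bins (bins 1–100 cover 10,000 bp upstream, bins
   101–200 cover 10,000 bp downstream in transcription direction) and
   assign each run's base pairs to bins positionwise.
3. **Expression classification** — per experiment, call each gene
   downregulated (Dn), upregulated (Up) or neutral (Nu) with a
   two-sided pooled-variance Student t-test at an inclusive threshold
   (`p <= 0.05`), then intersect same-direction calls between the two
   experiments and optionally filter the intersection by a stricter
   per-experiment p-value cut.
4. **Density comparison** — compare the per-gene window densities
   (bp/Mbp) of the Dn and Up classes against the Nu class with Student
   t-tests.

A synthetic-data generator produces genomes, annotations and expression
matrices with *planted*, exactly recorded structure, so each stage can
be validated against a known truth table.

# Definitions and conventions

**Intact run.** A maximal stretch of one base: the flanking characters,
where they exist, differ from the run base. A 15-mer inside a 30-mer is
part of that 30-mer, never counted separately. `N` terminates runs and
never belongs to one — ambiguous sequence can therefore never create a
repeat. Runs touching a chromosome end are maximal by construction.

**Length filter.** Runs are kept when `13 <= length <= 27` (both ends
inclusive, configurable). Longer runs are *excluded entirely, not
clipped*: downstream bin sums add full run lengths, and clipping a
31-mer to 27 bp would corrupt that arithmetic.

**Coordinates.** On disk the package speaks the standard formats: BED
(0-based half-open) for runs and annotations, and a 0-based TSV
annotation dialect (`tss` = 0-based TSS position, `gene_end` = 0-based
exclusive end in transcription direction). In memory everything is held
in `GRanges`/`IRanges`, which are 1-based closed — the Bioconductor
convention — with conversion confined to the readers and writers.
Round-trips are exact and tested.

**Window geometry.** For a plus-strand gene with TSS $t$ the window is
$[t - 10{,}000,\; t + 10{,}000)$ split into 200 bins of 100 bp; bin 1
is farthest upstream and the TSS base opens bin 101. For minus-strand
genes "upstream" is to the right on the reference, so bin order runs
right-to-left; bin indices always count in transcription direction.
The intragenic extent is fixed at 10,000 bp regardless of gene length —
bins are defined purely by distance from the TSS; `gene_end` is kept
for validation only.

**Proportional bin assignment.** A run contributes to a bin exactly the
number of its base pairs whose genomic positions fall inside that bin;
a run straddling a boundary therefore splits proportionately, and base
pairs outside the window are dropped. With integer coordinates this is
exact positionwise counting — no fractional base pairs arise. No length
filter is applied at the assignment stage (filtering belongs to the
scanner): a bin containing fully enclosed runs of 12, 13 and 15 bp sums
to 40 bp.

```{r worked-sum}
gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50001, 60000),
                               strand = "+")
S4Vectors::mcols(gene)$gene_id <- "g1"
S4Vectors::mcols(gene)$tss <- 50001L
w <- tssWindows(gene)
bin42 <- w[S4Vectors::mcols(w)$bin == 42]
s <- GenomicRanges::start(bin42)
runs <- GenomicRanges::GRanges("chr1",
  IRanges::IRanges(c(s, s + 20L, s + 40L), width = c(12L, 13L, 15L)))
sum(vapply(1:3, function(i) sum(assignRunToBins(runs[i], w)), numeric(1)))
```

**Density.** Per gene, the whole-window density is
$10^6 \times \sum_i \mathrm{binBp}_i \,/\, \sum_i \mathrm{coveredBp}_i$
in bp/Mbp; per group of genes, the pooled per-bin density is
$10^6 \times \sum_g \mathrm{binBp}_{g,i} / \sum_g \mathrm{coveredBp}_{g,i}$.
Both are computed because published profile curves could plot either;
the per-gene scalar is the primary endpoint for class comparisons.

# Statistical model

**Per-gene differential expression.** Each experiment provides a test
and a control group of replicate log-intensity columns (the emulated
design has 2 replicates per group, so the t-test has 2 degrees of
freedom — surfaced in the output). The test is the plain two-sided
pooled-variance Student t-test; no variance moderation is applied
because the procedure being reproduced uses the unmoderated test, and
no multiple-testing correction is applied because classification is on
raw p-values (BH-adjusted values can be emitted for information). A
zero pooled variance with equal means yields $t=0,\ p=1$; with unequal
means $p=0$ with a degeneracy flag. Thresholds are inclusive
(`p <= alpha`), and Up/Dn/Nu always partition the gene universe.

**Intersection.** Same-direction calls are intersected over the shared
gene universe. An optional hypergeometric upper-tail p-value for the
overlap is provided as an extension (the original intersection
procedure reports a chi-square association table instead; since no
overlap statistic is part of the reproduced results, the simpler exact
test was preferred and is clearly labelled optional). The
both-experiment p-value filter keeps intersection genes with
`p <= p_cut` in *both* experiments.

**Class-vs-neutral density comparison.** The unit of observation is the
gene; the statistic is its whole-window density. The published panels
state "Student's t-test", so the pooled test is the default; Welch's
unequal-variance test is available behind a flag since class variances
can differ under enrichment. An exploratory per-bin table (class vs Nu
t-test per bin, uncorrected) supports plotting and localisation but is
not confirmatory.

## Choices where the procedure was under-specified

* **Strand orientation of the base label.** Whether "A repeats" are
  counted on the reference or the gene's sense strand is not stated.
  Since "upstream" is explicitly transcription-directional, the default
  (`strandMode = "sense"`) treats the base label the same way: for
  minus-strand genes the complementary base is looked up on the
  reference. `strandMode = "reference"` preserves the literal reading.
* **Per-gene scalar for the class comparison.** Whole-window density
  was chosen (one test per panel matches one scalar per gene); the
  per-bin route is provided as exploratory output.
* **Multiple candidate TSSs.** The pipeline requires one TSS per gene
  and leaves transcript selection upstream, where annotation-specific
  knowledge lives.
* **Truncated windows.** Genes whose window loses more than 50% of its
  span to a chromosome end are dropped with a warning (threshold
  configurable); retained genes use the actually covered base pairs as
  the density denominator, so truncation does not bias density
  downward.
* **A worked example vs the filter.** The 12-bp run in the worked
  bin-sum above sits below the 13-bp filter; the assignment stage is
  deliberately filter-agnostic and the example demonstrates summation
  mechanics only. The scanner's inclusive 13–27 window is the filter.

# The synthetic-data generator

The generator emulates the study's inputs at configurable scale. Its
defaults are the emulated design: two experiments with 2 replicates per
group; a 300/1500/300 Dn/Nu/Up class split (the scale of regulated-gene
sets the classification chain produces); run lengths uniform on 13–27
bp; 3 expected background runs per base per 20-kb window (giving
baseline densities of a few thousand bp/Mbp, the order observed around
human TSSs at these lengths); 2-fold enrichment of sense-strand T runs
in Dn windows; replicate noise SD 0.25 on the log scale with a planted
effect of 1.0 log-units (a 4-SD effect — large enough that a
2-replicate design has appreciable but not saturating power); and 70%
of planted Up/Dn genes shared between the two experiments.

Mechanics worth knowing:

* Background sequence is i.i.d. uniform A/C/G/T; any naturally arising
  A/T run reaching the scanner's minimum length is broken by resampled
  C/G bases, so with suppression on the truth table is *exhaustive*:
  the scanner's expected output equals the planted set exactly. A flag
  disables suppression for calibration studies.
* Planted runs receive non-matching flanking bases, guaranteeing
  maximality; placements within a window avoid each other with a 1-bp
  buffer. A `placement` switch puts runs anywhere (`random`), fully
  inside one bin (`binAligned`), or forced across a bin boundary
  (`straddling`) to exercise proportional assignment explicitly.
* After generation the generator re-scans its own genome and stops if
  the scan differs from the truth table (self-check); the verifying
  index is returned so callers need not scan twice.
* Gene windows are spaced so they never overlap; each gene's planted
  runs are unambiguously its own.
* Expression is normal on the log scale, BeadChip-like; heavier tails
  are out of scope. Experiment 2 keeps a configured fraction of
  experiment 1's planted genes and redraws the rest from the neutral
  pool.
* Identical config and seed give byte-identical output bundles; the
  seed is mandatory.

**What passing tests on synthetic data do and do not show.** The
generator does not mimic real chromosome composition (isochores, CpG
islands, repeat families), real probe-level noise, or real
correlation between expression and promoter sequence. Recovery of
planted structure validates the *computation* — coordinates, binning,
conservation, test calibration — not the biological claim; applying the
pipeline to a real genome and real expression matrices is what tests
the claim.

# Numerical and degenerate-input policy

* Run detection works on the byte vector of each chromosome:
  positions of the base are grouped into consecutive stretches, each
  stretch one maximal run. Chromosomes are scanned independently, so
  runs can never merge across records. Validation of the
  `{A,C,G,T,N}` alphabet happens once per load, with the offending
  record and offset named.
* Bin assignment and densities are exact integer/rational arithmetic
  until the final division; group densities guard zero denominators
  (a bin with no covered bp reports 0, and a gene with zero covered
  window is refused upstream).
* Degenerate t-tests (zero pooled variance) are defined explicitly
  rather than left to produce `NaN`; exact mean ties give direction
  `"flat"`/`"equal"`.
* Classes with fewer than two genes are skipped with a warning in
  density comparisons — a t-test is undefined there.
* The t statistic and p-value agree with `stats::t.test(var.equal =
  TRUE)` to 12 significant digits on random inputs (tested); the
  implementation itself is a vectorised textbook formula, so a
  2,000-gene matrix classifies in milliseconds.

# Problem sizes used in the shipped checks

The test suite and acceptance script run the generator at the emulated
design scale where the property being checked demands it (e.g. 50
replicates of a 300-vs-1500-gene enrichment comparison on ~37-Mb
genomes; 200 null-label replicates across ten 300-gene genomes; 100
pure-null expression replicates of 1,000 genes), and at reduced window
extents (1–2 kb) for structural unit tests where geometry, not scale,
is under test. These sizes were chosen so each check has the
statistical resolution its tolerance implies.

# Known limitations

* No microsatellite/dinucleotide or interrupted-repeat detection; G/C
  homopolymers are configurable but unexercised.
* Probe-to-gene collapsing, BeadChip normalisation, and probe QC are
  the user's preprocessing burden: the expression input is assumed
  gene-level and already log-normalised, and is never transformed.
* No Gene Ontology enrichment of the filtered gene lists.
* The per-bin comparison table is uncorrected and exploratory.
* With 2 replicates per group the t-test has 2 df; power at the
  default planted effect is ~50–60%, and real designs of this size
  share that limitation — the pipeline reports df so readers can judge.
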