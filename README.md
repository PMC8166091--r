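# repeatDensity

Links long mononucleotide A/T tracts (poly(dA:dT) homopolymers) near
transcription start sites to differential gene expression between two
biological states — e.g. cancer-stem-cell-enriched spheroids vs
parental cells, or PNA-treated vs scramble-treated spheroids — as a
tested, reusable R pipeline for regulatory genomicists.

The pipeline:

1. **scan** — detect every *intact* (perfect, maximal) A and T
   homopolymer run in a genome FASTA and keep runs of 13–27 bp
   (inclusive; longer runs are excluded, never clipped);
2. **profile** — around each gene's TSS, build 200 contiguous 100-bp
   bins (bins 1–100 = 10 kb upstream, 101–200 = 10 kb downstream in
   transcription direction) and assign run base pairs to bins
   positionwise, so a straddling run contributes to each bin
   proportionately; per-gene repeat density is
   `10^6 * Σ binBp / Σ coveredBp` (bp/Mbp);
3. **classify** — per experiment, call genes Dn / Nu / Up with a
   two-sided pooled-variance Student t-test (test vs control,
   `p ≤ 0.05` inclusive), intersect same-direction calls between two
   experiments, and filter the intersection by a stricter p-value cut
   required in *both* experiments;
4. **compare** — Student t-tests of per-gene window densities, Dn vs
   Nu and Up vs Nu, per base (A, T on the gene's sense strand by
   default).

A first-class synthetic-data generator plants runs and expression
effects with an exact truth table (and verifies its own output by
re-scanning), so every stage is testable against known ground truth.

## Worked example

Simulate a study-scale dataset (2,100 genes, two 2-replicate
experiments, 2-fold T-run enrichment in Dn windows), then run the full
pipeline:

```r
library(repeatDensity)

cfg <- simConfig(seed = 5)              # defaults = emulated study design
emitFixtureBundle(cfg, "demo")          # genome.fa, genes.tsv, expr*.tsv,
                                        # truth.json, config.yaml
runPipeline(validateConfig("demo/config.yaml"), "demo_out",
            baseDir = "demo")
```

`demo_out/report.txt` from this exact run:

```
runs found: 13397
exp1 Dn/Nu/Up: 211/1679/210
exp2 Dn/Nu/Up: 188/1714/198
Dn intersection: 63 | filtered at p <= 0.05 : 63
Up intersection: 61 | filtered at p <= 0.05 : 61
```

13,397 intact 13–27 bp runs were found; each experiment's t-tests call
~210 genes per direction (planted: 300 per direction, recovered with
the ~50–60% power a 2-replicate, 2-df design has); 63 downregulated
genes replicate in both experiments. `demo_out/comparisons.tsv` holds
the density comparisons; the experiment-1 T-repeat rows:

```
experiment base contrast  n_class n_nu  mean_class mean_nu   t      p          direction
exp1       T    Dn-vs-Nu  211     1679  5119.4     3156.4    12.97  6.7e-37    increased
exp1       T    Up-vs-Nu  210     1679  3021.2     3156.4    -0.94  0.349      reduced
```

Genes called Dn carry ~1.6× the T-repeat density of neutral genes
(planted enrichment 2× is diluted by classification errors), strongly
significant; the Up class, where nothing was planted, is flat. Per-gene
profiles, group density curves and per-bin tables are written alongside.

Single stages are exported directly (`scanGenome`, `binProfiles`,
`classifyGenes`, `intersectCalls`, `filterByPvalue`,
`compareDensities`, ...), and `inst/scripts/repeatdensity.R` is a thin
CLI over the same functions (`simulate`, `scan`, `classify`, `run`).

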