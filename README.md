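# invex — inversion-karyotype analysis of testis and liver transcriptomes

`invex` is an R package and analysis workflow for bulk RNA-seq studies of
chromosomal inversion karyotypes, built around the zebra finch Z-chromosome
inversion system: males carry the ancestral arrangement (`AA`), two derived
inversion haplotypes (`BB`; the derived B and C arrangements are analysed
as one class), or the heterokaryotype (`AB`). It is written for
evolutionary genomicists who want the complete chain — from testis
histology to inversion breakpoints — as tested, reusable functions rather
than a one-off script pile.

The pipeline covers:

* **Developmental staging** from histology counts of elongating spermatids
  (ES) and spermatogonia (SP) via the maturation index
  *MI = (ES − SP)/(ES + SP) ∈ [−1, 1]*, with stages pooled into EARLY/LATE
  analysis groups.
* **Karyotype-contrast differential expression** per tissue: prefilter,
  TMM normalization, log-CPM, mean–variance precision weights, weighted
  cell-means fits with empirical-Bayes moderated *t* statistics
  (*t* = β̂ / (s̃√v), df = d₀ + d_g), 6 testis and 3 liver contrasts, and a
  *global* Benjamini–Hochberg rule over the pooled gene × contrast
  p-values at α = 0.05. Every step is cross-checked against edgeR/limma in
  the test suite and agrees to numerical precision.
* **Genomic localisation**: sliding-window hypergeometric enrichment of DE
  genes (4 Mb testis / 8 Mb liver windows, four steps per window,
  FDR 0.01), Yates-corrected χ² tests of chromosome-Z overrepresentation,
  and Z:autosome median-expression ratios.
* **Allele-specific expression**: variant filtering (QUAL ≥ 999,
  INFO/DP ≥ 640, DP ≥ 8, GQ ≥ 10), assignment of A- vs B-haplotype alleles
  from pooled homokaryotype allelic depths, per-gene A-allele proportions
  p_A in heterokaryotypes, and dominance-pattern classification from
  δ = (μ_AB − μ_BB)/(μ_AA − μ_BB).
* **Inversion landscape**: genotype polarization toward AA, segmentation
  of the Z into fixed-difference blocks (smoothed |AF_AA − AF_BB|),
  breakpoint estimation, and pairwise r².
* **A synthetic-data generator** that plants every one of these effects —
  the 32-bird design, cis effects inside three inversion regions on Z,
  trans effects on autosomes, diagnostic SNPs, a tissue-specific
  monoallelic gene, staged histology — with a machine-readable truth
  record, so all operating characteristics are measured in the tests.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic dataset and narrate what they find:

```sh
Rscript analysis/01_simulate.R --seed 1      # writes results/data/
Rscript analysis/02_staging.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_genomic_enrichment.R
Rscript analysis/05_allele_specific.R
Rscript analysis/06_inversion_landscape.R
```

With seed 1 this prints, among other things:

```
simulated 32 birds x 2 tissues; 1600 genes (400 on Z); 149 Z SNPs (36 diagnostic)
agreement with planted stages: 100%
testis: 1597 genes retained by prefilter, 117 DE genes (global BH < .05) across 6 contrasts
testis: DE genes on Z 54 vs expected 29.2, X2 = 26.8 (p = 2.2e-07)
testis: Z:autosome median-logCPM ratio 0.97 .. 1.01 across groups
fixed-difference blocks (bp):
  22356702 27976552
  33205850 40025420
  64061606 68682567
```

Reading these: staging recovers every planted stage from the histology;
the global rule finds ~117 DE genes of which a large excess sits on Z (54
observed against 29.2 expected — the planted cis effects); the Z:autosome
ratio stays at 1, i.e. no chromosome-wide dosage effect was planted or
found; and the three recovered fixed-difference blocks bracket the planted
inversion regions (22.5–27.9, 33.5–39.9, 64.0–68.9 Mb) to within a few
hundred kb. The testis enrichment stage reports merged enriched regions
covering those same three intervals, and the ASE stage shows the planted
tissue-specific gene near p_A ≈ 0.95 in testis but 0.5 in liver while
other genes sit at 0.5 in both.

## Layout

```
R/                 package code: staging, simulation, normalization, DE,
                   enrichment, ASE, landscape, IO + run_pipeline()
analysis/          numbered workflow drivers (thin, narrative)
tests/testthat/    unit, property and acceptance suites
scripts/           acceptance.R
vignettes/         methods vignette: models, assumptions, choices, limits
```
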