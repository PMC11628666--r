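---
title: "Methods: inversion-karyotype analysis of testis and liver transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inversion-karyotype analysis of testis and liver transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invex)
```

## The problem

A large region of the zebra finch Z chromosome segregates as a set of
inversion haplotypes. Individuals carry one of three karyotype classes —
`AA` (ancestral arrangement), `BB` (two derived inversion haplotypes; the
derived B and C arrangements are merged into one class because they behave
as one regulatory unit relative to A), and the heterokaryotype `AB`. The
inversions have pleiotropic effects, most strikingly on sperm phenotypes,
which suggests karyotype-dependent gene regulation in the developing
testis. `invex` implements the full analysis chain for such a study:
developmental staging of juvenile males from testis histology, differential
expression between karyotypes within developmental groups in testis and in
liver, localisation of the differentially expressed (DE) genes along the
genome, allele-specific expression (ASE) read off inversion-diagnostic
SNPs, classification of heterokaryotype dominance patterns, and
delineation of the inversion from the transcriptome-derived genotype
landscape.

Every stage is exercised against a synthetic-data generator that plants all
of these effects with a machine-readable truth record, so the pipeline's
operating characteristics (calibration, sensitivity, false-discovery
behaviour, breakpoint accuracy) are measured rather than assumed.

## Developmental staging

Spermatogonia (`SP`) and elongating spermatids (`ES`) are counted in five
histological sections per bird; the counts are **summed across sections**
before the maturation index

$$MI = \frac{ES - SP}{ES + SP} \in [-1, 1]$$

is computed. Summing (rather than averaging per-section indices) is a
deliberate choice: it weights sections by the evidence they carry and is
stable when individual sections are nearly empty. Stages follow the
histological definitions: *inactive* (no signs of spermatogenesis),
*accelerating I* (spermatocyte division but no elongating spermatids),
*accelerating II* (spermatids visible, $MI \in [-0.7, 0.1]$) and *active*
(spermatids visible, $MI \in (0.1, 0.7]$). The stage windows are printed
without open/closed notation in the histology protocol, so a deterministic
convention is required: the boundary $MI = 0.1$ belongs to *accelerating
II*, making the windows a partition. A bird with spermatids but $MI$
outside $[-0.7, 0.7]$ is flagged unstageable rather than forced into a
class. For the expression design the four stages are pooled into `EARLY`
(inactive, accelerating I) and `LATE` (accelerating II, active), because
per-stage cell sizes (2–3 birds) are too small to model stages separately.

## Differential expression

The expression model follows the standard weighted limma-style chain, each
step implemented from its published definition so that limit behaviours can
be tested directly (the test suite cross-checks every step against the
independent edgeR/limma implementations and they agree to numerical
precision):

1. **Prefilter.** A working copy of the counts floors every entry below 10
   to zero; a gene is kept when at least `min(group size)` samples have a
   working count of 10+ and the working total reaches 320. Downstream
   analysis uses the *original* counts of the kept genes — the floored copy
   exists only to make the membership decision, so scattered shallow counts
   cannot rescue a gene. The exact interaction between the flooring and the
   support rule cannot be recovered verbatim from the protocol's prose;
   this reading is the committed, documented one.
2. **TMM normalization.** Trimmed mean of M-values against the sample whose
   upper-quartile/library-size ratio is closest to the mean of that
   statistic; 30% of M values and 5% of A values trimmed from each tail,
   inverse-variance weights, factors rescaled to geometric mean 1.
3. **log-CPM.** $\log_2((y + 0.5) / (N f + 1) \times 10^6)$ on the
   TMM-scaled library sizes.
4. **Precision weights.** Per-gene residual standard deviations from an
   unweighted cell-means fit; $\sqrt{sd}$ smoothed against mean log-CPM
   with lowess (span 0.5, a fixed default — the protocol does not print
   one); each observation's weight is the predicted trend value at its
   fitted log-CPM to the power $-4$. The smoothing is done on the log-CPM
   abundance scale; with near-equal library sizes this is equivalent to
   smoothing against log-counts up to a shift.
5. **Moderated contrasts.** Weighted least squares on the six
   karyotype-by-stage-group cell means; contrasts are the three pairwise
   karyotype comparisons within `EARLY` and within `LATE` for testis (6
   contrasts) and, for liver — where development has no detectable effect —
   the karyotype comparisons after averaging each karyotype's two
   development cells with **equal weights** (3 contrasts). Equal rather
   than sample-size weighting is flagged as a choice; it makes the liver
   contrast estimate the balanced population quantity rather than the
   design-weighted one. Residual variances are squeezed by empirical
   Bayes: the prior degrees of freedom $d_0$ and prior variance $s_0^2$
   come from closed-form method of moments on $\log s_g^2$, the posterior
   variance is $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and
   the moderated $t = \hat\beta / (\tilde s_g \sqrt{v})$ has $d_0 + d_g$
   degrees of freedom. No robust or trended prior is offered — the smallest
   faithful implementation with testable limits ($d_0 = 0$ reduces to the
   ordinary weighted t; $d_0 = \infty$ squeezes completely).
6. **Global decision rule.** Benjamini–Hochberg is applied to the *pooled*
   vector of all gene-by-contrast p-values with one cutoff (0.05) across
   the whole matrix; a gene is "DE" when significant in at least one
   contrast. BH is the committed interpretation of the global rule; the
   adjustment method is configurable.

A consequence of the global rule worth stating precisely: pooled BH
controls the false-discovery rate *per gene-by-contrast decision*. The
union step ("DE in at least one of six contrasts") concentrates scattered
false decisions onto distinct genes, so the gene-level union list does not
inherit the same bound. The planted-recovery tests therefore measure
sensitivity at the gene level (what fraction of planted genes is found)
and the false-discovery proportion at the decision level (what the
procedure actually controls); under the default study conditions the
decision-level FDP sits at 5–8% and gene-level sensitivity at 99–100%.

DE genes are clustered into expression profiles after standardising each
gene to Z-scores across samples: hierarchical clustering, Euclidean
distance, Ward linkage, tree cut at $k = 10$. The cluster count is the only
quantity fixed by the study design; distance and linkage are this
package's documented choices, picked for determinism and convexity of the
resulting clusters.

## Genomic localisation of DE genes

Chromosomes are tiled with sliding windows — 4 Mb for testis, 8 Mb for
liver (liver's expressed genes are sparser), four steps per window, so the
step is a quarter window and interior positions are covered by four
windows. A gene belongs to a window when its start coordinate falls inside
it; assignment by start is unambiguous for genes spanning window edges.
Each window is tested with the hypergeometric upper tail (its DE count
among its expressed count, drawn from the genome-wide totals), p-values
are BH-adjusted *across all windows*, windows pass at FDR 0.01, and
overlapping significant windows are merged into enriched regions. The
window test is this package's committed implementation; the study protocol
delegated it to a web tool whose internal test is unpublished.

Chromosome-level overrepresentation uses a 1-df goodness-of-fit
chi-squared with Yates continuity correction,
$X^2 = \sum (|O - E| - 0.5)^2/E$ over the Z and autosome cells, with
expectations from the proportions of the full gene annotation ("genome"
background; an expressed-set background is available by passing that
universe instead). The continuity correction makes the test conservative —
null simulations in the test suite reject at ~3.5–4% at nominal 5%, and
the calibration check is run at a DE-list size (200) where the correction
is not the dominant term.

Dosage-compensation effects are probed with the Z:autosome ratio of median
log-CPM per karyotype-by-tissue-by-timepoint group, over retained genes,
with unplaced scaffolds excluded.

## Allele-specific expression

Variant filtering mirrors transcriptome variant calling: sites need
QUAL ≥ 999 and INFO/DP ≥ 640 and must be SNPs; individual genotypes need
DP ≥ 8 and GQ ≥ 10 or they are blanked (their allelic depths too, so a
shallow genotype can never leak into downstream pooling); the merged-tissue
mode additionally drops sites with any missing genotype.

At each SNP inside a Z gene, allelic depths are pooled across the AA
samples and across the BB samples. A SNP is **informative** when one
allele reaches a fraction of at least 0.9 in the AA pool while staying at
or below 0.1 in the BB pool, with both pooled depths at least 20; that
allele is the A-haplotype allele. The original protocol verified
assignments manually; the fixation and depth thresholds formalise that
manual step into a reproducible rule (both configurable; near-fixed rather
than fully fixed SNPs are admitted deliberately, since fully fixed
differences between the homokaryotype classes are rare). Heterokaryotype
samples never influence the assignment.

Per gene and sample, the A-allele proportion is
$p_A = \sum \text{depth}(A) / \sum \text{depth}$ over the gene's
informative SNPs — a depth-weighted aggregate, invariant to how depth is
split across SNPs, flagged undefined at zero depth. Homokaryotypes sit
near 1 (AA) and 0 (BB) up to the fixation leakage; the biologically
interesting signal is the heterokaryotype, where $p_A = 0.5$ is balanced
biallelic expression and the planted tissue-specific case (monoallelic in
testis, balanced in liver) appears as $|p_A^{testis} - p_A^{liver}| > 0.3$.

**Dominance patterns.** For each DE gene the heterokaryotype's position
between the homokaryotypes is scored per development group as
$\delta = (\mu_{AB} - \mu_{BB})/(\mu_{AA} - \mu_{BB})$ on mean log-CPM, so
$\delta = 1$ always means "AB matches AA" regardless of which
homokaryotype is higher. With margin $\tau = 0.25$ the group call is
A-like ($\delta \ge 0.75$), B-like ($\delta \le 0.25$) or intermediate,
and the two group calls combine: (A,A) → `A_dominant`; (B,B) →
`B_dominant`; (intermediate, intermediate) → `intermediate`; any mix of
intermediate with a specific call → `divergent_over_time` (the taxonomy
names the intermediate-to-specific direction; the reverse direction is
also a change of dominance over development and is given the same label);
(A,B) or (B,A) → `switching`. Genes whose homokaryotype separation is
below 1 log2 unit in either group are `unclassified` — $\delta$ is a ratio
and becomes noise when its denominator vanishes.

## Genotype landscape and breakpoints

Genotypes are polarized toward AA: at each SNP the allele carried by the
majority of AA haplotypes is re-coded as dosage 0 (ties keep the reference
allele at 0), which renders the inversion as bands — AA near 0, BB near 2,
heterokaryotypes near 1. Per-SNP differentiation
$d = |AF_{AA} - AF_{BB}|$ is smoothed by a centered moving average over
11 SNPs; candidate blocks are maximal runs with smoothed $d \ge 0.8$.
Because a centered moving average pulls the threshold crossing inward by
roughly half the smoothing window, each candidate's edges are then
expanded outward over contiguous SNPs whose *raw* $d$ also clears the
threshold; the reported boundary is the outermost such SNP extended
half-way to its neighbour. Detection is thus governed by the smoothed
profile (which is what keeps the null false-block rate below 0.05 per
chromosome in the test suite) while delineation reaches SNP resolution
(planted 20 Mb blocks at 0.5 Mb SNP spacing are recovered within 1 Mb on
every seed). The visual delineation used in the original study has no
published quantitative rule; this is the committed surrogate, with both
the window and the threshold configurable.

A pairwise $r^2$ utility (squared Pearson correlation of dosages over
jointly non-missing samples) supports LD inspection inside and outside
blocks; it is deliberately minimal and not a reanalysis of any external
SNP dataset.

## The synthetic-data generator

`simulate_dataset()` emulates the study design: 32 birds in the
karyotype-by-timepoint cells of the published design table (12 AA, 10 AB,
10 BB), each contributing a testis and a liver sample; negative-binomial
counts (dispersion 0.1, baseline means log-uniform on 20–500 — shallow but
realistic bulk RNA-seq coverage at desk scale) with a per-gene
developmental effect in testis (log2 SD 1.0) and none in liver; cis DE
genes confined to the three planted inversion regions on Z (22.5–27.9,
33.5–39.9, 64.0–68.9 Mb, matching the enriched regions the pipeline is
meant to find) with AA-vs-BB effect 2 log2 units and heterokaryotype
positions cycling through the five dominance classes; trans DE genes on
the autosomes at 1.5 log2 units with intermediate heterokaryotypes;
Z-chromosome SNPs at 2/Mb with diagnostic SNPs only inside the regions
(homokaryotype read fractions at the 0.98 fixation level, genotypes fully
karyotype-determined) and background polymorphism elsewhere; Poisson(50)
total depth per SNP and sample with binomial allelic depths; histology
counts drawn to satisfy each planted stage's defining window; and one
automatic tissue-specific ASE case ($p_A$ = 0.95 in testis, 0.5 in liver)
unless the caller plants their own. A focused companion,
`simulate_block_genotypes()`, emits regularly spaced genotype matrices
with one planted fixed-difference block for the landscape operations.

One master seed drives everything; per-component substreams are derived
deterministically from it, so a configuration is a complete description of
its dataset. Configuration errors name the offending field. ASE genes may
not overlap one another — a SNP shared by two genes cannot carry two
allelic proportions — and the generator rejects such configurations
rather than silently letting the later gene win.

What the generator does *not* emulate, and what passing tests therefore do
not show: mappability and reference bias in allelic depths (real AB
$p_A$ values are pulled toward the reference allele), family structure
(the real birds come from a small number of families, which can confound
karyotype contrasts; haplotype sharing is not modelled), allele-specific
expression distorting transcriptome-derived genotypes in heterokaryotypes
(a caveat the landscape stage inherits unchanged), overdispersion of
allelic counts beyond binomial, GC and length biases, and read-level
artefacts. Results on real data additionally depend on alignment and
counting choices that sit upstream of this package's scope.

## Numerical choices and problem sizes

Ties and degenerate inputs: the TMM reference falls back to factor 1 when
no genes survive trimming; zero-variance gene rows get a zero Z-score
profile (they carry no shape information) before clustering; windows with
no DE genes are never "significant" regardless of adjusted p; SNPs with no
genotyped AA sample are dropped (with a record) before polarization;
$r^2$ pairs with a zero-variance SNP are flagged, not computed. The
trigamma inversion inside the moments estimator uses Newton iteration with
the standard asymptotic fallbacks.

The test suite and the analysis scripts run the generator at 1,600–2,000
genes, 32 birds and ~150 Z SNPs — sizes chosen so the full suite completes
in well under a minute while every statistical check (calibration bands,
recovery rates, false-discovery proportions) retains enough resolution to
fail visibly if an implementation detail drifts. The third planted
inversion region (4.9 Mb near the Z terminus) receives only ~10 diagnostic
SNPs at the default density and sits at the resolution limit of an
11-SNP smoothing window; the default-dataset landscape sometimes reports
only the two larger blocks, which is the expected behaviour of the method
at that SNP density, not a defect — the breakpoint-recovery guarantees are
stated, and tested, at 0.5 Mb spacing.
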