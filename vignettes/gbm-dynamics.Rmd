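---
title: "Classifying Dynamic and Stable gene body methylation from read-level CG heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Dynamic and Stable gene body methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmdyn)
```

## The statistic: per-CG methylation heterogeneity

Whole-genome bisulfite and enzymatic methyl-seq libraries are sequenced
from DNA pooled over many cells. After PCR deduplication, each remaining
read at a cytosine is assumed to derive from an independent cell, so the
fraction of methylated reads at a CG,

$$ h = \frac{m}{t}, $$

with $m$ methylated and $t$ total deduplicated reads, estimates the
fraction of *cells* in which that CG is methylated. The two cytosines of a
symmetric CG dinucleotide (forward-strand C at position $p$, reverse-strand
C at $p+1$) report on the same epigenetic state and are pooled into one
site before computing $h$ (`pool_cg_dinucleotides()`). A cytosine whose
partner strand happens to be uncovered still forms a single-strand site:
discarding it would preferentially remove low-coverage sites and bias $h$.

Two assumptions matter here. First, deduplicated reads must really be
independent cells — heavily over-amplified libraries violate this and
compress the apparent heterogeneity. Second, each CG is treated
independently; the package does not phase multiple CGs on one read
(epiallele haplotyping), so within-read concordance is invisible to it.

Genome-wide, $h$ is strongly bimodal: maintenance methylation copies CG
states through DNA replication, so almost every CG is methylated in
essentially none or essentially all cells. Sites are therefore classified
(`classify_site()`) as

* **unmethylated** when $h \le 0.10$,
* **fully methylated** when $h \ge 0.85$,
* **heterogeneous** strictly in between.

Both boundary values leave the heterogeneous class; the classification is a
total step function of $h$ and the three classes partition $[0,1]$. Sites
with fewer than `min_coverage` pooled reads (default 5) are flagged
uncallable rather than classified — with fewer reads than that, the 10%/85%
cutoffs are not meaningful. The cutoffs and the floor are arguments
everywhere they are used.

## Dynamic versus Stable gene body methylation

A **Dynamic GbM** gene is one whose gene-body CGs are heterogeneously
methylated in wild type because a DNA demethylase ("eraser") pathway
continually removes methylation that maintenance methylation rewrites;
knocking the eraser out homogenizes the gene to full methylation. Given a
wild-type and an eraser-mutant methylome, `classify_dynamic()` applies two
cutoffs, both required:

1. at least one hypermethylated DMR (below) overlapping the gene body, and
2. at least 5 gene-body CG dinucleotides (10 CG cytosines) each gaining
   strictly more than 20 percentage points of methylation in the mutant.

The second filter removes genes with only a couple of heterogeneous sites
in an otherwise uniform body. The rule is monotone: adding methylation gain
in the mutant can never un-classify a Dynamic gene.

DMRs (`differential_sites()`, `call_dmrs()`) aggregate differential CGs —
sites covered at ≥ 5 reads in both samples with $|\Delta h| \ge 20$
percentage points — within overlapping 200-bp windows stepping 100 bp. A
window with ≥ 5 same-direction differential sites seeds a region;
overlapping or touching same-direction seeds merge; the merged span is
trimmed to its outermost member dinucleotides, because window-edge spans
would inflate downstream overlap statistics. Windows are anchored on the
step grid; the test suite checks the scan against a naive enumerator over
the same grid. Hyper- and hypomethylated regions are called independently
and never overlap within a direction.

**Stable GbM** genes carry CG-only methylation in essentially all cells.
With no published algorithmic restatement to follow, `classify_stable()`
implements the field-standard construction: a one-sided binomial test per
gene of the number of fully methylated gene-body CG sites against the
genome-wide background fraction of fully methylated sites,
Benjamini–Hochberg corrected across tested genes (q < 0.05), requiring ≥ 10
callable gene-body sites and gene-body CHG and CHH methylation ≤ 1% each
(the signature of de novo/TE-like methylation rather than GbM). A
user-supplied stable gene list can replace the test when an externally
defined set should be reproduced exactly. Genes classified both Dynamic and
Stable stay visible in the Venn summary but are placed on an exclusion list
that the expression comparisons consume (`resolve_overlap()`), keeping the
contrasted sets disjoint.

## Conversion QC

Both conversion chemistries leave a small fraction of unmethylated
cytosines reading as methylated. The chloroplast genome is endogenous,
unmethylated, and sequenced in every library, so the apparent methylation
fraction over all contexts on the control contig estimates the
non-conversion rate directly; `conversion_qc()` warns when the implied
conversion rate falls below 0.997, the level a well-behaved library should
exceed.

## Conservation, chromatin, and expression plasticity

**Conservation** (`enrichment_vs_random()`): homologs of the Dynamic set in
a target species are filtered to one-to-one orthologs with ≤ 1% gene-body
non-CG methylation (the two filters commute), then per-gene counts and
per-covered-CG densities of heterogeneous sites are compared against k = 10
random source-gene sets of the same size pushed through the identical
filters. The fold change is the focal per-gene mean over the average of the
k random-set means; the test is a Welch two-tailed t-test of focal genes
against the pooled random genes. Random sets are drawn from all source
genes (minus the focal set, by default); drawing before filtering means the
post-filter sizes vary, and both sizes are reported.

**Chromatin** (`normalize_track()`, `feature_enrichment()`,
`state_overlap()`): per-position coverage is expressed as
$\log_2((d+\varepsilon)/(\bar d+\varepsilon))$ against the genome-wide mean
depth, with pseudocount $\varepsilon = 0.5$ so zero-depth positions stay
finite. Enrichment is averaged per feature (bp-weighted within the
feature), then summarized per feature set with pairwise Cohen's d
(pooled-sd standardized mean difference) — averaging per feature rather
than per base weights every exon equally regardless of length, which is
the intended unit of the comparison. `length_binned_enrichment()` repeats
the contrast within gene-length bins to separate class effects from length
effects. `state_overlap()` intersects gene-body sets with a chromatin-state
partition (validated as non-overlapping) and reports per-state base pairs
and percentages of each set's total bp, which sum to 100 when the states
cover the genome.

**Plasticity** (`plasticity_stats()`): for each gene, across conditions
(replicates averaged per condition first), the coefficient of variation
$\sigma/\mu$ and the Fano factor $\sigma^2/\mu$. CV overstates variability
of lowly expressed genes and Fano of highly expressed ones, so a robust
class contrast should hold under both; the package computes both on linear
(count-like) expression values, where the Fano factor has its Poisson
calibration (Fano = 1). Zero-mean genes are flagged and counted, not
divided by.

**Decile dynamic range** (`decile_dynamic_range()`): decile edges come from
the wild-type genome-wide distribution of one focal condition; the report
shows what proportion of a gene set falls in each decile per genotype —
canalized genes vacate the extremes. The per-genotype spread is the
standard deviation of per-gene mean-centered cross-condition deviations
pooled over the set. This is exactly the quantity an affine shrinkage of a
gene's profile toward its own mean scales: if the mutant is
$\mu_g + f\,(x_{gc}-\mu_g)$, the ratio of the two sds estimates $f$
directly, independent of between-gene mean differences. Equality of the two
variances is tested with the classical two-tailed variance-ratio F-test on
those centered pools, using $G(C-1)$ degrees of freedom per genotype ($G$
genes, $C$ conditions) — per-gene centering costs one df per gene, and
using $GC-1$ instead would make the test slightly anticonservative.

**Tissue-specificity regression** (`tissue_specificity_regression()`): with
$r_g = \log_2(\text{focal}/\text{mean of other conditions})$ in wild type
and $y_g = \log_2(\text{mutant}/\text{WT})$ in the focal condition, loss of
plasticity collapses the mutant toward the cross-tissue mean, predicting a
negative slope of $y$ on $r$ — exactly $-1$, with $r = -1$, when the mutant
sits at the cross-tissue mean on noiseless input (the package's mean
aggregation of "other conditions" and mutant/WT contrast orientation make
this an algebraic identity). The mean is the default aggregation; a median
flag exists because the choice is not forced. Genes with zero coverage in
either genotype are excluded before fitting; a zero-variance response is
reported as slope 0, $R^2$ 0 rather than leaving `lm()` to produce an
unstable perfect fit.

`intergenic_control()` runs the CV/Fano comparison for genes whose only DMR
association is a 2-kb flank (strand-aware, from `associate_dmrs()`). If
elevated plasticity were a side effect of demethylase activity nearby
rather than of gene-body targeting, these flank-only genes would show it
too; the control compares them against all genes.

## What the synthetic generator emulates — and what it does not

`sim_config()` fixes the full parameterization; every generator is
deterministic given the seed. Defaults, chosen once as the study
conditions:

| parameter | default | rationale |
|---|---|---|
| genes per epigenotype | 100 stable / 100 dynamic / 100 unmethylated | ~300 genes: large enough for stable per-class statistics, minutes-scale on one CPU |
| CG dinucleotides per gene | 10–30 | at least the 10 sites the Stable test requires |
| per-cell methylation (WT/mutant) | stable 0.95/0.95, dynamic 0.50/0.95, unmethylated 0.01/0.01 | dynamic sits mid-band in WT and homogenizes in the eraser mutant |
| coverage | Poisson, mean 30 per pooled site | typical modern WGBS/EM-seq depth; Poisson rather than uniform so coverage floors are actually exercised |
| non-conversion rate | 0.003 | matches the >99.7% conversion a good library achieves |
| non-CG cytosines per gene | 100, per-cell rate 0.001 | H-context cytosines outnumber CGs in real gene bodies; this density keeps the per-gene non-CG fraction estimate stable against sampling noise |
| intergenic CGs | 400 per contig, 25% fully methylated | a bimodal genomic background so the Stable test's background rate is non-trivial |
| conditions | 12 | a small multi-tissue panel |
| condition-deviation sd | dynamic 30, unmethylated 15, stable 8 (mean 200) | dynamic > total > stable variability at matched means |
| canalization factor | 0.7 | the mutant's dynamic-gene spread shrinks to 70% |
| genome | 2 × ~500 kb contigs + 10 kb control contig | desk-scale |

Reads are sampled per site as independent cells: methylated with the
epigenotype's per-cell probability, then flipped to apparent-methylated
with the non-conversion probability if unmethylated; both strands of every
dinucleotide are emitted. The control contig is truly unmethylated.

The expression generator emits **two** mutant matrices, because the two
downstream analyses assume different sampling structures. `mut` redraws the
condition deviations (scaled by the canalization factor for Dynamic genes):
the genotypes are then independent replicates of the same law, which is
what a two-sample variance-ratio test assumes — at factor 1.0 the F-test's
type-I rate is the nominal 5%. `mut_paired` scales the *same* deviations
the wild type realized, emulating matched samples whose biological
condition effect is shared between genotypes: this is what the
tissue-specificity regression assumes, and with an independently redrawn
mutant every gene class — not just the canalized one — would show an
inverse slope purely by regression to the mean. Each consumer uses the
variant whose assumptions it satisfies; conflating them produces either a
conservative F-test or an artifactual regression.

Features of real data the generator deliberately omits: read-level linkage
of adjacent CGs (no epiallele phasing), realistic sequence composition,
transposon/repeat methylation, mapping artifacts, batch effects between
libraries, and count-distribution details of RNA-seq (expression is
Gaussian around class means, truncated at zero). Passing tests therefore
demonstrate that the statistics recover the generating parameters under
the stated model — not that the model captures every property of real
libraries.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; cytosine reports are
  1-based (mapper convention); conversion happens at the I/O boundary only.
* A dinucleotide belongs to a gene iff its forward-strand C lies in the
  gene interval — unambiguous for boundary-straddling dinucleotides.
* The DMR differential threshold is ≥ 20 pp while the Dynamic gain filter
  is strictly > 20 pp, each as stated for its step.
* Ties at decile edges follow `cut()` right-closed binning of the
  wild-type quantile grid.
* Empty inputs return empty, typed results (empty methylome, empty DMR
  table); genes with no callable sites are flagged `no_data`/untestable
  rather than silently classified; single-gene sets in the decile analysis
  are flagged degenerate; a k = 1 conservation baseline is flagged
  low-confidence.
* Background rate for the Stable test is clamped away from 0/1 before the
  binomial tail is computed.

## Problem sizes in the test suite

The unit suite runs reduced conditions (25 genes per class) for speed; the
end-to-end property checks run the default 300-gene conditions, 200 random
DMR instances against the brute-force enumerator, 100 expression
simulations for the F-test calibration, and the full pipeline twice for
bit-identity — a few minutes in total on one core. `scripts/acceptance.R`
re-runs the default conditions from scratch and writes every reported
quantity as JSON.

## Known limitations

Replicate-aware DMR testing is not implemented: replicate libraries are
pooled by summing counts per position, matching the threshold-aggregation
design rather than a hypothesis-testing one. The Stable-test background
rate treats all callable CGs genome-wide as exchangeable; a
composition-matched background (e.g. genic-only) would shift q-values
slightly. Homolog discovery is an input, not a computation. Divergence-time
estimation, peak calling, chromatin-state learning, differential-expression
inference, and GO enrichment are out of scope; externally computed tables
for these slot in where the corresponding arguments accept them.
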