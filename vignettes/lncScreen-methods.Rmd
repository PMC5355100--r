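---
title: "Methods: paired lncRNA biomarker discovery and panel evaluation"
author: "lncScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired lncRNA biomarker discovery and panel evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncScreen)
```

# The problem

Early-stage lung squamous cell carcinoma (LSCC) is usually diagnosed too
late for curative resection, and established protein markers lack the
sensitivity and specificity needed for screening. One discovery design for
transcript biomarkers profiles a small number of paired tumor/adjacent
nontumorous (NT) tissue samples on a combined lncRNA + mRNA microarray,
funnels the differential probes down to a qPCR-validatable shortlist, and
evaluates the validated markers — singly and as a combined panel — by ROC
analysis on independent training and validation cohorts. `lncScreen`
implements that funnel as a reusable, fully tested pipeline, together with
a synthetic-data generator so every stage can be exercised against planted
ground truth.

# The pipeline, stage by stage

## Normalization and paired differential expression

Intensities are quantile-normalized (each column's sorted values replaced
by the row-wise mean of sorted columns, ranks preserved; the operation is
idempotent). The per-probe effect estimate is the **mean of per-pair log2
ratios**, `mean(log2((T_i + c)/(N_i + c)))` with pseudocount `c = 1`; the
mean-of-ratios form respects the paired design, while a ratio-of-means
estimator would let a single intense pair dominate. Significance comes
from a two-tailed Student t-test on `log2(intensity + 1)` — pooled
equal-variance by default, with a paired mode available since the samples
are paired — followed by Benjamini–Hochberg step-up adjustment, applied
within the lncRNA and mRNA probe sets separately (the two lists are
reported separately; a joint mode is available). A probe is called
differential by the strict volcano rule: fold change **> 2.0** and FDR
**< 0.05** (a probe exactly on either line is excluded). Degenerate
zero-variance probes receive p = 1 with a warning rather than NaN, keeping
the pipeline total; thresholds ≥ 1 disable the FDR filter so the funnel
can be run wide open.

## Positional lncRNA–gene association

lncRNAs are associated with coding genes by genomic position, not by
expression correlation. On 0-based half-open interchange coordinates
(1-based closed internally, via `GenomicRanges`): overlapping intervals on
the same strand are `sense_overlap`, refined to `intronic_sense` when the
lncRNA lies strictly inside the gene; overlap on opposite strands is
`antisense_overlap`; disjoint intervals on one chromosome with a gap
strictly below 300 kb are neighbors, split into `enhancer_like_neighbor`
versus `intergenic_neighbor` by the array annotation's lncRNA class (that
distinction is a vendor-annotation property, not derivable from
coordinates). The co-expression summary then reports, per relation class,
how many association links have both ends differential and what fraction
changes in the same direction. When a lncRNA has several partner genes,
every link is counted as its own pair.

## Gene-set over-representation

Enrichment of the differential mRNA list against arbitrary gene-set
collections (GMT files) uses the exact upper-tail hypergeometric
probability `P[X >= x]`, including the observed overlap — the standard
over-representation convention. Sets are called enriched at raw p < 0.05
(strict); no multiple-testing correction is applied by default because a
raw cutoff is the convention this pipeline mirrors, but BH adjustment is
one argument away. Curated GO/KEGG databases are deliberately out of
scope; collections are user-supplied files.

## Candidate selection on raw intensities

The qPCR shortlist statistic works on **raw** intensities (the scale on
which hybridization quality is judged), even though the differential list
comes from normalized data. For each differential lncRNA with tumor mean
\(\bar T\), normal mean \(\bar N\), and \(A = |\bar T - \bar N|\): the
probe is a candidate when every raw intensity falls inside the working
gate (inclusive [100, 20000] — "between" is read inclusively, and the gate
is configurable) and **either** group's range (max − min) is strictly
smaller than \(A/10\). The OR reading means one tightly clustered group
suffices; a stricter AND mode is provided. The rule is scale-equivariant
(A and the ranges scale together) and monotone in within-group spread.
The gate is applied per sample, not per group mean. Output is ordered by
descending A, the natural priority for qPCR follow-up.

## 2^−ΔΔCp quantification

Replicate crossing points are averaged on the Cp scale (the convention of
the relative-quantification literature), then
\(\Delta Cp = Cp_{target} - Cp_{reference}\) within each sample and
\(\Delta\Delta Cp = \Delta Cp_{sample} - \Delta Cp_{calibrator}\), with
relative expression \(2^{-\Delta\Delta Cp}\) at fixed amplification
efficiency 2. Two calibrators are shipped because group-level summaries
do not pin the choice down: the sample's **paired normal** (default;
faithful to the paired design, but it collapses every normal sample to
exactly 1) and the **mean ΔCp of all normals** (keeps variation among
normals, hence what the ROC stage uses; its normal relative expressions
have geometric mean 1). ΔCp is invariant to sample-wide Cp shifts, so
differences in input RNA amount cancel by construction.

## ROC and the combined panel

Single-marker AUC is the Mann–Whitney estimate with midrank ties, its
standard error the Hanley–McNeil formula with \(Q_1 = A/(2-A)\),
\(Q_2 = 2A^2/(1+A)\), and the operating point the Youden-optimal observed
cutoff (rule: score ≥ threshold calls tumor; ties in J broken toward the
higher-specificity, i.e. larger, threshold). The **combination rule for
the panel is not standardized anywhere**, so the package adopts the
conventional choice: binary logistic regression of class on the marker
values, fit by iteratively reweighted least squares with a ridge penalty
of 1e-6 on the slopes so perfectly separable data still converge
deterministically; the panel score is the linear predictor, whose ROC is
identical to that of the fitted probability. The panel is always fit on
the training cohort only and frozen before scoring a validation cohort.

A closed-form **binormal AUC**,
\(\Phi\!\big((\mu_+-\mu_-)/\sqrt{\sigma_-^2+\sigma_+^2}\big)\), is
provided as a desk approximation for the common situation where only
group means and SDs are published. On the shipped reference summaries of
a five-lncRNA LSCC panel (`lsccPanelSummary()`), it reproduces the
reported empirical AUCs within their reported SEs (±0.05) for nine of ten
cohort × marker rows; the exception (validation-set ENST00000441841,
whose NT SD exceeds its mean, i.e. strongly right-skewed relative
expression) deviates by ~0.075 — a known limit of the normal
approximation for skewed 2^−ΔΔCp values, which the tests document rather
than hide.

# The synthetic-data generator

`simulateExpression()` draws log2 intensities as
`baseline + pairEffect + isTumor * log2fc + noise`, exponentiates, and
clips at 1 so logs stay defined. Defaults emulate the discovery design
this pipeline targets: **3 tumor/normal pairs**, probe baselines
N(10, 1.5²) on the log2 scale (intensities centred near 1,000, mostly
inside the 100–20,000 candidate gate), a per-probe per-pair subject
effect with SD 0.25 shared by the two samples of a pair, residual noise
SD 0.3, 10% of probes differential with |log2FC| drawn from [1, 3]. The
paper-style design fixes the cohort sizes and thresholds; the variance
components are stated assumptions chosen to look like well-behaved array
data, since no public noise model exists for the original arrays.
Differential probes are a **deterministic count** `round(fracDE * n)` so
count assertions are exact; signs are drawn balanced, then mRNA partners
of co-differential positional links are forced to the lncRNA's direction
so concordance summaries have known truth (this can leave the global
up/down split a few probes off exact balance). Each linked lncRNA–gene
pair is placed on its own pseudo-chromosome with coordinates that realise
the planted relation exactly — neighbor gaps equal the planted distance
to the base. Randomness is two-level: population quantities (baselines,
DE assignment, links) derive from the config seed, while sample-level
draws (pair effects, noise) can be re-seeded independently — that is how
an independent validation cohort is drawn from the *same* population as
the training cohort, which is what makes frozen-coefficient validation
meaningful. Cp tables follow `Cp = c0 − log2(expression) + noise` with a
constant-expression reference gene and triplicate wells.

What the generator does **not** emulate: batch and hybridization-physics
effects, probe-level cross-hybridization, intensity-dependent variance,
skewed (non-log-normal) relative-expression distributions, and dependence
between probes beyond the planted links. Green tests on synthetic data
therefore demonstrate correctness of the statistics and plumbing, not
robustness to every artifact of real arrays.

# Numerical and design choices

- Strict inequalities wherever a threshold is worded as "greater
  than"/"smaller than"; boundary cases are tested explicitly.
- BH via `stats::p.adjust`, t-tests via `stats::t.test`, hypergeometric
  tails via `stats::phyper`, quantile normalization via
  `limma::normalizeQuantiles` — each checked in the test suite against an
  independent brute-force oracle (step-up enumeration, closed-form
  Student formula, full mass enumeration, the sorted-mean definition).
- IRLS convergence: coefficient change < 1e-10 (relative), cap 100
  iterations, error (never a silent fallback) on divergence; constant
  markers dropped with a warning before fitting.
- The pipeline's stages communicate only via plain-text files (TSV / CSV
  / GMT), and `runPipeline()` writes a manifest with parameters, seed,
  per-stage record counts (the discovery funnel) and MD5 checksums;
  reruns with the same configuration reproduce the checksums exactly.
- Problem sizes in the test suite are chosen for tight feedback: oracle
  sweeps use vectors up to length 50 (1,000 replicates), exhaustive AUC
  checks cover class-size products up to 400, end-to-end recovery runs
  use 1,000 probes × 10 pairs, and panel-coefficient recovery uses
  n = 2,000 — sizes at which the checked properties are already sharp.

# Known limitations

- The enhancer-like/intergenic distinction is inherited from annotation,
  so misannotated classes propagate.
- The candidate rule's range statistic is extremely sensitive to single
  outlier samples at larger cohort sizes; it generalises the three-pair
  design it was built for, but users should treat it as a screening
  heuristic, not a test.
- Hanley–McNeil SEs assume independent observations; paired
  tumor/normal scores mildly violate this, so reported SEs are
  approximate.
- The logistic panel is one defensible combination rule among several;
  coefficients are reported so any monotone re-scoring can be applied.
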