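---
title: "Co-expression modules and module-activation classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression modules and module-activation classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`modact` implements a multi-cancer transcriptomic analysis in which the unit
of interest is not the single gene but the *co-expression module*: a group of
genes with a shared expression pattern across samples, presumed to share
regulation or pathway membership. The pipeline runs from a raw
gene-by-library read-count matrix to (i) modules, (ii) per-cancer module
activation profiles with significance calls, (iii) a nearest-centroid
classifier validated by cross-validated ROC analysis, and (iv) ranked
biomarker candidates. This vignette describes the model, every tunable
parameter that matters, the numerical choices made where the design was
open, and what the synthetic-data generator does and does not emulate.

## The data model

The input is a count matrix $C$ with elements $C_{g,s}$ (genes $g$, library
columns $s$) and per-library metadata: subject, cancer label, tumor/normal
condition, and a replicate group tying technical replicate libraries to
their biological sample. Preprocessing applies, in order:

1. **Library-size scaling.** Every column is rescaled to the mean library
   total. Nothing fancier (no trimmed-mean or median-of-ratios size
   factors) is intended: the replicates come from one protocol and differ
   only slightly in depth, and downstream Z-scaling absorbs residual scale.
2. **Low-count filter.** Keep genes with counts strictly above `min_count`
   (default 25) in at least `min_samples` (default 185) of the libraries —
   with 225 libraries this demands detectable expression in the large
   majority. The threshold pair is exposed as configuration and is *not*
   rescaled automatically for matrices of other widths; callers working
   with other designs should set it explicitly (the analysis scripts use
   80% of the library count when the width differs).
3. **Variance filter.** Keep the top `ceiling(q * n)` genes by count
   variance across libraries ($n-1$ denominator), default $q = 0.5$. Ties
   are broken by input gene order (stable sort) so runs are reproducible.
4. **Homolog filter** (optional). Keep genes present in a supplied
   cross-species homolog map; used when modules must be transferable
   between species. The filter order (homolog, counts, variance) is
   configurable because the composition is order-sensitive; whichever order
   runs is recorded in the result's `steps` attribute.
5. **Replicate averaging.** Arithmetic mean per replicate group; the
   operation is idempotent, and conflicting metadata within a group is an
   error rather than a silent collapse.
6. **Z-scaling.** Each sample column is centered and scaled by its own
   mean and standard deviation across genes:
   $$Z_{g,s} = \frac{C_{g,s} - \langle C\rangle_s}{\sigma_s}.$$
   $\sigma_s$ is read as the within-sample standard deviation of counts
   across genes, which is what makes columns strictly mean-0/SD-1. A value
   of, say, 7 therefore means "seven background standard deviations above
   this sample's average gene" — an absolute activation with 0 as
   reference. Because counts are non-negative and right-skewed, the Z
   distribution has a hard negative floor and a long positive tail; most
   genes sit slightly below 0 and active genes splay far positive.

## Module discovery

**Seeding.** Gene rows are clustered hierarchically with
$1 - \text{Pearson}$ correlation distance and average linkage, and the
dendrogram is cut at the level producing the most clusters whose sizes lie
strictly inside `(min_size, max_size)` (default $(10, 100)$ — roughly the
gene count of a curated pathway). Out-of-bounds clusters at that cut are
discarded rather than re-cut. When several cut levels tie on the count,
the smallest cut height (largest number of clusters) wins; this is purely
a determinism rule — seeds need not be perfect because refinement sharpens
them.

**Randomized expansion.** Each base seed is replicated `n_repeats` times,
each replicate unioned with `n_random` (default 100) genes drawn uniformly
without replacement. Duplicates inside a seed are impossible by the set
semantics. Randomizing starting points lets refinement explore many basins
of attraction instead of being locked to one clustering.

**Iterative signature refinement.** From each seed the algorithm
alternates until a fixed point:

* *sample scoring*: score every sample by the mean expression of the
  current gene set; keep samples above the score mean plus
  `sample_threshold` (default 1.0) standard deviations;
* *gene scoring*: score every gene by its mean expression over the kept
  samples, computed on a per-gene standardized copy of the matrix (the
  usual dual normalization — the input is column-standardized, gene
  scoring also row-standardizes); keep genes above the score mean plus
  `gene_threshold` (default 2.0) standard deviations.

Convergence demands consecutive gene sets with Jaccard overlap at least
$1 - \texttt{convergence\_tol}$; the default tolerance 0 demands an exact
fixed point, and `max_iter` (default 100) caps the iteration. Thresholds
sit in the conventional operating range for signature-style biclustering:
a stricter gene threshold than sample threshold keeps modules tight while
letting a cancer group of modest size be selected. Both are configurable;
raising `gene_threshold` can only shrink a converged module.

**Deduplication and the support screen.** Distinct fixed points are merged
by Jaccard closure: any pair with similarity $\ge$ `merge_jaccard`
(default 0.7) is unioned, repeatedly, until no pair qualifies. Each merged
module carries its *seed support* — the fraction of converged seeds whose
fixed point fell into it. Genuine signatures are attractors reached from
many randomized seeds; spurious fixed points of the noise are reached from
isolated ones. Modules with support below `min_support` (default 5%) are
therefore discarded. In the synthetic studies this screen separates
cleanly: planted modules each attract 10–17% of seeds, noise fixed points
at most 1–2 seeds in a thousand; on matrices with no planted structure
nothing survives the screen, which is the desired null behavior. Survivors
are sorted by size, largest first, and renumbered from 1.

## Activation algebra

All activation quantities are means over sub-blocks of $Z$:
$A_{g,s} = Z_{g,s}$ (gene in sample), $A_{g,c}$ (gene averaged over a
cancer's samples), $A_{m,s}$ (module genes averaged in one sample), and
$A_{m,c}$ (module averaged over genes and samples). Averaging per sample
then over samples equals the grand mean of the $|genes| \times |samples|$
sub-block, an identity the tests verify to $10^{-12}$.

**Significance.** Per-sample module activations (or per-sample gene
Z-values) are compared between a cancer's tumors and its matched normals.
Both sides are screened by Shapiro–Wilk at level 0.05; two clean sides get
a two-tailed two-sample t-test, otherwise the Wilcoxon rank-sum test is
used. A fully tied rank-sum comparison (both sides constant and equal) is
reported as $p = 1$. At least 3 observations per side are required — the
Shapiro–Wilk minimum — and a t-test on $n = 3$ normals is permitted but is
exactly as fragile as it sounds; the matched-normal design simply has no
more replication to offer. Raw p-values are Benjamini–Hochberg corrected
*within each cancer's module family* (one family of $N$ module tests per
cancer) and, for gene-level records, within each module's gene family.
Family boundaries are a genuine modeling choice; one global family is
available to callers by correcting the raw p-values themselves.

**Primary module.** For each cancer, the primary module is the most highly
activated module among those with corrected $p < 0.05$; ties break toward
the lower module id; no qualifying module leaves the call `NA`. The
p-values that gate the call are module-level (distributions of per-sample
module activations), not pooled gene-level values.

## Classification

A cancer's *module activation profile* $P_c = \{A_{m,c}\}_{m=1}^N$ places
it at a point in $N$-dimensional module space; those points are the class
centroids. A sample is classified to the centroid minimizing Euclidean
distance
$$D_{c,s} = \sqrt{\sum_{m=1}^N (A_{m,c} - A_{m,s})^2},$$
with exact ties broken lexicographically by label.

**ROC construction.** For one cancer, test samples are ranked by distance
to its centroid (closer = more positive) and a one-vs-rest ROC is traced
by sweeping the distance threshold; tied distances move the curve in a
single diagonal step, which makes the trapezoidal AUC identical to the
Mann–Whitney rank statistic with half-credit for ties (property-tested
against a brute-force pairwise oracle). Sensitivity is reported at the
most liberal curve point whose specificity is still $\ge$ the operating
specificity (default 0.70); linear interpolation between curve points is
deliberately not used — the reported pair is an achieved operating point.

**Cross-validation.** Internal validation repeats `n_trials` times: split
the tumor samples in half at random (stratified by cancer; normals take no
part in classification), fit centroids on the training half, rank the test
half, accumulate one ROC per cancer; metrics are means over trials, and
the whole run is reproducible from one seed. The full protocol
re-discovers modules on each training half; because that multiplies cost
by the full discovery pipeline, a fast path holding modules fixed is
provided and the analysis scripts run 200 fixed-module trials plus 20
full-protocol trials. External validation keeps module genes fixed,
draws training samples from the internal cohort only, uses the external
cohort exclusively as test data, and first puts all cohorts on one scale
by joint quantile normalization (rank-mean with tie averaging, after
intersecting gene sets; module genes missing from a cohort are dropped
from the module for that evaluation, with a warning). Optional background
negatives — samples of cancer types the model was never trained on — are
appended to the test set only; they can only dilute specificity, never
improve training.

## Biomarkers

Candidates are the genes of each cancer's primary module with activation
strictly above 1.5 — approximately the 95% confidence level for a Z score
relative to the per-sample background; the boundary value itself is
excluded. The annotation matrix binarizes externally supplied (or locally
computed hypergeometric) enrichment results at a BH-corrected cutoff and
tallies per-annotation module counts, separating shared from
cancer-specific biology. The novelty screen keeps candidates that are
`Tbio` or `Tdark` in the IDG target development classification, applies
the CTD literature cuts (inference score < 10 and references < 5) to
`Tbio` targets only — `Tdark` targets are essentially unstudied, so
literature cuts would be vacuous — and applies the tumor-vs-normal
p-value criterion only for cancers whose matched normals genuinely share
the tumor's tissue of origin (in the motivating design, the pulmonary
group). Missing CTD fields count as zero (maximally novel) and are
flagged `ctd_imputed` rather than silently filled.

## The synthetic-data generator

`sim_config()` defaults encode the study design the analysis assumes: five
cancer groups (12 tumors + 3 matched normals for three groups, 15 + 3 and
9 + 3 for the lymphomas — 75 samples), three technical replicate libraries
per sample (225 libraries), and five planted modules of sizes
225/204/158/69/161, each elevated at log2 fold 2 in its target cancer's
tumors only. Counts are negative-binomial around a baseline mean of 100
with dispersion 0.1 (variance $\mu + 0.1\mu^2$, mid-range for bulk RNA-seq
replicates), and per-library size factors jitter with CV 0.1. One group's
normals can optionally share the tumor tissue profile at half the log2
fold, mimicking normals sampled from the same organ as the tumor.

What the generator does *not* emulate — and hence what green synthetic
tests cannot show about real data: gene–gene correlation inside the
background (real co-expression is pervasive, not confined to planted
blocks), overlapping modules and genes active in several cancers,
tumor-purity and breed/batch covariates, count distributions with
gene-specific baselines and dispersions, and the long right tail of real
Z matrices (planted activations here reach $\sim$3–9, not 49). The
planted design is deliberately favorable: it answers "does the machinery
recover known structure and calibrate correctly under its own
assumptions", not "how hard is the real problem".

A gene-wise multiplicative log-normal batch distortion
(`apply_batch_effect`) emulates the platform/protocol differences that
separate cohorts; it is what makes the external-validation experiments
degrade realistically (internal $\ge$ external-like $\ge$
background-seeded AUC ordering).

## Problem sizes and runtime choices

The packaged experiments use: full study scale (4000 genes, 225 libraries,
2000 genes after filtering) for module discovery with 20 expansion repeats
per base seed (about 1,100 seeds — supports in the planted setting are so
well separated that hundreds of repeats add nothing but runtime), 200
fixed-module CV trials, 20 full-protocol CV trials, and 20-trial external
experiments; unit tests use 600–1200 gene studies. A full acceptance run
completes in under a minute on one CPU.

## Known limitations

* The support screen's 5% default presumes many randomized seeds; with a
  handful of seeds it is vacuous (set `min_support = 0` and inspect
  supports directly).
* Modules are hard gene sets; genes cannot carry weights or belong to two
  modules after closure merging.
* With $n = 3$ matched normals, the significance gate has little power and
  the Shapiro–Wilk screen is itself weak; primary-module calls on designs
  this small should be read as the study's convention, not as a
  well-powered test.
* Quantile normalization aligns marginal distributions only; it cannot
  repair cohort differences that reorder genes within samples.
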