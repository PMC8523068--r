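# modact — gene co-expression modules and module-activation cancer classification

`modact` is an R implementation of a multi-cancer transcriptomic analysis
for comparative oncology: starting from a raw gene-by-library RNA-seq count
matrix spanning several cancer types plus matched normal tissue, it

1. **preprocesses** the counts (library-size scaling; low-count, variance
   and homolog filters; technical-replicate averaging; per-sample
   Z-scaling, `Z_{g,s} = (C_{g,s} − ⟨C⟩_s)/σ_s`),
2. **discovers co-expression modules** — size-bounded hierarchical seed
   clusters, randomized seed expansion, and Iterative-Signature-style
   refinement to fixed points, deduplicated by Jaccard-closure merging and
   screened by seed support,
3. **profiles module activations** per cancer (`A_{m,c}` = mean Z over the
   module's genes and the cancer's samples), testing tumor vs. matched
   normal with a Shapiro–Wilk-gated t / Wilcoxon test and
   Benjamini–Hochberg correction, and calls each cancer's *primary module*
   (most activated module with corrected p < 0.05),
4. **classifies samples** by nearest module-activation centroid,
   `D_{c,s} = sqrt(Σ_m (A_{m,c} − A_{m,s})²)`, validated with
   random-subsample cross-validation producing per-cancer one-vs-rest ROC
   curves, AUC and sensitivity at a chosen operating specificity (0.70),
   with joint quantile normalization and background negatives for
   external-cohort experiments, and
5. **selects and prioritizes biomarkers**: primary-module genes with
   activation > 1.5, annotated via a module × annotation incidence matrix,
   and screened for target novelty (IDG Tbio/Tdark classes with CTD
   literature cuts).

A negative-binomial synthetic-data generator with planted co-expression
blocks reproduces the study design end to end (five cancer groups of
12/12/12/15/9 tumors + 3 matched normals, 3 replicate libraries per
sample, planted modules of sizes 225/204/158/69/161), so every stage is
testable without any external download. The intended users are
bioinformaticians analyzing multi-condition bulk RNA-seq who want
module-level, cross-cohort-transferable cancer signatures.

## Worked example

```r
library(modact)

sim  <- simulate_counts(sim_config(), rng_seed = 1)       # 4000 x 225 counts
expr <- preprocess_counts(sim$counts, min_count = 25, min_samples = 185)
expr
#> expression_matrix: 2000 genes x 75 samples
#> value range: [-2.975, 9.879], median -0.258

mods <- discover_modules(expr, n_repeats = 20, rng_seed = 2)
mods
#> gene_modules: 5 modules, sizes 225/204/161/158/69

activation_profiles(expr, mods)
#> BLSA: primary module 5; activations -0.19 -0.18 -0.19 -0.18 4.86
#> MEL: primary module 2; activations -0.32 2.82 -0.32 -0.32 -0.33
#> OSA: primary module 4; activations -0.28 -0.29 -0.28 3.22 -0.28
#> PULM: primary module 1; activations 2.67 -0.34 -0.34 -0.34 -0.34
#> TLSA: primary module 3; activations -0.27 -0.28 3.19 -0.29 -0.29

run_cv(expr, mods, n_trials = 20, refit_modules = FALSE, rng_seed = 3)
#> cv_result (internal mode, 20 trials): mean AUC 1.000, mean sensitivity 1.000
```

Reading the output: preprocessing keeps the 2000 most informative genes
over the 75 replicate-averaged samples; refinement recovers exactly the
five planted modules (sizes sorted decreasing); each cancer's primary
module is the module planted in its tumors (e.g. module 1 for PULM at
activation 2.67 versus ≈ −0.3 background), and the held-out halves
classify perfectly.

The `analysis/` directory holds the same workflow as numbered drivers
(`01_simulate.R` … `06_biomarkers.R`), each writing its tables under
`results/`; run them in order with `Rscript`.

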