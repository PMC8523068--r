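#!/usr/bin/env Rscript
# Step 1 — generate the synthetic multi-cancer study.
#
# Emulates the study design the pipeline assumes: five cancer groups
# (PULM/MEL/OSA 12 tumors each, BLSA 15, TLSA 9; 3 matched normals each),
# 3 replicate libraries per sample (225 libraries), and five planted
# co-expression modules of sizes 225/204/158/69/161 elevated at log2 fold
# 2 in their target cancer's tumors. Also draws a synthetic evidence table
# (IDG classes, CTD scores, COSMIC/OncoKB flags) for the biomarker step.
# Outputs land under results/data/.

suppressPackageStartupMessages(library(modact))
seed <- 20260101L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_counts(sim_config(), rng_seed = seed)
write_count_matrix(sim$counts, file.path(out, "counts.tsv"),
                   file.path(out, "library_meta.tsv"))
truth <- data.frame(gene_id = names(sim$truth$module_assignments),
                    module_id = unname(sim$truth$module_assignments))
write.table(truth, file.path(out, "truth_modules.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ev <- make_evidence_table(rownames(sim$counts$counts), rng_seed = seed + 1L)
write.table(ev, file.path(out, "evidence.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("wrote %d genes x %d libraries (%d samples, %d cancer groups)\n",
            nrow(sim$counts$counts), ncol(sim$counts$counts),
            length(unique(sim$counts$meta$sample_id)),
            length(unique(sim$counts$meta$cancer_label))))
cat(sprintf("planted modules: %s genes in tumors of %s\n",
            paste(table(truth$module_id), collapse = "/"),
            paste(sim$truth$target_cancer, collapse = "/")))
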