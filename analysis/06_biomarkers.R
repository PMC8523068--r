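#!/usr/bin/env Rscript
# Step 6 — biomarker selection, annotation matrix and novelty screen.
#
# Candidates are the genes of each cancer's primary module with activation
# strictly above 1.5 (about the 95% confidence level for a Z score).
# A synthetic gene -> term map built from the planted truth (one term per
# planted block plus random terms) feeds the local hypergeometric
# enrichment, whose BH-corrected associations populate the module x
# annotation incidence matrix. Finally the evidence table drives the
# target-novelty screen (Tbio/Tdark, CTD cuts; p-value criterion applied
# only where matched normals share the tumor tissue, here PULM).

suppressPackageStartupMessages(library(modact))
seed <- 20260106L
data_dir <- "results/data"
out <- "results"

expr <- read_expression_matrix(file.path(data_dir, "z_matrix.tsv"),
                               file.path(data_dir, "sample_meta.tsv"))
mods <- read_modules(file.path(data_dir, "modules.tsv"))
prof <- activation_profiles(expr, mods)
pm <- vapply(prof, function(p) p$primary_module, 1L)
recs <- read.delim(file.path(out, "gene_activations.tsv"),
                   stringsAsFactors = FALSE)

sel <- select_biomarkers(recs, pm, z_threshold = 1.5)
cat(sprintf("selected %d biomarker candidates across %d cancers\n",
            nrow(sel), length(unique(sel$cancer_label))))
print(table(sel$cancer_label))

# synthetic annotation source: one term per planted block + random terms
truth <- read.delim(file.path(data_dir, "truth_modules.tsv"))
set.seed(seed)
term_map <- rbind(
  do.call(rbind, lapply(split(truth$gene_id[!is.na(truth$module_id)],
                              truth$module_id[!is.na(truth$module_id)]),
                        function(g) data.frame(
                          gene_id = g,
                          term_id = paste0("planted_process_",
                                           truth$module_id[match(g[1], truth$gene_id)])))),
  data.frame(gene_id = sample(truth$gene_id, 600, replace = TRUE),
             term_id = paste0("random_term_", sample(1:12, 600,
                                                     replace = TRUE))))
term_map <- unique(term_map)
ann <- do.call(rbind, lapply(mods, function(m) {
  e <- enrich_hypergeometric(m$genes, term_map,
                             universe = rownames(expr$values))
  data.frame(annotation_id = e$term_id, module_id = m$module_id,
             bh_p = e$bh_p, stringsAsFactors = FALSE)
}))
amat <- build_annotation_matrix(ann, p_cut = 0.005)
write.table(cbind(annotation_id = rownames(amat$matrix), amat$matrix),
            file.path(out, "annotation_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("annotation matrix: %d annotations (%d shared, %d specific)\n",
            nrow(amat$matrix), amat$n_shared, amat$n_specific))

ev <- read_evidence_table(file.path(data_dir, "evidence.tsv"))
joined <- merge(sel, ev, by = "gene_id")
screened <- do.call(rbind, lapply(split(joined, joined$cancer_label),
                                  function(d) prioritize_novelty(
                                    d, has_valid_normals =
                                      d$cancer_label[1] == "PULM")))
screened <- screened[order(screened$cancer_label,
                           -screened$activation_cancer), ]
write.table(screened, file.path(out, "biomarker_candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("high-novelty targets: %d of %d candidates\n",
            sum(screened$high_novelty), nrow(screened)))
print(table(screened$cancer_label, screened$high_novelty))
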