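test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(n_genes = 200, module_sizes = c(20, 15, 10, 8, 6))
  a <- simulate_counts(cfg, rng_seed = 99)
  b <- simulate_counts(cfg, rng_seed = 99)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$counts$meta, b$counts$meta)
  c <- simulate_counts(cfg, rng_seed = 100)
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("the study design is mirrored in the metadata", {
  sim <- simulate_counts(sim_config(n_genes = 120,
                                    module_sizes = c(10, 8, 6, 5, 4)),
                         rng_seed = 1)
  meta <- sim$counts$meta
  # 5 cancers, (12+12+12+15+9) tumors + 15 normals, 3 replicates each
  expect_equal(ncol(sim$counts$counts), (60 + 15) * 3)
  expect_equal(length(unique(meta$replicate_group)), 75)
  expect_equal(sum(meta$condition == "tumor"), 60 * 3)
  tab <- table(meta$cancer_label[meta$condition == "tumor"]) / 3
  expect_equal(unname(tab[c("PULM", "MEL", "OSA", "BLSA", "TLSA")]),
               c(12, 12, 12, 15, 9), ignore_attr = TRUE)
})

test_that("background and planted means match the count model", {
  cfg <- sim_config(n_genes = 900, module_sizes = c(60, 50, 40, 30, 20),
                    baseline_mean = 100, log2_fold = 2,
                    library_size_cv = 0)
  sim <- simulate_counts(cfg, rng_seed = 2)
  counts <- sim$counts$counts
  meta <- sim$counts$meta
  background <- names(which(is.na(sim$truth$module_assignments)))
  # empirical background mean within 3 standard errors of baseline_mean
  bg <- counts[background, ]
  se <- sd(bg) / sqrt(length(bg))
  expect_lt(abs(mean(bg) - 100), 3 * se)
  # planted tumor / normal mean ratio approximates 2^log2_fold within 10%
  for (m in 1:5) {
    genes <- names(which(sim$truth$module_assignments == m))
    cl <- sim$truth$target_cancer[[as.character(m)]]
    tum <- meta$library_id[meta$cancer_label == cl & meta$condition == "tumor"]
    nor <- meta$library_id[meta$cancer_label == cl & meta$condition == "normal"]
    ratio <- mean(counts[genes, tum]) / mean(counts[genes, nor])
    expect_lt(abs(ratio - 4) / 4, 0.10)
  }
})

test_that("zero fold change plants nothing recoverable", {
  cfg <- sim_config(n_genes = 400,
                    cancer_groups = data.frame(
                      label = c("PULM", "MEL", "OSA", "BLSA", "TLSA"),
                      n_tumor = c(8, 8, 8, 8, 8), n_normal = rep(3, 5),
                      stringsAsFactors = FALSE),
                    n_replicates = 2,
                    module_sizes = c(30, 25, 20, 15, 10), log2_fold = 0)
  sim <- simulate_counts(cfg, rng_seed = 3)
  expr <- preprocess_study(sim)
  mods <- suppressWarnings(discover_modules(expr, n_repeats = 10,
                                            rng_seed = 3))
  best <- if (length(mods) == 0) 0 else
    max(vapply(mods, function(m)
      max(vapply(truth_blocks(sim), jaccard, numeric(1), a = m$genes)),
      numeric(1)))
  expect_lt(best, 0.5)
})

test_that("recovered activation difference grows with the planted fold", {
  diffs <- vapply(c(0.5, 1, 2, 3), function(lf) {
    sim <- small_study(seed = 17, log2_fold = lf)
    expr <- preprocess_study(sim)
    blocks <- truth_blocks(sim)
    genes <- intersect(blocks[["1"]], rownames(expr$values))
    meta <- expr$meta
    tum <- meta$sample_id[meta$cancer_label == "PULM" &
                            meta$condition == "tumor"]
    nor <- meta$sample_id[meta$cancer_label == "PULM" &
                            meta$condition == "normal"]
    module_activation_by_group(expr, genes, tum) -
      module_activation_by_group(expr, genes, nor)
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})

test_that("normals can share the tumor tissue profile for one group", {
  cfg <- sim_config(n_genes = 300, module_sizes = c(30, 25, 20, 15, 10),
                    normal_shares_profile = "PULM", library_size_cv = 0)
  sim <- simulate_counts(cfg, rng_seed = 5)
  counts <- sim$counts$counts
  meta <- sim$counts$meta
  g1 <- names(which(sim$truth$module_assignments == 1))
  pulm_norm <- meta$library_id[meta$cancer_label == "PULM" &
                                 meta$condition == "normal"]
  mel_norm <- meta$library_id[meta$cancer_label == "MEL" &
                                meta$condition == "normal"]
  # PULM normals elevated on module 1 genes (half the log2 fold); MEL
  # normals stay at baseline
  expect_gt(mean(counts[g1, pulm_norm]), 1.5 * mean(counts[g1, mel_norm]))
  g2 <- names(which(sim$truth$module_assignments == 2))
  expect_lt(abs(mean(counts[g2, mel_norm]) / 100 - 1), 0.15)
})

test_that("batch effects distort genes consistently across libraries", {
  sim <- simulate_counts(sim_config(n_genes = 100,
                                    module_sizes = c(10, 8, 6, 5, 4)),
                         rng_seed = 4)
  shifted <- apply_batch_effect(sim$counts, gene_sd = 0.5, rng_seed = 9)
  expect_identical(shifted$meta, sim$counts$meta)
  # same multiplicative factor for a gene in every library
  ratio <- shifted$counts / sim$counts$counts
  ratio[!is.finite(ratio)] <- NA
  per_gene_spread <- apply(ratio, 1, function(r) diff(range(r, na.rm = TRUE)))
  expect_true(all(per_gene_spread < 1e-9, na.rm = TRUE))
  expect_identical(apply_batch_effect(sim$counts, 0.5, 9)$counts,
                   shifted$counts)
  expect_identical(apply_batch_effect(sim$counts, 0, 1)$counts,
                   sim$counts$counts)
})

test_that("evidence table proportions and determinism behave", {
  genes <- sprintf("g%04d", 1:1000)
  ev <- make_evidence_table(genes, idg_proportions = c(Tclin = 0.25,
                                                       Tchem = 0.25,
                                                       Tbio = 0.25,
                                                       Tdark = 0.25),
                            rng_seed = 6)
  counts <- table(ev$idg_class)
  # binomial 99% envelope around 250 with n = 1000, p = 0.25: ~ +/- 35
  expect_true(all(abs(counts - 250) < 36))
  expect_identical(ev, make_evidence_table(genes,
                                           idg_proportions = c(Tclin = 0.25,
                                                               Tchem = 0.25,
                                                               Tbio = 0.25,
                                                               Tdark = 0.25),
                                           rng_seed = 6))
  all_tbio <- make_evidence_table(genes[1:50],
                                  idg_proportions = c(Tclin = 0, Tchem = 0,
                                                      Tbio = 1, Tdark = 0),
                                  rng_seed = 7)
  expect_true(all(all_tbio$idg_class == "Tbio"))
  expect_true(all(all_tbio$ctd_inference >= 0))
  expect_true(all(all_tbio$ctd_refs >= 0))
})
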