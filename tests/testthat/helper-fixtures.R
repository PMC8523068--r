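# Fixture builders used across the suite. Everything is generated in code;
# nothing is read from disk.

# Minimal count matrix: `counts` is a genes x libraries matrix (dimnames
# optional); libraries are grouped into replicate groups of `reps_per_sample`.
toy_counts <- function(counts, cancer_label = "CA", condition = "tumor",
                       reps_per_sample = 1) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("lib", seq_len(ncol(counts)))
  n_lib <- ncol(counts)
  stopifnot(n_lib %% reps_per_sample == 0)
  sample_idx <- rep(seq_len(n_lib / reps_per_sample), each = reps_per_sample)
  meta <- data.frame(
    library_id = colnames(counts),
    sample_id = paste0("s", sample_idx),
    subject_id = paste0("d", sample_idx),
    cancer_label = rep_len(cancer_label, n_lib),
    condition = rep_len(condition, n_lib),
    replicate_group = paste0("s", sample_idx),
    stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

# Expression matrix with planted correlated gene blocks: block genes share a
# latent sample profile (elevated in `hot_samples` columns) plus small noise;
# background genes are independent N(0, 1). Columns are then re-standardized
# so expression_matrix invariants hold.
planted_expr <- function(n_genes, n_samples, blocks, shift = 4, noise = 0.25,
                         seed = 1, meta = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  for (b in blocks) {
    profile <- rnorm(n_samples, sd = 0.5)
    profile[b$hot_samples] <- profile[b$hot_samples] + shift
    for (g in b$genes)
      m[g, ] <- profile + rnorm(n_samples, sd = noise)
  }
  m <- scale(m)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  if (is.null(meta))
    meta <- data.frame(sample_id = colnames(m),
                       subject_id = colnames(m),
                       cancer_label = "CA", condition = "tumor",
                       stringsAsFactors = FALSE)
  expression_matrix(unclass(m), meta)
}

# A small but complete synthetic study used by several test files: 5 cancer
# groups, planted modules, replicated counts. Kept small for speed.
small_study <- function(seed = 7, log2_fold = 2) {
  cfg <- sim_config(n_genes = 600,
                    cancer_groups = data.frame(
                      label = c("PULM", "MEL", "OSA", "BLSA", "TLSA"),
                      n_tumor = c(8, 8, 8, 8, 8),
                      n_normal = c(3, 3, 3, 3, 3),
                      stringsAsFactors = FALSE),
                    n_replicates = 2,
                    module_sizes = c(40, 35, 30, 25, 20),
                    log2_fold = log2_fold)
  simulate_counts(cfg, rng_seed = seed)
}

# Preprocess a simulated study with thresholds scaled to its width.
preprocess_study <- function(sim, variance_quantile = 0.5) {
  n_lib <- ncol(sim$counts$counts)
  preprocess_counts(sim$counts, min_count = 25,
                    min_samples = round(0.8 * n_lib),
                    variance_quantile = variance_quantile)
}

# Gene sets of the planted truth, as a list module_id -> character vector.
truth_blocks <- function(sim) {
  a <- sim$truth$module_assignments
  split(names(a)[!is.na(a)], a[!is.na(a)])
}

# Brute-force Mann-Whitney AUC oracle: fraction of (positive, negative)
# pairs where the positive ranks closer (ties half credit). Smaller
# distance = more positive.
mw_auc <- function(distances, is_positive) {
  pos <- distances[is_positive]
  neg <- distances[!is_positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p < q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}
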