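#' Default synthetic-study configuration
#'
#' Mirrors the design of the motivating multi-cancer study: five cancer
#' groups (12 tumors + 3 matched normals each for PULM, MEL and OSA; 15 + 3
#' for BLSA; 9 + 3 for TLSA), three technical replicate libraries per
#' sample, and five planted co-expression modules of sizes
#' 225/204/158/69/161, each elevated (log2 fold 2) in one cancer's tumor
#' samples only. Counts follow a negative-binomial model around a common
#' baseline with configurable dispersion and library-size jitter.
#'
#' @param n_genes Total genes (planted module sizes must fit inside).
#' @param cancer_groups Data frame `label`, `n_tumor`, `n_normal`.
#' @param n_replicates Technical replicate libraries per sample.
#' @param module_sizes Integer vector of planted module sizes; module i is
#'   elevated in cancer group i's tumors.
#' @param log2_fold Per-module log2 fold elevation (recycled).
#' @param baseline_mean Negative-binomial baseline mean count per gene.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param library_size_cv Coefficient of variation of per-library size
#'   factors.
#' @param normal_shares_profile Label of a group whose matched normals
#'   share the tumor tissue profile (the planted elevation appears in its
#'   normals at half the log2 fold), mimicking normals drawn from the same
#'   tissue as the tumor; `NULL` for none.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 4000,
                       cancer_groups = data.frame(
                         label = c("PULM", "MEL", "OSA", "BLSA", "TLSA"),
                         n_tumor = c(12, 12, 12, 15, 9),
                         n_normal = c(3, 3, 3, 3, 3),
                         stringsAsFactors = FALSE),
                       n_replicates = 3,
                       module_sizes = c(225, 204, 158, 69, 161),
                       log2_fold = 2,
                       baseline_mean = 100,
                       dispersion = 0.1,
                       library_size_cv = 0.1,
                       normal_shares_profile = NULL) {
  if (sum(module_sizes) > n_genes)
    stop("planted module sizes exceed the number of genes")
  if (nrow(cancer_groups) < 2) stop("need at least 2 cancer groups")
  if (length(module_sizes) > nrow(cancer_groups))
    stop("more planted modules than cancer groups")
  if (baseline_mean <= 0 || dispersion <= 0 || library_size_cv < 0)
    stop("count model parameters must be positive")
  structure(list(n_genes = n_genes, cancer_groups = cancer_groups,
                 n_replicates = n_replicates, module_sizes = module_sizes,
                 log2_fold = rep_len(log2_fold, length(module_sizes)),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 library_size_cv = library_size_cv,
                 normal_shares_profile = normal_shares_profile),
            class = "sim_config")
}

#' Generate a synthetic multi-cancer count study
#'
#' Draws a replicated RNA-seq count matrix with planted co-expression
#' structure. Background genes share the baseline mean in every sample;
#' the genes of planted module i have mean `baseline_mean * 2^log2_fold[i]`
#' in the tumor samples of cancer group i and baseline elsewhere (normals
#' included, unless the group is flagged as sharing its tissue profile, in
#' which case its normals sit at half the log2 fold). Every library is an
#' independent negative-binomial draw around its sample's expected profile,
#' scaled by a per-library size factor with the configured coefficient of
#' variation. The whole draw is reproducible from `rng_seed`.
#'
#' @param cfg A [sim_config()].
#' @param rng_seed Integer seed.
#' @return A list: `counts` (a [count_matrix()], genes x libraries),
#'   `truth` (list with `module_assignments` — named vector gene ->
#'   module id or `NA` for background — `target_cancer` per module, and
#'   `log2_fold`).
#' @export
simulate_counts <- function(cfg = sim_config(), rng_seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(rng_seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  module_of <- rep(NA_integer_, cfg$n_genes)
  names(module_of) <- genes
  pos <- 0
  for (i in seq_along(cfg$module_sizes)) {
    module_of[pos + seq_len(cfg$module_sizes[i])] <- i
    pos <- pos + cfg$module_sizes[i]
  }
  groups <- cfg$cancer_groups
  meta_rows <- list()
  mu_cols <- list()
  for (gi in seq_len(nrow(groups))) {
    label <- groups$label[gi]
    for (cond in c("tumor", "normal")) {
      n_s <- if (cond == "tumor") groups$n_tumor[gi] else groups$n_normal[gi]
      for (si in seq_len(n_s)) {
        sample_id <- sprintf("%s_%s_%02d", label,
                             ifelse(cond == "tumor", "T", "N"), si)
        mu <- rep(cfg$baseline_mean, cfg$n_genes)
        if (gi <= length(cfg$module_sizes)) {
          lf <- cfg$log2_fold[gi]
          in_mod <- !is.na(module_of) & module_of == gi
          if (cond == "tumor") {
            mu[in_mod] <- cfg$baseline_mean * 2^lf
          } else if (!is.null(cfg$normal_shares_profile) &&
                     label == cfg$normal_shares_profile) {
            mu[in_mod] <- cfg$baseline_mean * 2^(lf / 2)
          }
        }
        mu_cols[[sample_id]] <- mu
        meta_rows[[sample_id]] <- data.frame(
          sample_id = sample_id,
          subject_id = sprintf("%s_D%02d", label, si),
          cancer_label = label, condition = cond,
          stringsAsFactors = FALSE)
      }
    }
  }
  sample_ids <- names(mu_cols)
  n_lib <- length(sample_ids) * cfg$n_replicates
  counts <- matrix(0, cfg$n_genes, n_lib)
  lib_meta <- vector("list", n_lib)
  lib_names <- character(n_lib)
  size <- 1 / cfg$dispersion
  k <- 0L
  for (s in sample_ids) {
    for (r in seq_len(cfg$n_replicates)) {
      k <- k + 1L
      sf <- if (cfg$library_size_cv > 0)
        stats::rgamma(1, shape = 1 / cfg$library_size_cv^2,
                      scale = cfg$library_size_cv^2) else 1
      counts[, k] <- stats::rnbinom(cfg$n_genes, mu = mu_cols[[s]] * sf,
                                    size = size)
      lib_names[k] <- sprintf("%s_r%d", s, r)
      m <- meta_rows[[s]]
      lib_meta[[k]] <- data.frame(library_id = lib_names[k],
                                  sample_id = m$sample_id,
                                  subject_id = m$subject_id,
                                  cancer_label = m$cancer_label,
                                  condition = m$condition,
                                  replicate_group = m$sample_id,
                                  stringsAsFactors = FALSE)
    }
  }
  dimnames(counts) <- list(genes, lib_names)
  truth <- list(
    module_assignments = module_of,
    target_cancer = stats::setNames(
      groups$label[seq_along(cfg$module_sizes)],
      seq_along(cfg$module_sizes)),
    log2_fold = cfg$log2_fold)
  list(counts = count_matrix(counts, do.call(rbind, lib_meta)),
       truth = truth)
}

#' Apply a multiplicative per-gene batch effect to a count matrix
#'
#' Emulates the systematic gene-wise distortions (platform, protocol,
#' annotation differences) that separate an external cohort from the cohort
#' a model was trained on: every gene's counts are multiplied across all
#' libraries by its own log-normal factor with standard deviation
#' `gene_sd` on the log scale. Column-wise Z-scaling does not remove such
#' distortions, which is exactly why cross-cohort classification needs
#' joint quantile normalization and still degrades.
#'
#' @param x A [count_matrix()].
#' @param gene_sd Standard deviation of the per-gene log-normal factor.
#' @param rng_seed Integer seed.
#' @return A [count_matrix()] with distorted counts.
#' @export
apply_batch_effect <- function(x, gene_sd = 0.4, rng_seed = 1L) {
  stopifnot(inherits(x, "count_matrix"), gene_sd >= 0)
  set.seed(rng_seed)
  f <- exp(stats::rnorm(nrow(x$counts), sd = gene_sd))
  count_matrix(x$counts * f, x$meta)
}

#' Generate a synthetic gene evidence table
#'
#' Assigns IDG target development levels with configurable proportions and
#' draws CTD inference scores (exponential), CTD reference counts
#' (negative binomial) and COSMIC/OncoKB membership flags (Bernoulli), so
#' every branch of the biomarker novelty screen is exercised on synthetic
#' data. The table is synthetic throughout — it stands in for externally
#' curated evidence, not a reconstruction of it.
#'
#' @param genes Character vector of gene identifiers.
#' @param idg_proportions Named numeric vector over
#'   `c("Tclin", "Tchem", "Tbio", "Tdark")`, summing to 1.
#' @param ctd_inference_mean Mean of the exponential inference-score draw.
#' @param ctd_refs_mean Mean of the reference-count draw.
#' @param cosmic_rate,oncokb_rate Membership probabilities.
#' @param rng_seed Integer seed.
#' @return Data frame `gene_id`, `idg_class`, `ctd_inference`, `ctd_refs`,
#'   `in_cosmic`, `in_oncokb`.
#' @export
make_evidence_table <- function(genes,
                                idg_proportions = c(Tclin = 0.05,
                                                    Tchem = 0.10,
                                                    Tbio = 0.60,
                                                    Tdark = 0.25),
                                ctd_inference_mean = 15,
                                ctd_refs_mean = 8,
                                cosmic_rate = 0.3, oncokb_rate = 0.1,
                                rng_seed = 1L) {
  classes <- c("Tclin", "Tchem", "Tbio", "Tdark")
  if (!setequal(names(idg_proportions), classes))
    stop("`idg_proportions` must name exactly: ",
         paste(classes, collapse = ", "))
  if (abs(sum(idg_proportions) - 1) > 1e-8)
    stop("`idg_proportions` must sum to 1")
  set.seed(rng_seed)
  n <- length(genes)
  data.frame(
    gene_id = genes,
    idg_class = sample(classes, n, replace = TRUE,
                       prob = idg_proportions[classes]),
    ctd_inference = round(stats::rexp(n, rate = 1 / ctd_inference_mean), 2),
    ctd_refs = stats::rnbinom(n, mu = ctd_refs_mean, size = 1),
    in_cosmic = stats::runif(n) < cosmic_rate,
    in_oncokb = stats::runif(n) < oncokb_rate,
    stringsAsFactors = FALSE)
}
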