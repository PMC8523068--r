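#' Average activation of a gene over a sample group
#'
#' A gene's activation in a single sample is its Z-scaled expression value;
#' its activation for a cancer (or normal) group is the mean of those values
#' over the group's samples.
#'
#' @param expr An [expression_matrix()].
#' @param gene Gene identifier.
#' @param group_samples Character vector of sample identifiers (non-empty).
#' @return The mean Z value (scalar).
#' @export
gene_activation <- function(expr, gene, group_samples) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(group_samples) == 0) stop("`group_samples` must be non-empty")
  if (!gene %in% rownames(expr$values)) stop("unknown gene: ", gene)
  if (!all(group_samples %in% colnames(expr$values)))
    stop("unknown sample(s) in `group_samples`")
  mean(expr$values[gene, group_samples])
}

#' Module activation in a single sample
#'
#' The mean Z value over the module's genes in one sample.
#'
#' @param expr An [expression_matrix()].
#' @param module A single module (list with a `genes` element) or a
#'   character vector of gene identifiers.
#' @param sample Sample identifier.
#' @return Scalar activation.
#' @export
module_activation_by_sample <- function(expr, module, sample) {
  genes <- if (is.list(module)) module$genes else module
  stopifnot(inherits(expr, "expression_matrix"))
  if (!all(genes %in% rownames(expr$values)))
    stop("module contains genes absent from the expression matrix")
  if (!sample %in% colnames(expr$values)) stop("unknown sample: ", sample)
  mean(expr$values[genes, sample])
}

#' Module activation averaged over a sample group
#'
#' The mean of per-sample module activations over the group — identical in
#' value to the grand mean of the module x group sub-block of Z. The same
#' formula serves cancer groups and matched-normal groups.
#'
#' @inheritParams module_activation_by_sample
#' @param group_samples Character vector of sample identifiers (non-empty).
#' @return Scalar activation.
#' @export
module_activation_by_group <- function(expr, module, group_samples) {
  genes <- if (is.list(module)) module$genes else module
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(group_samples) == 0) stop("`group_samples` must be non-empty")
  per_sample <- vapply(group_samples, function(s)
    module_activation_by_sample(expr, genes, s), numeric(1))
  mean(per_sample)
}

#' Matrix of module activations per sample
#'
#' Rows are modules, columns are samples; entry (m, s) is the mean Z of
#' module m's genes in sample s. This is the coordinate matrix used for the
#' centroid classifier and the activation PCA.
#'
#' @param expr An [expression_matrix()].
#' @param modules A `gene_modules` list.
#' @return Numeric matrix, modules x samples, rownames `module_<id>`.
#' @export
module_activation_matrix <- function(expr, modules) {
  stopifnot(inherits(expr, "expression_matrix"))
  z <- expr$values
  out <- t(vapply(modules, function(m) {
    genes <- intersect(m$genes, rownames(z))
    if (length(genes) == 0)
      stop("module ", m$module_id, " has no genes in the expression matrix")
    if (length(genes) < length(m$genes))
      warning("module ", m$module_id, ": dropping ",
              length(m$genes) - length(genes),
              " genes absent from the expression matrix")
    colMeans(z[genes, , drop = FALSE])
  }, numeric(ncol(z))))
  rownames(out) <- paste0("module_",
                          vapply(modules, function(m) as.integer(m$module_id),
                                 1L))
  colnames(out) <- colnames(z)
  out
}

#' Two-sample activation test with normality gating
#'
#' Compares per-sample activations (module means, or a single gene's Z
#' values) between a cancer group and its matched normals. Both sides are
#' screened with the Shapiro-Wilk normality test at level 0.05: a two-tailed
#' two-sample t-test is used when both pass, otherwise the Wilcoxon rank-sum
#' test. The raw two-sided p-value is returned; Benjamini-Hochberg
#' correction across the relevant family is the caller's responsibility.
#'
#' @param cancer_values,normal_values Numeric vectors of per-sample
#'   activations, at least 3 observations each (the Shapiro-Wilk minimum).
#' @return Raw two-sided p-value.
#' @export
activation_test <- function(cancer_values, normal_values) {
  if (length(cancer_values) < 3 || length(normal_values) < 3)
    stop("need at least 3 observations per group")
  normal_ok <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)  # degenerate: not testably normal
    stats::shapiro.test(v)$p.value > 0.05
  }
  p <- if (normal_ok(cancer_values) && normal_ok(normal_values)) {
    stats::t.test(cancer_values, normal_values,
                  alternative = "two.sided")$p.value
  } else {
    suppressWarnings(stats::wilcox.test(cancer_values, normal_values,
                                        alternative = "two.sided"))$p.value
  }
  if (is.nan(p)) p <- 1  # fully tied rank-sum: no evidence of a difference
  p
}

#' Per-cancer module activation profiles with primary-module calls
#'
#' For every cancer label in the metadata, computes each module's activation
#' over the cancer's tumor samples and over its matched normals, tests the
#' tumor-vs-normal difference of per-sample module activations
#' (Shapiro-Wilk-gated t / Wilcoxon), BH-corrects the p-values within the
#' cancer's module family, and calls the primary module: the most highly
#' activated module with corrected p below `alpha` (ties broken toward the
#' lower module id); `NA` when no module qualifies.
#'
#' @param expr An [expression_matrix()] whose metadata carries
#'   `cancer_label` and `condition`; normals are matched to a cancer by
#'   sharing its `cancer_label`.
#' @param modules A `gene_modules` list.
#' @param alpha Significance level for the primary-module call.
#' @return A list of class `activation_profiles`: per cancer, a list with
#'   `cancer_label`, `activations`, `normal_activations`, `p_raw`, `p_bh`
#'   (vectors indexed by module) and `primary_module` (integer or `NA`).
#'   The module x sample activation matrix is attached as attribute
#'   `"activation_matrix"`.
#' @export
activation_profiles <- function(expr, modules, alpha = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  act <- module_activation_matrix(expr, modules)
  meta <- expr$meta
  cancers <- sort(unique(meta$cancer_label[meta$condition == "tumor"]))
  module_ids <- vapply(modules, function(m) as.integer(m$module_id), 1L)
  profiles <- lapply(cancers, function(cl) {
    tumor <- meta$sample_id[meta$cancer_label == cl & meta$condition == "tumor"]
    norm <- meta$sample_id[meta$cancer_label == cl & meta$condition == "normal"]
    a_c <- rowMeans(act[, tumor, drop = FALSE])
    a_n <- if (length(norm) > 0) rowMeans(act[, norm, drop = FALSE])
           else rep(NA_real_, nrow(act))
    p_raw <- if (length(norm) >= 3 && length(tumor) >= 3) {
      vapply(seq_len(nrow(act)), function(i)
        activation_test(act[i, tumor], act[i, norm]), numeric(1))
    } else rep(NA_real_, nrow(act))
    p_bh <- stats::p.adjust(p_raw, method = "BH")
    eligible <- which(!is.na(p_bh) & p_bh < alpha)
    primary <- if (length(eligible) == 0) NA_integer_ else {
      best <- eligible[which.max(a_c[eligible])]  # which.max: first max,
      module_ids[best]                            # lower id wins ties
    }
    list(cancer_label = cl,
         activations = stats::setNames(a_c, rownames(act)),
         normal_activations = stats::setNames(a_n, rownames(act)),
         p_raw = stats::setNames(p_raw, rownames(act)),
         p_bh = stats::setNames(p_bh, rownames(act)),
         primary_module = primary)
  })
  names(profiles) <- cancers
  structure(profiles, class = "activation_profiles",
            activation_matrix = act)
}

#' @export
print.activation_profiles <- function(x, ...) {
  for (p in x) {
    cat(sprintf("%s: primary module %s; activations %s\n",
                p$cancer_label,
                ifelse(is.na(p$primary_module), "none", p$primary_module),
                paste(sprintf("%.2f", p$activations), collapse = " ")))
  }
  invisible(x)
}

#' Long-format activation report
#'
#' One row per (cancer, module): cancer and normal activations, raw and
#' BH-corrected p-values, and a primary-module flag.
#'
#' @param profiles An `activation_profiles` object.
#' @return A data frame with columns `cancer_label`, `module_id`,
#'   `activation_cancer`, `activation_normal`, `p_raw`, `p_bh`, `primary`.
#' @export
activation_report <- function(profiles) {
  stopifnot(inherits(profiles, "activation_profiles"))
  do.call(rbind, lapply(profiles, function(p) {
    ids <- as.integer(sub("module_", "", names(p$activations)))
    data.frame(cancer_label = p$cancer_label, module_id = ids,
               activation_cancer = unname(p$activations),
               activation_normal = unname(p$normal_activations),
               p_raw = unname(p$p_raw), p_bh = unname(p$p_bh),
               primary = ids == p$primary_module & !is.na(p$primary_module),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Per-gene activation records for a cancer's primary module
#'
#' For each gene of the given module, computes the gene's mean activation
#' over the cancer's tumor samples and over its matched normals, and a
#' tumor-vs-normal test on the per-sample Z values, BH-corrected across the
#' module's gene family.
#'
#' @param expr An [expression_matrix()].
#' @param module A module (list with `genes`) or character vector of genes.
#' @param cancer_label Cancer whose tumor/normal samples are compared.
#' @return Data frame `gene_id`, `cancer_label`, `activation_cancer`,
#'   `activation_normal`, `p_raw`, `p_bh`, sorted decreasing by
#'   `activation_cancer`.
#' @export
gene_activation_records <- function(expr, module, cancer_label) {
  genes <- if (is.list(module)) module$genes else module
  stopifnot(inherits(expr, "expression_matrix"))
  meta <- expr$meta
  tumor <- meta$sample_id[meta$cancer_label == cancer_label &
                            meta$condition == "tumor"]
  norm <- meta$sample_id[meta$cancer_label == cancer_label &
                           meta$condition == "normal"]
  if (length(tumor) == 0) stop("no tumor samples for ", cancer_label)
  z <- expr$values
  a_c <- rowMeans(z[genes, tumor, drop = FALSE])
  a_n <- if (length(norm) > 0) rowMeans(z[genes, norm, drop = FALSE])
         else rep(NA_real_, length(genes))
  p_raw <- if (length(norm) >= 3 && length(tumor) >= 3) {
    vapply(genes, function(g)
      activation_test(z[g, tumor], z[g, norm]), numeric(1))
  } else rep(NA_real_, length(genes))
  out <- data.frame(gene_id = genes, cancer_label = cancer_label,
                    activation_cancer = unname(a_c),
                    activation_normal = unname(a_n),
                    p_raw = unname(p_raw),
                    p_bh = stats::p.adjust(p_raw, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$activation_cancer, decreasing = TRUE), , drop = FALSE]
}

#' PCA of the module x sample activation matrix
#'
#' A plain principal-component decomposition of per-sample module
#' activations, for inspecting how tumor and normal samples separate in
#' module space.
#'
#' @param expr An [expression_matrix()].
#' @param modules A `gene_modules` list.
#' @return The [stats::prcomp()] object, with the sample metadata attached
#'   as attribute `"meta"`.
#' @export
activation_pca <- function(expr, modules) {
  act <- module_activation_matrix(expr, modules)
  pc <- stats::prcomp(t(act), center = TRUE, scale. = FALSE)
  attr(pc, "meta") <- expr$meta
  pc
}
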