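#' Scale libraries to a common total read count
#'
#' Each column of the raw count matrix is rescaled so that all libraries have
#' the same total count, taken as the mean of the observed library totals.
#' This removes the (small) between-library differences in sequencing depth
#' before any filtering is applied.
#'
#' @param x A [count_matrix()].
#' @return A [count_matrix()] with equal column totals; gene and library
#'   order are preserved. Values are no longer integer in general.
#' @export
scale_library_size <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    bad <- colnames(x$counts)[totals == 0]
    stop("library has zero total count: ", paste(bad, collapse = ", "))
  }
  target <- mean(totals)
  scaled <- sweep(x$counts, 2, target / totals, `*`)
  count_matrix(scaled, x$meta)
}

#' Drop genes with low read counts across libraries
#'
#' A gene is retained if its count strictly exceeds `min_count` in at least
#' `min_samples` libraries. The study default (25 counts in at least 185 of
#' 225 libraries) keeps genes detectably expressed in the large majority of
#' libraries.
#'
#' @param x A [count_matrix()].
#' @param min_count Count threshold (a gene must exceed it).
#' @param min_samples Minimum number of libraries exceeding the threshold.
#' @return A filtered [count_matrix()] (gene order preserved). Warns if no
#'   gene survives.
#' @export
filter_low_counts <- function(x, min_count = 25, min_samples = 185) {
  stopifnot(inherits(x, "count_matrix"))
  if (min_count < 0) stop("`min_count` must be >= 0")
  if (min_samples > ncol(x$counts))
    stop("`min_samples` exceeds the number of libraries")
  keep <- rowSums(x$counts > min_count) >= min_samples
  if (!any(keep)) warning("no genes pass the low-count filter")
  count_matrix(x$counts[keep, , drop = FALSE], x$meta)
}

#' Keep the most variable genes
#'
#' Retains the top `ceil(variance_quantile * n_genes)` genes ranked by
#' sample variance (n - 1 denominator) across libraries. Ties are broken by
#' input gene order (stable sort), so the result is deterministic.
#'
#' @param x A [count_matrix()].
#' @param variance_quantile Fraction of genes to retain, in (0, 1].
#' @return A filtered [count_matrix()]; the surviving genes keep their
#'   original relative order.
#' @export
filter_low_variance <- function(x, variance_quantile = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  if (variance_quantile <= 0 || variance_quantile > 1)
    stop("`variance_quantile` must be in (0, 1]")
  n <- nrow(x$counts)
  if (n < 2) stop("need at least 2 genes to rank variances")
  v <- apply(x$counts, 1, stats::var)
  n_keep <- ceiling(variance_quantile * n)
  ord <- order(v, decreasing = TRUE)  # stable: ties keep input order
  keep <- sort(ord[seq_len(n_keep)])
  count_matrix(x$counts[keep, , drop = FALSE], x$meta)
}

#' Keep genes with a cross-species homolog
#'
#' Restricts the matrix to genes present in a homolog map (e.g. canine
#' symbols with an assigned human ortholog). The map is consumed as a plain
#' table; only its keys matter here.
#'
#' @param x A [count_matrix()].
#' @param homolog_map Either a character vector of gene identifiers, or a
#'   data frame whose first column holds them.
#' @return A filtered [count_matrix()] (gene order preserved).
#' @export
filter_homologs <- function(x, homolog_map) {
  stopifnot(inherits(x, "count_matrix"))
  keys <- if (is.data.frame(homolog_map)) as.character(homolog_map[[1]])
          else as.character(homolog_map)
  keep <- rownames(x$counts) %in% keys
  if (!any(keep))
    stop("no genes in the matrix are present in the homolog map")
  count_matrix(x$counts[keep, , drop = FALSE], x$meta)
}

#' Average technical replicates into one column per sample
#'
#' Collapses libraries by `replicate_group`: each output column is the
#' arithmetic mean of the group's libraries. Metadata must be constant
#' within a group (same sample, subject, cancer label and condition);
#' conflicting metadata is an error. The operation is idempotent.
#'
#' @param x A [count_matrix()].
#' @return A [count_matrix()] with one column per replicate group, ordered
#'   by first appearance of each group.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  groups <- x$meta$replicate_group
  uniq <- unique(groups)
  checked <- c("sample_id", "subject_id", "cancer_label", "condition")
  out <- matrix(0, nrow(x$counts), length(uniq),
                dimnames = list(rownames(x$counts), NULL))
  meta_rows <- vector("list", length(uniq))
  for (i in seq_along(uniq)) {
    idx <- which(groups == uniq[i])
    sub <- x$meta[idx, checked, drop = FALSE]
    if (nrow(unique(sub)) != 1)
      stop("replicate group '", uniq[i], "' has conflicting metadata")
    out[, i] <- rowMeans(x$counts[, idx, drop = FALSE])
    m <- x$meta[idx[1], , drop = FALSE]
    m$library_id <- m$sample_id
    meta_rows[[i]] <- m
  }
  meta <- do.call(rbind, meta_rows)
  colnames(out) <- meta$sample_id
  meta$replicate_group <- meta$sample_id
  count_matrix(out, meta)
}

#' Z-scale a count matrix column-wise
#'
#' Centers and scales each sample column: subtract the column's mean count
#' across genes and divide by its standard deviation (n - 1 denominator).
#' The result expresses each gene's count relative to the sample's overall
#' background, so a value of 7 means seven background standard deviations
#' above the sample average — an absolute activation scale with 0 as the
#' reference.
#'
#' @param x A [count_matrix()] (typically replicate-averaged).
#' @return An [expression_matrix()]; every column has mean 0 and standard
#'   deviation 1 to within 1e-9.
#' @export
z_transform <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  sds <- apply(x$counts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x$counts)[sds == 0]
    stop("zero standard deviation in sample: ", paste(bad, collapse = ", "))
  }
  z <- scale(x$counts, center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  # one column per sample: keyed by column identifier (equal to sample_id
  # after replicate averaging, library_id otherwise)
  meta <- data.frame(sample_id = colnames(x$counts),
                     subject_id = x$meta$subject_id,
                     cancer_label = x$meta$cancer_label,
                     condition = x$meta$condition,
                     stringsAsFactors = FALSE)
  expression_matrix(unclass(z), meta)
}

#' Run the full count-matrix preprocessing pipeline
#'
#' Applies, in order: library-size scaling, then the configured filter
#' sequence, then replicate averaging, then Z-scaling. The default filter
#' order is homolog, low-count, low-variance. The composition is
#' order-sensitive, so the order actually applied is recorded in the
#' result's `"steps"` attribute.
#'
#' @param x A [count_matrix()] of raw counts.
#' @param min_count,min_samples See [filter_low_counts()].
#' @param variance_quantile See [filter_low_variance()].
#' @param homolog_map Optional; see [filter_homologs()]. `NULL` skips the
#'   homolog filter.
#' @param filter_order Character vector, a permutation of (a subset of)
#'   `c("homolog", "counts", "variance")`.
#' @return An [expression_matrix()] with attribute `"steps"` listing the
#'   steps applied in order.
#' @export
preprocess_counts <- function(x, min_count = 25, min_samples = 185,
                              variance_quantile = 0.5, homolog_map = NULL,
                              filter_order = c("homolog", "counts",
                                               "variance")) {
  stopifnot(inherits(x, "count_matrix"))
  allowed <- c("homolog", "counts", "variance")
  if (!all(filter_order %in% allowed) || anyDuplicated(filter_order))
    stop("`filter_order` must be distinct values among: ",
         paste(allowed, collapse = ", "))
  steps <- "scale_library_size"
  x <- scale_library_size(x)
  for (step in filter_order) {
    if (step == "homolog") {
      if (is.null(homolog_map)) next
      x <- filter_homologs(x, homolog_map)
    } else if (step == "counts") {
      x <- filter_low_counts(x, min_count, min_samples)
    } else {
      x <- filter_low_variance(x, variance_quantile)
    }
    steps <- c(steps, paste0("filter_", step))
  }
  x <- average_replicates(x)
  steps <- c(steps, "average_replicates")
  out <- z_transform(x)
  steps <- c(steps, "z_transform")
  attr(out, "steps") <- steps
  out
}
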