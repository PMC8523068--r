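#' Construct a count matrix with per-library metadata
#'
#' The container for raw RNA-seq read counts: a genes x libraries integer (or
#' numeric, after library-size scaling) matrix plus one metadata row per
#' library. Libraries belonging to the same biological sample share a
#' `replicate_group`; replicate groups partition the libraries.
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene identifiers,
#'   unique), libraries in columns (colnames = library identifiers). All
#'   entries must be non-negative and finite.
#' @param meta Data frame with one row per library and columns `library_id`,
#'   `sample_id`, `subject_id`, `cancer_label`, `condition` (`"tumor"` or
#'   `"normal"`), `replicate_group`. Rows are matched to columns by
#'   `library_id`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `meta` (reordered to match the column order).
#' @export
count_matrix <- function(counts, meta) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("`counts` must have gene rownames and library colnames")
  if (anyDuplicated(rownames(counts)))
    stop("gene identifiers must be unique")
  if (anyDuplicated(colnames(counts)))
    stop("library identifiers must be unique")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("library_id", "sample_id", "subject_id", "cancer_label",
                "condition", "replicate_group")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!setequal(meta$library_id, colnames(counts)))
    stop("metadata library_id values must match the count matrix columns")
  if (!all(meta$condition %in% c("tumor", "normal")))
    stop("condition must be 'tumor' or 'normal'")
  meta <- meta[match(colnames(counts), meta$library_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries (%d replicate groups)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$replicate_group))))
  cat("cancer labels:",
      paste(sort(unique(x$meta$cancer_label)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a Z-scaled expression matrix
#'
#' Holds the column-standardized expression values produced by
#' [z_transform()]: one column per biological sample (replicate-group level),
#' each column with mean 0 and unit standard deviation across genes.
#'
#' @param values Numeric matrix, genes x samples, with dimnames.
#' @param meta Data frame with one row per sample: columns `sample_id`,
#'   `subject_id`, `cancer_label`, `condition`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (any(!is.finite(values)))
    stop("expression values must be finite (no missing values)")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "subject_id", "cancer_label", "condition")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!setequal(meta$sample_id, colnames(values)))
    stop("metadata sample_id values must match the matrix columns")
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("value range: [%.3f, %.3f], median %.3f\n",
              min(x$values), max(x$values), stats::median(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a tab-delimited count matrix and its sample metadata
#'
#' The count-matrix dialect is plain TSV: first column the gene identifier,
#' header row of library identifiers. The metadata file is TSV with columns
#' `library_id`, `sample_id`, `subject_id`, `cancer_label`, `condition`,
#' `replicate_group`.
#'
#' @param counts_file Path to the count TSV.
#' @param meta_file Path to the metadata TSV.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_file, meta_file) {
  tab <- utils::read.delim(counts_file, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  meta <- utils::read.delim(meta_file, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  count_matrix(m, meta)
}

#' Write a count matrix (and optionally its metadata) to TSV
#'
#' @param x A [count_matrix()].
#' @param counts_file Output path for the count TSV.
#' @param meta_file Optional output path for the metadata TSV.
#' @return Invisibly, `x`.
#' @export
write_count_matrix <- function(x, counts_file, meta_file = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_file))
    utils::write.table(x$meta, meta_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}

#' Read a Z-scaled expression matrix from TSV
#'
#' Same layout as the count dialect: gene identifiers in the first column,
#' sample identifiers in the header. Metadata columns: `sample_id`,
#' `subject_id`, `cancer_label`, `condition`.
#'
#' @param values_file Path to the expression TSV.
#' @param meta_file Path to the sample metadata TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(values_file, meta_file) {
  tab <- utils::read.delim(values_file, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  meta <- utils::read.delim(meta_file, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  expression_matrix(m, meta)
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' @param x An [expression_matrix()].
#' @param values_file Output path for the expression TSV.
#' @param meta_file Optional output path for the metadata TSV.
#' @return Invisibly, `x`.
#' @export
write_expression_matrix <- function(x, values_file, meta_file = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, values_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_file))
    utils::write.table(x$meta, meta_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}
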