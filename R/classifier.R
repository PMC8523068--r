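#' Joint quantile normalization of expression matrices
#'
#' Forces every sample column, across all supplied matrices, onto one
#' empirical distribution: after restricting to the shared gene set, the
#' value at rank r in each column is replaced by the mean of the rank-r
#' values across columns, with ties averaged. This is the standard device
#' for putting cohorts measured on different platforms onto a common
#' dynamic range before computing cross-cohort activations.
#'
#' @param matrices A list of [expression_matrix()] objects. Gene sets are
#'   intersected first; a warning reports any loss.
#' @return A list of [expression_matrix()] objects of the same length, all
#'   on the shared gene set, with identical sorted column values.
#' @export
quantile_normalize_joint <- function(matrices) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "expression_matrix")))
  shared <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (length(shared) == 0) stop("matrices share no genes")
  n_all <- vapply(matrices, function(m) nrow(m$values), 1L)
  if (any(n_all > length(shared)))
    warning("dropping ", max(n_all) - length(shared),
            " genes absent from some cohort")
  combined <- do.call(cbind, lapply(matrices, function(m)
    m$values[shared, , drop = FALSE]))
  normed <- limma::normalizeQuantiles(combined, ties = TRUE)
  dimnames(normed) <- dimnames(combined)
  offsets <- cumsum(c(0, vapply(matrices, function(m) ncol(m$values), 1L)))
  lapply(seq_along(matrices), function(i) {
    cols <- (offsets[i] + 1):offsets[i + 1]
    expression_matrix(normed[, cols, drop = FALSE], matrices[[i]]$meta)
  })
}

#' Fit per-cancer module-activation centroids
#'
#' Each cancer's centroid is its module activation profile: the vector of
#' per-module activations averaged over the cancer's training tumor
#' samples. A cancer is thereby a point in N-dimensional module space.
#'
#' @param expr An [expression_matrix()] of training samples.
#' @param modules A `gene_modules` list.
#' @param samples Optional character vector restricting which tumor samples
#'   are used (defaults to all tumor samples in the metadata).
#' @return A matrix, cancers x modules, rownames = cancer labels.
#' @export
centroid_fit <- function(expr, modules, samples = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  meta <- expr$meta
  use <- meta$sample_id[meta$condition == "tumor"]
  if (!is.null(samples)) use <- intersect(use, samples)
  if (length(use) == 0) stop("no training tumor samples")
  act <- module_activation_matrix(expr, modules)[, use, drop = FALSE]
  labels <- meta$cancer_label[match(use, meta$sample_id)]
  cancers <- sort(unique(labels))
  cent <- t(vapply(cancers, function(cl)
    rowMeans(act[, labels == cl, drop = FALSE]), numeric(nrow(act))))
  rownames(cent) <- cancers
  cent
}

#' Euclidean distance in module-activation space
#'
#' @param centroid Numeric vector (a cancer's module profile).
#' @param position Numeric vector (a sample's module profile), same length.
#' @return Non-negative scalar: `sqrt(sum((centroid - position)^2))`.
#' @export
module_distance <- function(centroid, position) {
  if (length(centroid) != length(position))
    stop("centroid and position must have equal length")
  sqrt(sum((centroid - position)^2))
}

#' Classify a sample by its nearest cancer centroid
#'
#' @param centroids Cancers x modules matrix from [centroid_fit()].
#' @param position Numeric vector: the sample's module activations.
#' @return The label of the closest centroid; ties are broken by
#'   lexicographic label order.
#' @export
classify_sample <- function(centroids, position) {
  if (nrow(centroids) < 1) stop("need at least one centroid")
  d <- apply(centroids, 1, module_distance, position = position)
  ord <- order(d, rownames(centroids))  # lexicographic tie-break
  rownames(centroids)[ord[1]]
}

#' ROC curve from a distance ranking
#'
#' Builds a one-vs-rest ROC for one cancer: test samples are ranked by
#' distance to the cancer's centroid (smaller = more positive) and the
#' true-positive rate is tracked against the false-positive rate as the
#' distance threshold sweeps the ranking. Tied distances move the curve in
#' a single step (diagonal segment), which makes the trapezoidal AUC equal
#' the Mann-Whitney rank statistic with the usual half-credit for ties.
#' Sensitivity is read off at the curve point with the smallest specificity
#' still at or above `operating_specificity`.
#'
#' @param distances Numeric vector of distances of test samples to the
#'   centroid.
#' @param is_positive Logical vector: is each test sample of the centroid's
#'   cancer type? At least one `TRUE` and one `FALSE` required.
#' @param operating_specificity Specificity at which sensitivity is
#'   reported.
#' @return A list of class `roc_result`: `curve` (data frame `fpr`, `tpr`),
#'   `auc`, `sensitivity_at_spec`, `operating_specificity`,
#'   `achieved_specificity`.
#' @export
roc_from_ranking <- function(distances, is_positive,
                             operating_specificity = 0.7) {
  stopifnot(length(distances) == length(is_positive))
  is_positive <- as.logical(is_positive)
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative test sample")
  thresholds <- sort(unique(distances))
  fpr <- c(0, vapply(thresholds, function(t)
    sum(distances <= t & !is_positive), numeric(1)) / n_neg)
  tpr <- c(0, vapply(thresholds, function(t)
    sum(distances <= t & is_positive), numeric(1)) / n_pos)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  spec <- 1 - fpr
  ok <- which(spec >= operating_specificity)
  at <- ok[which.min(spec[ok])]  # most liberal point meeting the target
  structure(list(curve = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc,
                 sensitivity_at_spec = tpr[at],
                 operating_specificity = operating_specificity,
                 achieved_specificity = spec[at]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f, sensitivity %.3f at specificity %.2f (achieved %.2f)\n",
              x$auc, x$sensitivity_at_spec, x$operating_specificity,
              x$achieved_specificity))
  invisible(x)
}

# Stratified half split of tumor samples: returns list(train, test) of
# sample ids. With equalize = TRUE each cancer contributes the same number
# of positives to both halves (floor(n/2) each, remainder dropped).
split_half <- function(meta, equalize = FALSE) {
  tumor <- meta[meta$condition == "tumor", , drop = FALSE]
  train <- character(0); test <- character(0)
  for (cl in unique(tumor$cancer_label)) {
    ids <- tumor$sample_id[tumor$cancer_label == cl]
    ids <- sample(ids)
    n <- length(ids)
    n_train <- if (equalize) floor(n / 2) else ceiling(n / 2)
    n_test <- if (equalize) floor(n / 2) else n - n_train
    train <- c(train, ids[seq_len(n_train)])
    if (n_test > 0) test <- c(test, ids[n_train + seq_len(n_test)])
  }
  list(train = train, test = test)
}

#' Random-subsample cross-validation of the centroid classifier
#'
#' Repeats, `n_trials` times: split the tumor samples in half at random
#' (stratified by cancer); fit per-cancer centroids on the training half;
#' rank the test half by distance to each centroid; accumulate a
#' one-vs-rest ROC per cancer. Reported metrics (AUC, sensitivity at the
#' operating specificity) are means over trials.
#'
#' Two modes follow the two validation protocols. In `"internal"` mode the
#' test half comes from the same cohort; by default the modules themselves
#' are re-discovered on each training half (`refit_modules = TRUE`), with a
#' fast path that keeps them fixed. In `"external"` mode module genes stay
#' fixed, the external cohort is test-only (training samples are always
#' drawn from the internal cohort), the internal and external matrices are
#' jointly quantile-normalized beforehand, and optional background
#' negatives — samples of cancer types the model was never trained on — are
#' appended to the test set only.
#'
#' @param expr Internal cohort [expression_matrix()].
#' @param modules A `gene_modules` list (the fixed modules).
#' @param n_trials Number of random splits.
#' @param mode `"internal"` or `"external"`.
#' @param refit_modules Internal mode only: re-run module discovery on each
#'   training half. `FALSE` keeps `modules` fixed (fast path).
#' @param external External cohort [expression_matrix()] (required in
#'   external mode); its samples are used as the test set.
#' @param negatives Optional [expression_matrix()] of background-negative
#'   samples (external mode), appended to the test set only.
#' @param equalize_positives Force each cancer to contribute equally many
#'   training samples per trial (floor of half the smallest group).
#' @param operating_specificity Specificity at which sensitivity is read.
#' @param rng_seed Integer seed; the full run is reproducible.
#' @param refit_args List of arguments passed to [discover_modules()] when
#'   `refit_modules = TRUE`.
#' @return A list of class `cv_result`: `per_cancer` (data frame with mean
#'   `auc`, `sensitivity`, `specificity`, `n_trials` per cancer),
#'   `mean_auc`, `mean_sensitivity`, `mode`, `n_trials`.
#' @export
run_cv <- function(expr, modules, n_trials = 200,
                   mode = c("internal", "external"),
                   refit_modules = (mode == "internal"),
                   external = NULL, negatives = NULL,
                   equalize_positives = FALSE,
                   operating_specificity = 0.7, rng_seed = 1L,
                   refit_args = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expression_matrix"), n_trials >= 1)
  if (mode == "external") {
    if (is.null(external)) stop("external mode requires an external cohort")
    refit_modules <- FALSE
    mats <- list(expr, external)
    if (!is.null(negatives)) mats <- c(mats, list(negatives))
    mats <- quantile_normalize_joint(mats)
    expr <- mats[[1]]; external <- mats[[2]]
    if (!is.null(negatives)) negatives <- mats[[3]]
  }
  meta <- expr$meta
  cancers <- sort(unique(meta$cancer_label[meta$condition == "tumor"]))
  set.seed(rng_seed)
  acc <- lapply(cancers, function(cl)
    list(auc = numeric(0), sens = numeric(0), spec = numeric(0)))
  names(acc) <- cancers
  for (trial in seq_len(n_trials)) {
    halves <- split_half(meta, equalize = equalize_positives)
    mods <- modules
    if (refit_modules) {
      train_expr <- expression_matrix(
        expr$values[, halves$train, drop = FALSE],
        meta[match(halves$train, meta$sample_id), , drop = FALSE])
      mods <- try(do.call(discover_modules,
                          c(list(expr = train_expr), refit_args)),
                  silent = TRUE)
      if (inherits(mods, "try-error") || length(mods) == 0) next
    }
    cent <- centroid_fit(expr, mods, samples = halves$train)
    if (mode == "internal") {
      test_ids <- halves$test
      test_act <- module_activation_matrix(expr, mods)[, test_ids,
                                                       drop = FALSE]
      test_labels <- meta$cancer_label[match(test_ids, meta$sample_id)]
    } else {
      test_act <- module_activation_matrix(external, mods)
      test_labels <- external$meta$cancer_label[
        match(colnames(test_act), external$meta$sample_id)]
      if (!is.null(negatives)) {
        neg_act <- module_activation_matrix(negatives, mods)
        test_act <- cbind(test_act, neg_act)
        test_labels <- c(test_labels, negatives$meta$cancer_label[
          match(colnames(neg_act), negatives$meta$sample_id)])
      }
    }
    for (cl in intersect(cancers, rownames(cent))) {
      is_pos <- test_labels == cl
      if (!any(is_pos) || all(is_pos)) next
      d <- apply(test_act, 2, module_distance, centroid = cent[cl, ])
      roc <- roc_from_ranking(d, is_pos, operating_specificity)
      acc[[cl]]$auc <- c(acc[[cl]]$auc, roc$auc)
      acc[[cl]]$sens <- c(acc[[cl]]$sens, roc$sensitivity_at_spec)
      acc[[cl]]$spec <- c(acc[[cl]]$spec, roc$achieved_specificity)
    }
  }
  per_cancer <- do.call(rbind, lapply(cancers, function(cl) data.frame(
    cancer_label = cl,
    auc = mean(acc[[cl]]$auc),
    sensitivity = mean(acc[[cl]]$sens),
    specificity = mean(acc[[cl]]$spec),
    n_trials = length(acc[[cl]]$auc),
    stringsAsFactors = FALSE)))
  structure(list(per_cancer = per_cancer,
                 mean_auc = mean(per_cancer$auc),
                 mean_sensitivity = mean(per_cancer$sensitivity),
                 mode = mode, n_trials = n_trials),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s mode, %d trials): mean AUC %.3f, mean sensitivity %.3f\n",
              x$mode, x$n_trials, x$mean_auc, x$mean_sensitivity))
  print(x$per_cancer, row.names = FALSE)
  invisible(x)
}
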