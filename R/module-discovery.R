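#' Seed gene sets by size-bounded hierarchical clustering
#'
#' Clusters gene rows of the expression matrix by agglomerative hierarchical
#' clustering (1 - Pearson correlation distance, average linkage) and cuts
#' the dendrogram at the level yielding the most clusters whose sizes lie
#' strictly inside `(min_size, max_size)`. Clusters outside the bounds at
#' that cut are discarded. When several cut levels tie, the smallest cut
#' height (largest number of clusters) wins, so the result is deterministic.
#'
#' The size bounds default to the approximate gene count of a curated
#' pathway (more than 10, fewer than 100 genes), so each seed is plausibly a
#' single biological process.
#'
#' @param expr An [expression_matrix()].
#' @param min_size,max_size Exclusive size bounds for an admissible cluster.
#' @param method Linkage method passed to [stats::hclust()].
#' @return An object of class `seed_set`: list with `seeds` (list of
#'   character vectors of gene identifiers) and `provenance`.
#' @export
seed_clusters <- function(expr, min_size = 10, max_size = 100,
                          method = "average") {
  stopifnot(inherits(expr, "expression_matrix"))
  if (min_size < 2) stop("`min_size` must be >= 2")
  if (max_size <= min_size) stop("`max_size` must exceed `min_size`")
  n <- nrow(expr$values)
  if (n <= min_size)
    stop("matrix has too few genes (", n, ") for the size bounds")
  cors <- stats::cor(t(expr$values))
  d <- stats::as.dist(1 - cors)
  hc <- stats::hclust(d, method = method)
  ks <- 2:n
  memb <- stats::cutree(hc, k = ks)
  best_k <- NA_integer_
  best_count <- -1L
  for (j in seq_along(ks)) {
    sizes <- tabulate(memb[, j])
    count <- sum(sizes > min_size & sizes < max_size)
    # strict improvement only: among ties prefer the largest k seen first?
    # heights decrease with k, so to take the smallest cut height we must
    # prefer larger k on ties -> use >= for count comparison.
    if (count >= best_count && count > 0) {
      if (count > best_count || is.na(best_k) || ks[j] > best_k) {
        best_count <- count
        best_k <- ks[j]
      }
    }
  }
  if (is.na(best_k))
    stop("no dendrogram cut yields a cluster inside the size bounds")
  assignment <- memb[, best_k - 1L]
  sizes <- tabulate(assignment)
  keep_ids <- which(sizes > min_size & sizes < max_size)
  seeds <- lapply(keep_ids, function(id) rownames(expr$values)[assignment == id])
  structure(list(
    seeds = seeds,
    provenance = list(n_base_clusters = length(seeds), n_random_added = 0L,
                      n_repeats = 1L, rng_seed = NA_integer_, cut_k = best_k)
  ), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  sizes <- lengths(x$seeds)
  cat(sprintf("seed_set: %d seeds (sizes %d-%d)\n",
              length(x$seeds), min(sizes), max(sizes)))
  invisible(x)
}

#' Expand seed gene sets with random genes
#'
#' Each base seed is replicated `n_repeats` times; every replicate is the
#' union of the base seed with `n_random` genes drawn uniformly without
#' replacement from the gene universe. Randomizing the starting points lets
#' the downstream refinement escape the particular hierarchical cut and
#' explore many basins of attraction.
#'
#' @param seeds A `seed_set` from [seed_clusters()].
#' @param genes Character vector: the gene universe to draw from (the
#'   expression matrix rownames).
#' @param n_random Number of random genes added per replicate.
#' @param n_repeats Number of replicates per base seed.
#' @param rng_seed Integer seed making the draw reproducible.
#' @return A `seed_set` with `length(seeds) * n_repeats` seeds.
#' @export
expand_seeds <- function(seeds, genes, n_random = 100, n_repeats = 481,
                         rng_seed = 1L) {
  stopifnot(inherits(seeds, "seed_set"))
  if (n_random > length(genes))
    stop("`n_random` exceeds the number of genes")
  set.seed(rng_seed)
  out <- vector("list", length(seeds$seeds) * n_repeats)
  k <- 0L
  for (r in seq_len(n_repeats)) {
    for (s in seeds$seeds) {
      k <- k + 1L
      extra <- if (n_random > 0) sample(genes, n_random) else character(0)
      out[[k]] <- union(s, extra)
    }
  }
  structure(list(
    seeds = out,
    provenance = list(n_base_clusters = length(seeds$seeds),
                      n_random_added = n_random, n_repeats = n_repeats,
                      rng_seed = rng_seed)
  ), class = "seed_set")
}

# One ISA run from a single seed. Returns a character vector of genes at the
# fixed point, or NULL if the iteration emptied out or failed to converge.
isa_one <- function(z, z_gene_std, seed_genes, gene_threshold,
                    sample_threshold, max_iter, convergence_tol) {
  genes <- intersect(seed_genes, rownames(z))
  if (length(genes) == 0) return(NULL)
  current <- genes
  for (iter in seq_len(max_iter)) {
    # sample scoring: mean expression over the current gene set
    s_scores <- colMeans(z[current, , drop = FALSE])
    s_keep <- s_scores > mean(s_scores) + sample_threshold * stats::sd(s_scores)
    if (!any(s_keep)) return(NULL)
    # gene scoring: mean row-standardized expression over selected samples
    g_scores <- rowMeans(z_gene_std[, s_keep, drop = FALSE])
    nxt <- rownames(z)[g_scores > mean(g_scores) +
                         gene_threshold * stats::sd(g_scores)]
    if (length(nxt) == 0) return(NULL)
    inter <- length(intersect(current, nxt))
    overlap <- inter / length(union(current, nxt))
    if (overlap >= 1 - convergence_tol) return(sort(nxt))
    current <- nxt
  }
  NULL
}

#' Refine seeds into co-expression modules (Iterative Signature Algorithm)
#'
#' For each seed, alternates two thresholded averaging steps until a fixed
#' point: (i) samples are scored by the mean expression of the current gene
#' set and kept when they exceed the score mean by `sample_threshold`
#' standard deviations; (ii) genes are scored by their mean (per-gene
#' standardized) expression over the selected samples and kept when they
#' exceed the gene-score mean by `gene_threshold` standard deviations.
#' Seeds that empty out or fail to reach a fixed point within `max_iter`
#' iterations are dropped. Converged gene sets are deduplicated by merging
#' (union) any pair with Jaccard similarity at least `merge_jaccard`,
#' repeated to closure. Each merged module's seed support — the fraction of
#' converged seeds whose fixed point fell into it — is then used as a
#' robustness screen: randomized seeds land on a genuine co-expression
#' signature from many starting points, while spurious fixed points of the
#' noise attract isolated seeds, so modules with support below
#' `min_support` are discarded. Survivors are sorted by size (decreasing)
#' and renumbered from 1.
#'
#' The input is already column-standardized; gene scoring uses an
#' additional per-gene (row) standardization, the usual dual normalization
#' of signature-style biclustering.
#'
#' @param expr An [expression_matrix()].
#' @param seeds A `seed_set`.
#' @param gene_threshold,sample_threshold Score cutoffs in SD units.
#' @param max_iter Iteration cap per seed.
#' @param convergence_tol Allowed Jaccard distance between consecutive gene
#'   sets at convergence; 0 demands an exact fixed point.
#' @param merge_jaccard Jaccard similarity at or above which two converged
#'   gene sets are merged during deduplication.
#' @param min_support Minimum fraction of converged seeds a merged module
#'   must have attracted to be kept; 0 disables the screen.
#' @return A list of class `gene_modules`: each element is a list with
#'   `module_id`, `genes` (sorted character vector), `score` (mean
#'   within-module pairwise gene correlation) and `support` (fraction of
#'   converged seeds attracted).
#' @export
isa_refine <- function(expr, seeds, gene_threshold = 2.0,
                       sample_threshold = 1.0, max_iter = 100,
                       convergence_tol = 0, merge_jaccard = 0.7,
                       min_support = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(seeds, "seed_set"))
  if (max_iter < 1) stop("`max_iter` must be >= 1")
  if (merge_jaccard <= 0 || merge_jaccard > 1)
    stop("`merge_jaccard` must be in (0, 1]")
  z <- expr$values
  row_sd <- apply(z, 1, stats::sd)
  row_sd[row_sd == 0] <- 1  # constant rows contribute zero signal, not NaN
  z_gene_std <- (z - rowMeans(z)) / row_sd
  converged <- list()
  support <- integer(0)   # seeds attracted per distinct fixed point
  seen <- character(0)
  n_conv <- 0L
  for (s in seeds$seeds) {
    res <- isa_one(z, z_gene_std, s, gene_threshold, sample_threshold,
                   max_iter, convergence_tol)
    if (is.null(res)) next
    n_conv <- n_conv + 1L
    key <- paste(res, collapse = "\r")
    hit <- match(key, seen)
    if (is.na(hit)) {
      seen <- c(seen, key)
      converged[[length(converged) + 1L]] <- res
      support <- c(support, 1L)
    } else {
      support[hit] <- support[hit] + 1L
    }
  }
  if (length(converged) == 0) {
    warning("no seeds converged to a module")
    return(structure(list(), class = "gene_modules"))
  }
  merged <- merge_gene_sets(converged, merge_jaccard, support)
  frac <- attr(merged, "support") / n_conv
  keep <- frac >= min_support
  if (!any(keep)) {
    warning("no module met the seed-support screen")
    return(structure(list(), class = "gene_modules"))
  }
  frac <- frac[keep]
  merged <- merged[keep]
  ord <- order(lengths(merged), decreasing = TRUE)
  merged <- merged[ord]
  frac <- frac[ord]
  mods <- lapply(seq_along(merged), function(i) {
    g <- merged[[i]]
    score <- if (length(g) > 1) {
      cm <- stats::cor(t(z[g, , drop = FALSE]))
      mean(cm[upper.tri(cm)])
    } else NA_real_
    list(module_id = i, genes = g, score = score, support = frac[i])
  })
  structure(mods, class = "gene_modules")
}

# Jaccard-closure merging of a list of gene sets: repeatedly union any pair
# with similarity >= threshold until no pair qualifies. Optional per-set
# support counts are summed on merge and returned as attr "support".
merge_gene_sets <- function(sets, threshold, support = NULL) {
  if (is.null(support)) support <- rep(1L, length(sets))
  repeat {
    if (length(sets) <= 1) break
    merged_any <- FALSE
    i <- 1
    while (i < length(sets)) {
      j <- i + 1
      while (j <= length(sets)) {
        jac <- jaccard(sets[[i]], sets[[j]])
        if (jac >= threshold) {
          sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
          support[i] <- support[i] + support[j]
          sets[[j]] <- NULL
          support <- support[-j]
          merged_any <- TRUE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
    if (!merged_any) break
  }
  attr(sets, "support") <- support
  sets
}

#' Jaccard similarity of two sets
#'
#' @param a,b Vectors treated as sets.
#' @return `|a intersect b| / |a union b|`; 0 when both are empty.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' @export
print.gene_modules <- function(x, ...) {
  if (length(x) == 0) {
    cat("gene_modules: none\n")
    return(invisible(x))
  }
  cat(sprintf("gene_modules: %d modules, sizes %s\n", length(x),
              paste(vapply(x, function(m) length(m$genes), 1L),
                    collapse = "/")))
  invisible(x)
}

#' Discover co-expression modules from an expression matrix
#'
#' Convenience wrapper running [seed_clusters()], [expand_seeds()] and
#' [isa_refine()] with one call.
#'
#' @param expr An [expression_matrix()].
#' @param min_size,max_size Seed-cluster size bounds.
#' @param n_random,n_repeats,rng_seed Seed-expansion parameters.
#' @param ... Passed on to [isa_refine()].
#' @return A `gene_modules` list.
#' @export
discover_modules <- function(expr, min_size = 10, max_size = 100,
                             n_random = 100, n_repeats = 481, rng_seed = 1L,
                             ...) {
  base <- seed_clusters(expr, min_size, max_size)
  expanded <- expand_seeds(base, rownames(expr$values), n_random, n_repeats,
                           rng_seed)
  isa_refine(expr, expanded, ...)
}

#' Read a module table (module_id, gene_id TSV)
#'
#' @param file Path to a TSV with columns `module_id` and `gene_id`.
#' @return A `gene_modules` list (scores are `NA`; recompute against an
#'   expression matrix if needed).
#' @export
read_modules <- function(file) {
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("module_id", "gene_id") %in% names(tab)))
    stop("module file must have columns module_id and gene_id")
  ids <- sort(unique(tab$module_id))
  mods <- lapply(seq_along(ids), function(i) {
    list(module_id = i, genes = sort(unique(tab$gene_id[tab$module_id == ids[i]])),
         score = NA_real_)
  })
  structure(mods, class = "gene_modules")
}

#' Write modules as a module_id, gene_id TSV
#'
#' @param modules A `gene_modules` list.
#' @param file Output path.
#' @return Invisibly, `modules`.
#' @export
write_modules <- function(modules, file) {
  stopifnot(inherits(modules, "gene_modules"))
  tab <- do.call(rbind, lapply(modules, function(m)
    data.frame(module_id = m$module_id, gene_id = m$genes,
               stringsAsFactors = FALSE)))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(modules)
}
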