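#' Build the module x annotation incidence matrix
#'
#' From a long annotation table (one row per annotation-module association
#' with its BH-corrected enrichment p-value), keeps associations with
#' `bh_p < p_cut` and assembles a binary matrix: rows are annotations with
#' at least one surviving association, columns are modules, entry 1 iff the
#' association survives. Per-row module counts and mean p-values summarize
#' how widely shared each annotation is.
#'
#' @param table Data frame with columns `annotation_id`, `module_id`,
#'   `bh_p` (and optionally `annotation_name`).
#' @param p_cut Significance cutoff in (0, 1).
#' @return A list: `matrix` (binary, annotations x modules), `summary`
#'   (data frame `annotation_id`, `n_modules`, `mean_bh_p`), plus counts
#'   `n_shared` (annotations on 2+ modules) and `n_specific` (exactly 1).
#' @export
build_annotation_matrix <- function(table, p_cut = 0.005) {
  if (p_cut <= 0 || p_cut >= 1) stop("`p_cut` must be in (0, 1)")
  required <- c("annotation_id", "module_id", "bh_p")
  if (!all(required %in% names(table)))
    stop("annotation table needs columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(table[, c("annotation_id", "module_id")]))
    stop("(annotation, module) pairs must be unique")
  hit <- table[table$bh_p < p_cut, , drop = FALSE]
  if (nrow(hit) == 0) {
    return(list(matrix = matrix(0, 0, 0),
                summary = data.frame(annotation_id = character(0),
                                     n_modules = integer(0),
                                     mean_bh_p = numeric(0)),
                n_shared = 0L, n_specific = 0L))
  }
  anns <- sort(unique(hit$annotation_id))
  mods <- sort(unique(table$module_id))
  m <- matrix(0L, length(anns), length(mods),
              dimnames = list(anns, paste0("module_", mods)))
  m[cbind(match(hit$annotation_id, anns), match(hit$module_id, mods))] <- 1L
  n_modules <- rowSums(m)
  mean_p <- vapply(anns, function(a)
    mean(hit$bh_p[hit$annotation_id == a]), numeric(1))
  list(matrix = m,
       summary = data.frame(annotation_id = anns,
                            n_modules = as.integer(n_modules),
                            mean_bh_p = unname(mean_p),
                            stringsAsFactors = FALSE, row.names = NULL),
       n_shared = sum(n_modules >= 2),
       n_specific = sum(n_modules == 1))
}

#' Select biomarker candidates from primary-module genes
#'
#' For each cancer, candidates are the genes of its primary module whose
#' activation over the cancer's tumor samples strictly exceeds
#' `z_threshold` (default 1.5, roughly the 95% confidence level for a Z
#' score relative to the per-sample background). Candidates are sorted
#' decreasing by activation within each cancer.
#'
#' @param gene_records Data frame as from [gene_activation_records()],
#'   covering each cancer's primary-module genes (rows for several cancers
#'   may be stacked).
#' @param primary_module_map Named integer vector: cancer label ->
#'   primary module id (entries may be `NA`; such cancers yield no
#'   candidates).
#' @param z_threshold Strict activation cutoff.
#' @return The selected rows with columns `module_id` and `selected = TRUE`
#'   added, sorted by cancer then decreasing activation.
#' @export
select_biomarkers <- function(gene_records, primary_module_map,
                              z_threshold = 1.5) {
  keep <- gene_records$activation_cancer > z_threshold &
    gene_records$cancer_label %in% names(primary_module_map)[
      !is.na(primary_module_map)]
  out <- gene_records[keep, , drop = FALSE]
  out$module_id <- unname(primary_module_map[out$cancer_label])
  out$selected <- rep(TRUE, nrow(out))
  out[order(out$cancer_label, -out$activation_cancer), , drop = FALSE]
}

#' Flag high-novelty drug-target candidates
#'
#' Applies the target-novelty screen to selected biomarkers joined with
#' their evidence fields. A record is `high_novelty` when all of the
#' following hold: activation above `z_threshold`; if the cancer has valid
#' matched normals (same tissue as the tumor), BH-corrected tumor-vs-normal
#' p below `p_cut`; IDG target development level `Tbio` or `Tdark`; and,
#' for `Tbio` targets only, CTD inference score below `ctd_inference_max`
#' and CTD reference count below `ctd_refs_max` (`Tdark` targets, being
#' essentially unstudied, are exempt from the CTD cuts). Missing CTD fields
#' are treated as 0 (maximally novel) and flagged.
#'
#' @param records Data frame of biomarker records carrying
#'   `activation_cancer`, `p_bh`, `idg_class`, `ctd_inference`, `ctd_refs`.
#' @param has_valid_normals Logical: apply the p-value criterion (only
#'   meaningful when the normals share the tumor's tissue of origin).
#' @param z_threshold,p_cut,ctd_inference_max,ctd_refs_max Screen cutoffs.
#' @return `records` with logical columns `high_novelty` and
#'   `ctd_imputed` added.
#' @export
prioritize_novelty <- function(records, has_valid_normals = FALSE,
                               z_threshold = 1.5, p_cut = 0.05,
                               ctd_inference_max = 10, ctd_refs_max = 5) {
  required <- c("activation_cancer", "idg_class", "ctd_inference", "ctd_refs")
  if (!all(required %in% names(records)))
    stop("records need columns: ", paste(required, collapse = ", "))
  ctd_imputed <- is.na(records$ctd_inference) | is.na(records$ctd_refs)
  inf <- ifelse(is.na(records$ctd_inference), 0, records$ctd_inference)
  refs <- ifelse(is.na(records$ctd_refs), 0, records$ctd_refs)
  ok <- records$activation_cancer > z_threshold &
    records$idg_class %in% c("Tbio", "Tdark")
  if (has_valid_normals) {
    if (!"p_bh" %in% names(records))
      stop("p_bh column required when `has_valid_normals`")
    ok <- ok & !is.na(records$p_bh) & records$p_bh < p_cut
  }
  tbio_cut <- records$idg_class != "Tbio" |
    (inf < ctd_inference_max & refs < ctd_refs_max)
  records$high_novelty <- ok & tbio_cut
  records$ctd_imputed <- ctd_imputed
  records
}

#' Read a gene evidence table
#'
#' TSV with columns `gene_id`, `idg_class` (Tclin/Tchem/Tbio/Tdark),
#' `ctd_inference`, `ctd_refs`, `in_cosmic`, `in_oncokb`.
#'
#' @param file Path to the TSV.
#' @return A data frame.
#' @export
read_evidence_table <- function(file) {
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("gene_id", "idg_class", "ctd_inference", "ctd_refs",
                "in_cosmic", "in_oncokb")
  if (!all(required %in% names(tab)))
    stop("evidence table needs columns: ", paste(required, collapse = ", "))
  tab
}

#' Hypergeometric annotation enrichment (local utility)
#'
#' An offline alternative to web-based functional enrichment: given a
#' gene -> term map, tests each term for over-representation in a gene set
#' against the gene universe with the hypergeometric distribution, and
#' BH-corrects across terms. Provided as a convenience; the analysis
#' proper consumes externally computed annotation tables.
#'
#' @param genes Character vector: the gene set (e.g. a module).
#' @param term_map Data frame with columns `gene_id`, `term_id` (and
#'   optionally `term_name`).
#' @param universe Character vector of all genes considered (defaults to
#'   all genes in `term_map`).
#' @return Data frame `term_id`, `n_set`, `n_term`, `p`, `bh_p`, sorted by
#'   `p`.
#' @export
enrich_hypergeometric <- function(genes, term_map, universe = NULL) {
  if (is.null(universe)) universe <- unique(term_map$gene_id)
  genes <- intersect(genes, universe)
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- unique(term_map$term_id)
  n_u <- length(universe); n_g <- length(genes)
  res <- do.call(rbind, lapply(terms, function(tm) {
    members <- unique(term_map$gene_id[term_map$term_id == tm])
    k <- length(intersect(genes, members))
    p <- stats::phyper(k - 1, length(members), n_u - length(members), n_g,
                       lower.tail = FALSE)
    data.frame(term_id = tm, n_set = k, n_term = length(members), p = p,
               stringsAsFactors = FALSE)
  }))
  res$bh_p <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}
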