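#' Map biological risk genes to drugs
#'
#' Emits one gene-drug edge per (gene, drug) pair where the drug-target
#' table links the drug to a gene of the input list and the drug passes
#' the query filters: a pharmacological action on the target (optional)
#' and membership in at least one allowed approval group. Duplicate
#' target rows collapse to a single edge.
#'
#' @param genes character vector of gene symbols (the biological risk
#'   genes).
#' @param targets drug-target tibble (see [read_drug_target_table()]).
#' @param require_pharm_action drop target rows without a known
#'   pharmacological action (default `TRUE`).
#' @param allowed_groups approval groups that qualify a drug (default
#'   approved, investigational, experimental).
#' @return tibble of edges: `gene`, `drug_id`, `drug_name`, `action`.
#' @export
map_genes_to_drugs <- function(genes, targets,
                               require_pharm_action = TRUE,
                               allowed_groups = c("approved", "investigational",
                                                  "experimental")) {
  stopifnot(length(genes) > 0)
  genes <- unique(normalize_symbol(genes))
  ok_group <- vapply(targets$groups, function(g) length(intersect(g, allowed_groups)) > 0,
                     logical(1))
  keep <- targets$target_gene %in% genes & ok_group &
    (!require_pharm_action | targets$has_pharmacological_action)
  hit <- targets[keep, , drop = FALSE]
  edges <- tibble::tibble(gene = hit$target_gene, drug_id = hit$drug_id,
                          drug_name = hit$drug_name, action = hit$action)
  edges[!duplicated(edges[c("gene", "drug_id")]), , drop = FALSE]
}

#' Druggable genes of an edge list
#'
#' The distinct genes appearing in at least one gene-drug edge.
#'
#' @param edges tibble from [map_genes_to_drugs()].
#' @return sorted character vector of gene symbols.
#' @export
druggable_genes <- function(edges) {
  sort(unique(edges$gene))
}
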