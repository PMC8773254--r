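CRITERION_NAMES <- c("missense", "cis_eqtl", "ko_mouse", "ppi_gobp", "kegg")

#' Criterion 1: genes with a missense risk variant
#'
#' A gene earns the missense point when one of its own risk variants
#' (seed or LD proxy, at the same r2 threshold used for gene mapping) is
#' annotated as a missense mutation.
#'
#' @param risk a `risk_gene_set` (see [map_to_genes()]).
#' @return character vector of gene symbols.
#' @export
criterion_missense <- function(risk) {
  stopifnot(inherits(risk, "risk_gene_set"))
  risk$genes[risk$gene_missense[risk$genes]]
}

#' Criterion 2: genes with a significant cis-eQTL in the target tissue
#'
#' The significant eQTL variant must be one of the gene's own risk
#' variants (seed or proxy), not any variant genome-wide, and the eQTL
#' must be observed in the requested tissue.
#'
#' @param risk a `risk_gene_set`.
#' @param eqtl eQTL tibble (see [read_eqtl_table()]).
#' @param tissue tissue name to match exactly (default `"lung"`).
#' @return character vector of gene symbols.
#' @export
criterion_eqtl <- function(risk, eqtl, tissue = "lung") {
  stopifnot(inherits(risk, "risk_gene_set"), nzchar(tissue))
  sig <- eqtl[eqtl$is_significant & eqtl$tissue == tissue, , drop = FALSE]
  hits <- vapply(risk$genes, function(g) {
    any(sig$gene == g & sig$variant_id %in% risk$gene_to_variants[[g]])
  }, logical(1))
  risk$genes[hits]
}

#' Criteria 3-5: genes in significantly enriched sets of one collection
#'
#' A gene earns the point for a namespace (mouse-knockout phenotype, GO
#' biological process, or KEGG pathway) when it belongs to at least one
#' gene set flagged enriched (FDR q below threshold) in the ORA of that
#' collection run with the risk genes as query.
#'
#' @param risk a `risk_gene_set`.
#' @param collection the `gene_set_collection` that was tested.
#' @param ora the [run_ora()] result for that collection.
#' @return character vector of gene symbols.
#' @export
criterion_ora <- function(risk, collection, ora) {
  stopifnot(inherits(risk, "risk_gene_set"),
            inherits(collection, "gene_set_collection"))
  enriched_ids <- ora$set_id[ora$enriched]
  if (length(enriched_ids) == 0) return(character(0))
  members <- unique(unlist(lapply(collection$sets[enriched_ids], `[[`, "genes"),
                           use.names = FALSE))
  intersect(risk$genes, members)
}

#' Assemble the genes x 5-criteria indicator matrix
#'
#' Column order is fixed: missense, cis_eqtl, ko_mouse, ppi_gobp, kegg.
#' The per-gene score is the row sum (0-5).
#'
#' @param risk a `risk_gene_set`.
#' @param per_criterion named list of five character vectors (names as
#'   above), each a subset of `risk$genes`.
#' @return tibble of class `criterion_matrix`: `gene`, the five 0/1
#'   indicator columns, `score`.
#' @export
build_matrix <- function(risk, per_criterion) {
  stopifnot(inherits(risk, "risk_gene_set"),
            setequal(names(per_criterion), CRITERION_NAMES))
  for (crit in CRITERION_NAMES) {
    outside <- setdiff(per_criterion[[crit]], risk$genes)
    if (length(outside) > 0) {
      stop(sprintf("criterion '%s' contains gene(s) outside the risk set: %s",
                   crit, paste(utils::head(outside, 3), collapse = ", ")),
           call. = FALSE)
    }
  }
  mat <- tibble::tibble(gene = risk$genes)
  for (crit in CRITERION_NAMES) {
    mat[[crit]] <- as.integer(mat$gene %in% per_criterion[[crit]])
  }
  mat$score <- as.integer(rowSums(mat[CRITERION_NAMES]))
  class(mat) <- c("criterion_matrix", class(mat))
  mat
}

#' Select biological risk genes by minimum score
#'
#' Genes meeting at least `min_score` of the five criteria (default 2,
#' the "biological risk gene" definition), ordered by descending score
#' then gene symbol for reproducible reports. The boundary is inclusive.
#'
#' @param matrix a `criterion_matrix`.
#' @param min_score integer in 0..5.
#' @return character vector of gene symbols.
#' @export
select_biological <- function(matrix, min_score = 2) {
  stopifnot(min_score >= 0, min_score <= 5)
  hit <- matrix[matrix$score >= min_score, , drop = FALSE]
  hit$gene[order(-hit$score, hit$gene, method = "radix")]
}

#' Histogram of criterion scores
#' @param matrix a `criterion_matrix`.
#' @return tibble with `score` (0..5) and `n_genes`; counts sum to the
#'   number of genes.
#' @export
score_histogram <- function(matrix) {
  tibble::tibble(score = 0:5,
                 n_genes = vapply(0:5, function(s) sum(matrix$score == s), integer(1)))
}

#' Pairwise phi correlation between the five criteria
#'
#' The correlogram of the indicator columns. Constant columns (all zeros
#' or all ones) have undefined phi and yield `NA` in their row/column;
#' the diagonal is 1 where defined.
#'
#' @param matrix a `criterion_matrix` with >= 2 genes.
#' @return symmetric 5x5 numeric matrix with criterion dimnames.
#' @export
criterion_correlogram <- function(matrix) {
  stopifnot(nrow(matrix) >= 2)
  out <- matrix(NA_real_, 5, 5, dimnames = list(CRITERION_NAMES, CRITERION_NAMES))
  for (i in seq_along(CRITERION_NAMES)) {
    for (j in i:length(CRITERION_NAMES)) {
      phi <- phi_correlation(matrix[[CRITERION_NAMES[i]]], matrix[[CRITERION_NAMES[j]]])
      out[i, j] <- phi
      out[j, i] <- phi
    }
  }
  out
}

#' Write the criterion matrix as TSV
#' @param matrix a `criterion_matrix`.
#' @param path output path.
#' @export
write_criterion_matrix <- function(matrix, path) {
  readr::write_tsv(tibble::as_tibble(matrix), path, progress = FALSE)
  invisible(path)
}
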