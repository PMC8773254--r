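DRUG_TIERS <- c("approved", "clinical", "preclinical", "novel")

matches_disease <- function(text, disease_terms) {
  if (length(text) == 0) return(logical(0))
  pat <- tolower(disease_terms)
  vapply(tolower(text), function(t) any(vapply(pat, grepl, logical(1), x = t, fixed = TRUE)),
         logical(1), USE.NAMES = FALSE)
}

#' Classify one drug into an evidence tier for the study disease
#'
#' Tier precedence: approved > clinical > preclinical > novel.
#' A drug is *approved* when its own indication text mentions a disease
#' term (case-insensitive substring over a configurable term list);
#' *clinical* when at least one trial-registry record links it to the
#' disease; *preclinical* when it has no such trial but at least one
#' preclinical publication for the disease; *novel* otherwise.
#'
#' @param drug_name drug name.
#' @param indication_text the drug's current-indication free text.
#' @param genes target genes of the drug (carried into the result).
#' @param evidence evidence tibble pre-filtered to this drug (see
#'   [read_evidence_table()]); disease matching is applied here.
#' @param disease_terms character vector of disease terms (default
#'   `"asthma"`).
#' @return object of class `drug_classification`: `drug_name`, `tier`,
#'   `supporting` (the matching evidence rows), `genes`.
#' @export
classify_drug <- function(drug_name, indication_text, genes, evidence,
                          disease_terms = "asthma") {
  stopifnot(length(disease_terms) > 0, all(nzchar(disease_terms)))
  ev <- evidence[matches_disease(evidence$disease, disease_terms), , drop = FALSE]
  trials <- ev[ev$kind == "trial", , drop = FALSE]
  preclin <- ev[ev$kind == "publication" & ev$is_preclinical, , drop = FALSE]
  tier <- if (any(matches_disease(indication_text, disease_terms))) {
    "approved"
  } else if (nrow(trials) > 0) {
    "clinical"
  } else if (nrow(preclin) > 0) {
    "preclinical"
  } else {
    "novel"
  }
  supporting <- if (tier %in% c("clinical", "preclinical")) ev else ev[0, , drop = FALSE]
  structure(list(drug_name = drug_name, tier = tier, supporting = supporting,
                 genes = sort(unique(normalize_symbol(genes)))),
            class = "drug_classification")
}

#' @export
print.drug_classification <- function(x, ...) {
  cat(sprintf("<drug_classification> %s: %s (%d supporting record(s), genes: %s)\n",
              x$drug_name, x$tier, nrow(x$supporting),
              paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Classify every drug of an edge list
#'
#' Convenience wrapper: groups the edges by drug, pulls each drug's
#' indication text from the target table and its evidence rows by name,
#' and applies [classify_drug()].
#'
#' @param edges gene-drug edges (see [map_genes_to_drugs()]).
#' @param targets drug-target tibble (source of indication text).
#' @param evidence evidence tibble for all drugs.
#' @param disease_terms disease term list (default `"asthma"`).
#' @return named list of `drug_classification` objects, one per distinct
#'   drug in `edges`, in drug-name order.
#' @export
classify_drugs <- function(edges, targets, evidence, disease_terms = "asthma") {
  drug_names <- sort(unique(edges$drug_name))
  out <- lapply(drug_names, function(d) {
    classify_drug(
      drug_name = d,
      indication_text = unique(targets$indication_text[targets$drug_name == d]),
      genes = edges$gene[edges$drug_name == d],
      evidence = evidence[evidence$drug_name == d, , drop = FALSE],
      disease_terms = disease_terms
    )
  })
  stats::setNames(out, drug_names)
}

#' Promising target genes
#'
#' Genes targeted by at least one drug whose tier is approved, clinical
#' or preclinical: existing evidence on the target makes drugs sharing it
#' repurposing-worthy.
#'
#' @param classifications list of `drug_classification` objects covering
#'   every drug in `edges`.
#' @param edges gene-drug edges.
#' @return sorted character vector of gene symbols.
#' @export
promising_targets <- function(classifications, edges) {
  tiers <- vapply(classifications, `[[`, character(1), "tier")
  uncovered <- setdiff(unique(edges$drug_name), names(classifications))
  if (length(uncovered) > 0) {
    stop(sprintf("classifications missing for drug(s): %s",
                 paste(utils::head(uncovered, 3), collapse = ", ")), call. = FALSE)
  }
  backed <- names(tiers)[tiers %in% c("approved", "clinical", "preclinical")]
  sort(unique(edges$gene[edges$drug_name %in% backed]))
}

#' Repurposing candidates among the novel drugs
#'
#' A novel-tier drug becomes a candidate when it targets at least one
#' promising gene (a gene already backed by an approved, clinical or
#' preclinical drug). For each candidate the tiers of the other drugs on
#' its matched genes are reported as the rationale.
#'
#' @param classifications list of `drug_classification` objects.
#' @param promising promising gene set from [promising_targets()] derived
#'   from the same classifications.
#' @param edges gene-drug edges.
#' @return tibble ordered by drug name: `drug_name`, `matched_genes`
#'   (list-column), `rationale_tiers` (list-column of the non-novel tiers
#'   seen on those genes).
#' @export
repurposing_candidates <- function(classifications, promising, edges) {
  tiers <- vapply(classifications, `[[`, character(1), "tier")
  novel <- names(tiers)[tiers == "novel"]
  rows <- lapply(sort(novel), function(d) {
    matched <- sort(intersect(edges$gene[edges$drug_name == d], promising))
    if (length(matched) == 0) return(NULL)
    co_drugs <- setdiff(unique(edges$drug_name[edges$gene %in% matched]), d)
    tibble::tibble(drug_name = d, matched_genes = list(matched),
                   rationale_tiers = list(sort(unique(tiers[co_drugs][tiers[co_drugs] != "novel"]))))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(drug_name = character(), matched_genes = list(),
                          rationale_tiers = list())
  }
  out
}

#' Count drugs per evidence tier
#'
#' @param classifications list of `drug_classification` objects.
#' @return named integer vector over approved / clinical / preclinical /
#'   novel; sums to the number of drugs.
#' @export
tier_summary <- function(classifications) {
  tiers <- vapply(classifications, `[[`, character(1), "tier")
  vapply(stats::setNames(DRUG_TIERS, DRUG_TIERS),
         function(t) sum(tiers == t), integer(1))
}

#' Write the per-drug classification report as TSV
#' @param classifications list of `drug_classification` objects.
#' @param path output path.
#' @export
write_classification_table <- function(classifications, path) {
  tab <- tibble::tibble(
    drug_name = vapply(classifications, `[[`, character(1), "drug_name"),
    tier = vapply(classifications, `[[`, character(1), "tier"),
    genes = vapply(classifications, function(x) paste(x$genes, collapse = "|"), character(1)),
    evidence_ids = vapply(classifications, function(x) {
      ids <- ifelse(x$supporting$kind == "trial", x$supporting$registry_id,
                    x$supporting$pub_id)
      paste(ids, collapse = "|")
    }, character(1))
  )
  tab <- tab[order(tab$drug_name, method = "radix"), , drop = FALSE]
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
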