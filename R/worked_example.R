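#' Load the bundled asthma candidate-drug evidence example
#'
#' A curated table of 17 asthma candidate drugs backed by clinical-trial
#' registrations or preclinical publications, transcribed from public
#' trial-registry (NCT / ACTRN) and PubMed records. Each row carries the
#' drug, its target gene, action, current (non-asthma) indication,
#' development phase, one or more `|`-separated evidence ids, and a flag
#' marking preclinical (in vivo / in vitro) support. Ids starting with
#' `NCT` or `ACTRN` become trial evidence records; numeric ids become
#' publication records inheriting the row's preclinical flag; the
#' evidence disease is asthma throughout.
#'
#' @param path fixture path; defaults to the copy installed with the
#'   package.
#' @return list with `table` (the raw 17-row tibble), `drugs` (one row
#'   per drug: `drug_name`, `gene`, `action`, `indication_text`) and
#'   `evidence` (expanded evidence records, one per id, in the layout of
#'   [read_evidence_table()]).
#' @export
load_evidence_example <- function(path = system.file("extdata",
                                                     "asthma_candidate_evidence.tsv",
                                                     package = "snp2drug")) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  tab$preclinical_flag <- parse_flag(tab$preclinical_flag)
  ev_rows <- lapply(seq_len(nrow(tab)), function(i) {
    ids <- trimws(strsplit(tab$registry_or_pub_id[i], "|", fixed = TRUE)[[1]])
    is_trial <- grepl("^(NCT|ACTRN)", ids)
    tibble::tibble(
      drug_name = tab$drug[i],
      disease = "asthma",
      kind = ifelse(is_trial, "trial", "publication"),
      registry_id = ifelse(is_trial, ids, ""),
      phase = ifelse(is_trial, tab$phase[i], ""),
      pub_id = ifelse(is_trial, "", ids),
      is_preclinical = !is_trial & tab$preclinical_flag[i]
    )
  })
  list(
    table = tab,
    drugs = tibble::tibble(drug_name = tab$drug,
                           gene = normalize_symbol(tab$gene),
                           action = tab$action,
                           indication_text = tab$indication),
    evidence = dplyr::bind_rows(ev_rows)
  )
}

#' Classify the bundled evidence example
#'
#' Runs [classify_drug()] over every drug of [load_evidence_example()]
#' and summarizes the tiers. Because these drugs are approved for other
#' diseases but carry asthma trial or preclinical evidence, the expected
#' outcome is a partition into clinical and preclinical tiers only.
#'
#' @param example output of [load_evidence_example()].
#' @param disease_terms disease term list (default `"asthma"`).
#' @return list with `classifications` (named list of
#'   `drug_classification`) and `tiers` (the [tier_summary()] counts).
#' @export
classify_evidence_example <- function(example = load_evidence_example(),
                                      disease_terms = "asthma") {
  drugs <- example$drugs
  classifications <- lapply(stats::setNames(drugs$drug_name, drugs$drug_name), function(d) {
    classify_drug(
      drug_name = d,
      indication_text = drugs$indication_text[drugs$drug_name == d],
      genes = drugs$gene[drugs$drug_name == d],
      evidence = example$evidence[example$evidence$drug_name == d, , drop = FALSE],
      disease_terms = disease_terms
    )
  })
  list(classifications = classifications, tiers = tier_summary(classifications))
}
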