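#' Default pipeline configuration
#'
#' Every threshold of the pipeline in one list: per-source p-value
#' cutoffs (GWAS 1e-5, PheWAS 0.05, strict `<`), LD expansion (r2 > 0.8,
#' population `"ASN"`), eQTL tissue (`"lung"`), ORA FDR threshold (q <
#' 0.05), biological-gene score cutoff (>= 2), drug filters
#' (pharmacological action required; approved / investigational /
#' experimental groups), disease term list (`"asthma"`), and an optional
#' drug-name blocklist applied to the candidate report (empty by
#' default).
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    thresholds = c(GWAS = 1e-5, PheWAS = 0.05),
    r2_min = 0.8,
    population = "ASN",
    tissue = "lung",
    q_threshold = 0.05,
    min_score = 2,
    require_pharm_action = TRUE,
    allowed_groups = c("approved", "investigational", "experimental"),
    disease_terms = "asthma",
    blocklist = character(0)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys fall back to
#' [default_config()]. A `paths` section (associations, ld, eqtl,
#' gene_sets: \{MP, GOBP, KEGG\}, drug_targets, evidence) is carried
#' through for [run_pipeline()], resolved relative to the YAML file.
#'
#' @param path YAML file path.
#' @return list with elements `config` and `paths`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  paths <- raw$paths
  raw$paths <- NULL
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (k in names(raw)) {
    v <- raw[[k]]
    if (k == "thresholds") v <- unlist(v)
    cfg[[k]] <- v
  }
  if (!is.null(paths)) {
    base <- dirname(normalizePath(path))
    resolve <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
    for (k in setdiff(names(paths), "gene_sets")) paths[[k]] <- resolve(paths[[k]])
    paths$gene_sets <- lapply(paths$gene_sets, resolve)
  }
  list(config = cfg, paths = paths)
}

read_pipeline_tables <- function(paths) {
  gene_sets <- lapply(stats::setNames(names(paths$gene_sets), names(paths$gene_sets)),
                      function(ns) read_gmt(paths$gene_sets[[ns]], namespace = ns))
  list(
    associations = read_association_table(paths$associations),
    ld = read_ld_table(paths$ld),
    eqtl = read_eqtl_table(paths$eqtl),
    gene_sets = gene_sets,
    drug_targets = read_drug_target_table(paths$drug_targets),
    evidence = read_evidence_table(paths$evidence)
  )
}

#' Run the full variant-to-drug pipeline
#'
#' Executes harvest (per-source p-value filter, merge to seed set), LD
#' expansion and gene mapping, the five criteria (missense, lung
#' cis-eQTL, and one ORA per gene-set namespace), the 0-5 scoring and
#' biological-gene selection, drug mapping, evidence-tier classification
#' and repurposing-candidate extraction. Degenerate inputs (no passing
#' associations, no risk genes, no druggable genes) short-circuit to
#' zero counts instead of failing.
#'
#' @param tables named list of in-memory input tables (`associations`,
#'   `ld`, `eqtl`, `gene_sets`, `drug_targets`, `evidence`), e.g.
#'   `generate_universe(...)$tables`; if `NULL`, tables are read from
#'   `paths`.
#' @param paths named list of file paths (see [read_pipeline_config()]).
#' @param config configuration list (see [default_config()]).
#' @param out_dir if non-`NULL`, all stage outputs are written there as
#'   TSV plus a JSON run report.
#' @return list of class `pipeline_result`: `report` (stage counts and
#'   the echoed config) and the stage objects (`seed`, `variants`,
#'   `risk`, `ora`, `matrix`, `biological`, `edges`, `classifications`,
#'   `promising`, `candidates`).
#' @export
run_pipeline <- function(tables = NULL, paths = NULL, config = default_config(),
                         out_dir = NULL) {
  if (is.null(tables)) {
    stopifnot(!is.null(paths))
    tables <- read_pipeline_tables(paths)
  }

  filtered <- filter_by_source(tables$associations, config$thresholds)
  seed <- merge_to_seed_set(filtered)
  variants <- expand_ld(seed, tables$ld, config$r2_min, config$population)
  risk <- map_to_genes(variants, tables$ld)

  ora <- list()
  per_criterion <- stats::setNames(vector("list", 5), CRITERION_NAMES)
  per_criterion$missense <- criterion_missense(risk)
  per_criterion$cis_eqtl <- criterion_eqtl(risk, tables$eqtl, config$tissue)
  ns_crit <- c(MP = "ko_mouse", GOBP = "ppi_gobp", KEGG = "kegg")
  for (ns in names(ns_crit)) {
    crit <- ns_crit[[ns]]
    collection <- tables$gene_sets[[ns]]
    if (length(risk$genes) > 0 && !is.null(collection) &&
        length(intersect(risk$genes, collection_universe(collection))) > 0) {
      ora[[ns]] <- run_ora(risk$genes, collection, q_threshold = config$q_threshold)
      per_criterion[[crit]] <- criterion_ora(risk, collection, ora[[ns]])
    } else {
      per_criterion[[crit]] <- character(0)
    }
  }

  matrix <- build_matrix(risk, per_criterion)
  biological <- select_biological(matrix, config$min_score)

  if (length(biological) > 0) {
    edges <- map_genes_to_drugs(biological, tables$drug_targets,
                                config$require_pharm_action, config$allowed_groups)
  } else {
    edges <- tibble::tibble(gene = character(), drug_id = character(),
                            drug_name = character(), action = character())
  }
  classifications <- classify_drugs(edges, tables$drug_targets, tables$evidence,
                                    config$disease_terms)
  promising <- promising_targets(classifications, edges)
  candidates <- repurposing_candidates(classifications, promising, edges)
  if (length(config$blocklist) > 0 && nrow(candidates) > 0) {
    candidates <- candidates[!(tolower(candidates$drug_name) %in%
                                 tolower(config$blocklist)), , drop = FALSE]
  }
  tiers <- tier_summary(classifications)

  report <- list(
    n_associations_in = nrow(tables$associations),
    n_associations_pass = nrow(filtered),
    n_seed_variants = length(seed$variants),
    n_expanded_variants = length(variants),
    n_risk_genes = length(risk$genes),
    per_criterion = vapply(per_criterion, length, integer(1)),
    n_biological_genes = length(biological),
    n_edges = nrow(edges),
    n_druggable_genes = length(druggable_genes(edges)),
    tier_counts = tiers,
    n_candidates = nrow(candidates),
    config = config
  )
  result <- structure(list(
    report = report, seed = seed, variants = variants, risk = risk, ora = ora,
    matrix = matrix, biological = biological, edges = edges,
    classifications = classifications, promising = promising,
    candidates = candidates
  ), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("<pipeline_result>\n")
  cat(sprintf("  associations: %d in, %d pass filters\n",
              r$n_associations_in, r$n_associations_pass))
  cat(sprintf("  seed variants: %d -> expanded: %d -> risk genes: %d\n",
              r$n_seed_variants, r$n_expanded_variants, r$n_risk_genes))
  cat(sprintf("  per-criterion genes: %s\n",
              paste(sprintf("%s=%d", names(r$per_criterion), r$per_criterion),
                    collapse = ", ")))
  cat(sprintf("  biological genes (score >= %d): %d\n",
              r$config$min_score, r$n_biological_genes))
  cat(sprintf("  drug edges: %d over %d druggable genes\n",
              r$n_edges, r$n_druggable_genes))
  cat(sprintf("  tiers: %s\n",
              paste(sprintf("%s=%d", names(r$tier_counts), r$tier_counts),
                    collapse = ", ")))
  cat(sprintf("  repurposing candidates: %d\n", r$n_candidates))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the output directory.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed_tab <- tibble::tibble(
    variant_id = result$seed$variants,
    sources = vapply(result$seed$provenance, paste, character(1), collapse = "|")
  )
  readr::write_tsv(seed_tab, file.path(out_dir, "seed_variants.tsv"), progress = FALSE)
  risk_tab <- tibble::tibble(
    gene = result$risk$genes,
    variants = vapply(result$risk$gene_to_variants, paste, character(1), collapse = "|"),
    has_missense = unname(result$risk$gene_missense)
  )
  readr::write_tsv(risk_tab, file.path(out_dir, "risk_genes.tsv"), progress = FALSE)
  for (ns in names(result$ora)) {
    write_ora_table(result$ora[[ns]], file.path(out_dir, sprintf("ora_%s.tsv", ns)))
  }
  write_criterion_matrix(result$matrix, file.path(out_dir, "criterion_matrix.tsv"))
  readr::write_tsv(score_histogram(result$matrix),
                   file.path(out_dir, "score_histogram.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(gene = result$biological),
                   file.path(out_dir, "biological_genes.tsv"), progress = FALSE)
  tiers <- vapply(result$classifications, `[[`, character(1), "tier")
  edges <- result$edges
  edges$tier <- unname(tiers[edges$drug_name])
  write_edge_list(edges, file.path(out_dir, "gene_drug_edges.tsv"))
  write_classification_table(result$classifications,
                             file.path(out_dir, "drug_classifications.tsv"))
  cand <- result$candidates
  cand_tab <- tibble::tibble(
    drug_name = cand$drug_name,
    matched_genes = vapply(cand$matched_genes, paste, character(1), collapse = "|"),
    rationale_tiers = vapply(cand$rationale_tiers, paste, character(1), collapse = "|")
  )
  readr::write_tsv(cand_tab, file.path(out_dir, "repurposing_candidates.tsv"),
                   progress = FALSE)
  jsonlite::write_json(result$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
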