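#!/usr/bin/env Rscript
# Map biological risk genes to drugs, tier each drug by its evidence for
# the study disease, and extract repurposing candidates: novel drugs on
# genes already backed by approved, clinical or preclinical drugs.

suppressMessages(library(snp2drug))

bio <- readr::read_tsv("results/biological_genes.tsv", show_col_types = FALSE)$gene
targets <- read_drug_target_table("results/synthetic/drug_targets.tsv")
evidence <- read_evidence_table("results/synthetic/evidence.tsv")

edges <- map_genes_to_drugs(bio, targets)
cat(sprintf("%d gene-drug edges over %d druggable of %d biological genes\n",
            nrow(edges), length(druggable_genes(edges)), length(bio)))

cls <- classify_drugs(edges, targets, evidence, disease_terms = "asthma")
tiers <- tier_summary(cls)
cat(sprintf("evidence tiers: %s\n",
            paste(sprintf("%s=%d", names(tiers), tiers), collapse = ", ")))

promising <- promising_targets(cls, edges)
cat(sprintf("promising target genes (backed by non-novel drugs): %s\n",
            paste(promising, collapse = ", ")))

cand <- repurposing_candidates(cls, promising, edges)
cat(sprintf("%d repurposing candidate(s): %s\n",
            nrow(cand), paste(cand$drug_name, collapse = ", ")))

tier_of <- vapply(cls, `[[`, character(1), "tier")
edges$tier <- unname(tier_of[edges$drug_name])
write_edge_list(edges, "results/gene_drug_edges.tsv")
write_classification_table(cls, "results/drug_classifications.tsv")
readr::write_tsv(
  tibble::tibble(drug_name = cand$drug_name,
                 matched_genes = vapply(cand$matched_genes, paste, character(1), collapse = "|"),
                 rationale_tiers = vapply(cand$rationale_tiers, paste, character(1), collapse = "|")),
  "results/repurposing_candidates.tsv")

# cross-check the staged run against the one-shot orchestrator
res <- run_pipeline(paths = list(
  associations = "results/synthetic/associations.tsv",
  ld = "results/synthetic/ld.tsv",
  eqtl = "results/synthetic/eqtl.tsv",
  gene_sets = list(MP = "results/synthetic/mp.gmt",
                   GOBP = "results/synthetic/gobp.gmt",
                   KEGG = "results/synthetic/kegg.gmt"),
  drug_targets = "results/synthetic/drug_targets.tsv",
  evidence = "results/synthetic/evidence.tsv"))
stopifnot(setequal(res$candidates$drug_name, cand$drug_name))
cat("one-shot run_pipeline() agrees with the staged scripts\n")
print(res)
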