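#!/usr/bin/env Rscript
# Score every risk gene against the five functional-annotation criteria
# (missense, lung cis-eQTL, and ORA membership in mouse-knockout
# phenotype, GO biological-process and KEGG pathway namespaces at
# FDR q < 0.05), then select biological risk genes at score >= 2.

suppressMessages(library(snp2drug))

risk_tab <- readr::read_tsv("results/risk_genes.tsv", show_col_types = FALSE)
ld <- read_ld_table("results/synthetic/ld.tsv")
eqtl <- read_eqtl_table("results/synthetic/eqtl.tsv")
collections <- list(MP = read_gmt("results/synthetic/mp.gmt", "MP"),
                    GOBP = read_gmt("results/synthetic/gobp.gmt", "GOBP"),
                    KEGG = read_gmt("results/synthetic/kegg.gmt", "KEGG"))

variants <- unique(unlist(strsplit(risk_tab$variants, "|", fixed = TRUE)))
risk <- map_to_genes(variants, ld)

per_criterion <- list(
  missense = criterion_missense(risk),
  cis_eqtl = criterion_eqtl(risk, eqtl, tissue = "lung")
)
for (ns in names(collections)) {
  crit <- c(MP = "ko_mouse", GOBP = "ppi_gobp", KEGG = "kegg")[[ns]]
  ora <- run_ora(risk$genes, collections[[ns]], q_threshold = 0.05)
  write_ora_table(ora, sprintf("results/ora_%s.tsv", ns))
  per_criterion[[crit]] <- criterion_ora(risk, collections[[ns]], ora)
  cat(sprintf("%s ORA: %d/%d sets enriched at q < 0.05\n",
              ns, sum(ora$enriched), nrow(ora)))
}

mat <- build_matrix(risk, per_criterion)
bio <- select_biological(mat, min_score = 2)
cat(sprintf("per-criterion gene counts: %s\n",
            paste(sprintf("%s=%d", names(per_criterion), lengths(per_criterion)),
                  collapse = ", ")))
cat(sprintf("%d of %d risk genes reach score >= 2 (biological risk genes)\n",
            length(bio), nrow(mat)))
print(score_histogram(mat))
cat("pairwise phi correlation between criteria:\n")
print(round(criterion_correlogram(mat), 2))

write_criterion_matrix(mat, "results/criterion_matrix.tsv")
readr::write_tsv(score_histogram(mat), "results/score_histogram.tsv")
readr::write_tsv(tibble::tibble(gene = bio), "results/biological_genes.tsv")
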