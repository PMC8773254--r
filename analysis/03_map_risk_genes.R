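#!/usr/bin/env Rscript
# Expand the seed variants through LD proxies (r2 > 0.8, Asian-panel
# rows) and map the expanded set to risk genes with missense flags.

suppressMessages(library(snp2drug))

seed_tab <- readr::read_tsv("results/seed_variants.tsv", show_col_types = FALSE)
ld <- read_ld_table("results/synthetic/ld.tsv")

variants <- expand_ld(seed_tab$variant_id, ld, r2_min = 0.8, population = "ASN")
risk <- map_to_genes(variants, ld)
cat(sprintf("%d seed variants -> %d after LD expansion -> %d risk genes (%d with missense)\n",
            nrow(seed_tab), length(variants), length(risk$genes),
            sum(risk$gene_missense)))

readr::write_tsv(
  tibble::tibble(gene = risk$genes,
                 variants = vapply(risk$gene_to_variants, paste, character(1), collapse = "|"),
                 has_missense = unname(risk$gene_missense)),
  "results/risk_genes.tsv")
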