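Package: snp2drug
Title: Variant-to-Drug Repurposing from GWAS and PheWAS Association Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated genomic drug-repurposing pipeline: harvests
    trait-associated variants from GWAS- and PheWAS-catalog style tables,
    expands them through linkage-disequilibrium proxies, scores candidate
    risk genes against five functional-annotation criteria (missense,
    cis-eQTL, and hypergeometric over-representation in mouse-knockout
    phenotype, GO biological-process, and KEGG pathway gene sets with
    Benjamini-Hochberg FDR control), maps high-scoring "biological risk
    genes" to drugs through DrugBank-style target tables, and tiers each
    candidate drug by clinical evidence (approved, clinical, preclinical,
    novel) to emit repurposing candidates. Ships a synthetic-data
    generator that plants ground truth in all six input table kinds so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
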