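#!/usr/bin/env Rscript
# Classify the bundled real-data worked example: 17 asthma candidate
# drugs transcribed from public trial-registry and PubMed records. All
# are approved for other diseases, so the expected partition is clinical
# (trial-backed) vs preclinical (in vivo / in vitro publications only).

suppressMessages(library(snp2drug))

ex <- load_evidence_example()
out <- classify_evidence_example(ex)

cat(sprintf("%d drugs, %d evidence records\n", nrow(ex$table), nrow(ex$evidence)))
cat(sprintf("tiers: %s\n",
            paste(sprintf("%s=%d", names(out$tiers), out$tiers), collapse = ", ")))
for (d in names(out$classifications)) print(out$classifications[[d]])

dir.create("results", showWarnings = FALSE)
write_classification_table(out$classifications, "results/evidence_example_tiers.tsv")
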