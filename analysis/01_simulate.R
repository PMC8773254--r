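#!/usr/bin/env Rscript
# Generate the synthetic mini-universe used by the downstream analysis
# steps: association, LD, eQTL, gene-set, drug-target and evidence tables
# with planted ground truth, written under results/synthetic/.

suppressMessages(library(snp2drug))

params <- synthetic_params(rng_seed = 1)
universe <- generate_universe(params)
paths <- write_universe(universe, "results/synthetic")

print(universe)
cat(sprintf("planted biological genes: %s\n",
            paste(universe$truth$planted_biological_genes, collapse = ", ")))
cat(sprintf("planted repurposing candidates: %s\n",
            paste(universe$truth$planted_candidates, collapse = ", ")))
cat(sprintf("wrote %d files under results/synthetic/\n", length(paths)))
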