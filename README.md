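# snp2drug

An integrated genomic drug-repurposing pipeline in R. Starting from
trait-associated variants harvested from GWAS-catalog and PheWAS-catalog
style tables, it identifies disease risk genes through linkage-disequilibrium
(LD) proxy expansion, prioritizes them with a five-criterion
functional-annotation score, maps the high-scoring genes to drugs through a
DrugBank-style target table, and tiers every candidate drug by its clinical
evidence to nominate repurposing candidates. The motivating application is
asthma, where existing controller drugs leave a large fraction of severe
patients inadequately treated and genetics-guided repurposing offers a
cheaper route than de novo discovery.

The package is for computational biologists and pharmacogenomics analysts
who have flat-file snapshots of association catalogs, LD/eQTL annotation
exports, gene-set collections and a drug-target extract, and want a tested,
deterministic pipeline from variants to ranked drug candidates — plus a
synthetic-data generator with planted ground truth so every stage can be
validated offline.

## Method

1. **Variant harvest.** Associations are filtered per source with strict
   cutoffs (GWAS *p* < 10⁻⁵, PheWAS *p* < 0.05) and merged into one seed set,
   deduplicated by rsID with per-source provenance.
2. **LD expansion and gene mapping.** Seeds are expanded one hop through LD
   proxies with *r*² > 0.8 in the configured population; every variant in the
   expanded set credits the genes its LD rows annotate.
3. **Five-criterion scoring.** Each risk gene scores one point per
   criterion met: (1) a missense risk variant; (2) a significant *cis*-eQTL
   in the target tissue (lung) on one of its own risk variants; (3)–(5)
   membership in a gene set significantly over-represented in the risk-gene
   list, tested separately in mouse-knockout phenotype (MP), GO biological
   process, and KEGG pathway namespaces. Over-representation uses the
   one-sided hypergeometric tail,
   P(X ≥ k) = Σⱼ₌ₖ C(K, j) C(N−K, n−j) / C(N, n),
   with Benjamini–Hochberg FDR control per namespace and enrichment declared
   at *q* < 0.05. Genes with score ≥ 2 are the **biological risk genes**.
4. **Drug mapping and evidence tiers.** Biological risk genes are joined to
   a drug-target table (requiring pharmacological action and an allowed
   approval group), and each drug is tiered for the study disease with
   precedence approved > clinical > preclinical > novel: an indication
   matching a disease term, a trial-registry record, or a preclinical
   publication. Novel drugs targeting a gene already backed by a non-novel
   drug are the **repurposing candidates**.

Criterion dependence is summarized with the pairwise phi coefficient of the
indicator columns.

## Worked example

The package ships a curated table of 17 asthma candidate drugs backed by
trial-registry (NCT/ACTRN) or preclinical PubMed evidence:

```r
library(snp2drug)
out <- classify_evidence_example()
out$tiers
#>    approved    clinical preclinical       novel
#>           0          12           5           0
out$classifications$Tocilizumab
#> <drug_classification> Tocilizumab: clinical (3 supporting record(s), genes: IL6R)
out$classifications$Pitavastatin
#> <drug_classification> Pitavastatin: preclinical (1 supporting record(s), genes: HMGCR)
```

All 17 drugs are approved for other diseases, so none reach the approved
tier; 12 carry asthma trial registrations (clinical) and 5 only in vivo /
in vitro publications (preclinical).

The full pipeline on a synthetic universe with planted ground truth:

```r
u <- generate_universe(synthetic_params(rng_seed = 1))
res <- run_pipeline(tables = u$tables)
res
#> <pipeline_result>
#>   associations: 83 in, 43 pass filters
#>   seed variants: 40 -> expanded: 130 -> risk genes: 30
#>   per-criterion genes: missense=17, cis_eqtl=15, ko_mouse=13, ppi_gobp=14, kegg=9
#>   biological genes (score >= 2): 23
#>   drug edges: 30 over 16 druggable genes
#>   tiers: approved=4, clinical=7, preclinical=4, novel=15
#>   repurposing candidates: 8
setequal(res$biological, u$truth$planted_biological_genes)   # TRUE
setequal(res$candidates$drug_name, u$truth$planted_candidates) # TRUE
```

The numbered scripts under `analysis/` run the same flow stage by stage
(simulate → harvest → map genes → score → drugs → worked example), writing
their tables under `results/`.

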