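---
title: "From risk variants to repurposing candidates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From risk variants to repurposing candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snp2drug)
```

## The pipeline and its assumptions

`snp2drug` operationalizes a genetics-first repurposing argument: if common
variants implicate a gene in a disease, and drugs already act on that gene
for other indications, those drugs are rational repurposing candidates. The
pipeline is a deterministic funnel:

variants → LD-expanded variants → risk genes → biological risk genes
(score ≥ 2) → druggable genes → tiered drugs → candidates.

Its core assumptions are worth stating explicitly. Association signals are
taken at face value: no fine-mapping, no effect-size weighting, and a
variant's gene assignment is whatever the LD annotation table says
(typically nearest-gene or source-curated). LD expansion is one hop only —
each seed variant is expanded through the proxies reported for it, with no
proxy-of-proxy chaining, mirroring one annotation query per seed. And the
evidence tiers treat the *presence* of a trial registration as the signal;
trial phase is carried through as text but never ranked.

## Stage definitions

**Harvest.** A record survives iff `p_value < threshold[source]`, strict at
the boundary, with defaults GWAS 1e-5 and PheWAS 0.05 — the two catalogs
use different significance conventions, and the strict inequality keeps the
rule unambiguous at printed cutoffs. Deduplication is by rsID alone: a
variant reported for several related traits, or by both catalogs, counts
once, with every contributing source kept as provenance. Traits are
metadata from here on.

**LD and gene mapping.** Proxies qualify at `r2 > r2_min` (default 0.8,
strict) in an exactly matching population code (default `"ASN"`). Any LD
row may annotate its proxy to a gene; a variant annotating several genes
credits all of them, since the sources impose no one-gene-per-SNP rule. A
gene's missense flag requires the missense variant to be one of the gene's
own seed-or-proxy variants at the same r² threshold — missense credit
through weaker LD would make criterion 1 laxer than the gene mapping
itself.

**Scoring.** Five binary criteria in fixed column order (`missense`,
`cis_eqtl`, `ko_mouse`, `ppi_gobp`, `kegg`); the score is the row sum and
biological risk genes are those with score ≥ 2 (inclusive). The
protein-interaction criterion is deliberately operationalized as GO
biological-process over-representation: that is how the annotation was
actually computed in the workflow this package systematizes, despite the
"PPI" label the field often uses. The cis-eQTL criterion demands the
significant eQTL variant be among the gene's own risk variants in the
configured tissue (default `"lung"`), not any eQTL genome-wide — otherwise
the criterion would leak information from loci unrelated to the trait.

**Over-representation.** One-sided hypergeometric upper tail per set,
BH-adjusted *per collection* (MP, GO-BP, KEGG are three separate multiple-
testing families, mirroring three separate enrichment runs), enrichment at
q < 0.05. The default universe is the set of genes appearing in at least
one set of the collection under test — the reference-set convention of
enrichment web tools — and is overridable when a custom background is more
appropriate. Query genes outside the universe are dropped with a logged
count; sets are clipped to the universe and dropped if they empty out.

**Drugs and tiers.** Gene→drug edges require the target row to pass a
pharmacological-action flag (default on) and an approval-group filter
(default approved/investigational/experimental); biologics and small
molecules are treated identically. Tier precedence is
approved > clinical > preclinical > novel, evaluated per drug against a
case-insensitive substring term list (default `"asthma"`), applied to the
drug's indication text and to the evidence records' disease field. An
anticancer blocklist can be applied to the candidate report but is off by
default: excluding cytotoxic drugs is a downstream judgment about
tolerability, not part of the mapping itself.

## Numerical choices

The hypergeometric tail is summed in log space (`lchoose`) and
re-exponentiated against the running maximum, so 10⁴-gene universes cannot
overflow; results agree with exact combinatorial ratios to < 1e-12
everywhere they are representable exactly (N ≤ 25, verified exhaustively in
the tests). `k = 0` returns exactly 1. The BH step-up is the literal
`min_{j≥i} p_(j) m / j` with a cap at 1; ties need no tie-breaking under
this formula. The phi coefficient returns `NA` whenever a contingency
margin is zero (a constant indicator column), rather than a conventional 0,
so degenerate criteria are visibly undefined in the correlogram. Report
orderings (biological genes by score then symbol; edge lists by gene, drug
name, drug id) are fixed so repeated runs are byte-identical.

## What the synthetic generator emulates — and what it does not

`generate_universe()` builds all six input tables around planted ground
truth: each planted risk gene hangs off one seed variant with
`ld_block_size` proxies at `r2_high` (default 0.95); decoy LD rows sit at
`r2_low` ≤ 0.8 or in a non-matching population; planted association
p-values are drawn log-uniformly below a tenth of their source's cutoff and
decoys above ten times it, so the filter boundary is never ambiguous while
the written files still exercise scientific-notation parsing (every fifth
p-value is typeset as `a × 10−b` with a Unicode minus). Criterion flags
follow a per-gene planted membership (sizes drawn to give a realistic
spread of 0–5 scores, topped up so each enrichment namespace has at least
five members and at least five genes reach score ≥ 2); the recorded ground
truth is the *realized* membership, so `planted_biological_genes` is by
construction the score ≥ 2 set. Non-novel drugs receive trial or
preclinical evidence records (or an asthma indication); novel drugs placed
on already-backed genes are the planted candidates.

Two regimes matter. With `enrichment_strength > 1`, the planted set of each
namespace contains exactly the planted members plus fillers from the
non-planted pool, with the set size capped so observed-over-expected
overlap stays at or above the requested fold; decoy sets are drawn from
non-planted genes, which makes the noise-free regime *exactly separable* —
the recovery tests can then demand set equality with the ground truth
rather than high overlap, a much stronger check. With
`enrichment_strength = 1`, every set, planted included, is a uniform draw
from the whole universe: the null regime used to verify BH type-I control
with uniformly drawn queries.

What the generator does **not** mimic: real LD block structure and allele
frequencies, gene-set size distributions and between-set redundancy of real
ontologies, polypharmacology (each synthetic drug targets one gene), or
dirty identifiers. Passing the recovery tests therefore shows the pipeline
implements its own rules exactly; it does not show robustness to annotation
noise, background misspecification, or the correlated gene sets of real
collections, where enrichment q-values are well known to be conservative or
anti-conservative depending on overlap structure.

## Problem sizes and determinism

The test and verification runs use a universe of 800 genes, 40 seed + 40
decoy variants, 30 planted risk genes, 25 sets per collection and 30 drugs
— small enough for the whole suite to run in well under a minute while
keeping every stage's statistics non-trivial (planted ORA p-values around
1e-8–1e-15, null false-enrichment rates estimable from 500 replicates). A
single integer seed drives one generator stream; the session RNG state is
saved and restored around generation, and identical parameters produce
byte-identical written tables.

## The bundled worked example

`inst/extdata/asthma_candidate_evidence.tsv` transcribes public
trial-registry and PubMed records for 17 asthma candidate drugs, each
approved for another disease. Ids beginning `NCT`/`ACTRN` expand to trial
evidence records and numeric ids to publication records inheriting the
row's preclinical flag, with the evidence disease set to asthma
throughout. Classification yields 12 clinical and 5 preclinical drugs and
no approved or novel tier — the expected partition, since every drug in the
table was selected for having asthma evidence short of approval. One
transcription note: the source registry table lists *PIK3CB* as
duvelisib's target even though the drug is generally described as a
PIK3CD/PI3K-δ inhibitor; the fixture keeps the transcribed value.

## Known limitations and open points

Headline counts from any real snapshot (numbers of seed variants, risk
genes, biological genes, drugs) depend entirely on the dates and curation
of the upstream databases, which is why the package's verification is
property-based rather than count-based, and why every threshold is echoed
into the run report for provenance. Cross-source deduplication rules in
published variant counts are often under-specified; this implementation
documents its rule (rsID-only) and makes no attempt to match any particular
published total. The candidate rule is symmetric and transparent — novel
drug on a backed gene — and deliberately includes no mechanism or
direction-of-effect reasoning (an agonist may share a target with an
antagonist); such filtering belongs to downstream curation, as does the
anticancer blocklist.
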