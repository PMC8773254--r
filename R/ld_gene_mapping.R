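#' Expand seed variants through LD proxies
#'
#' One-hop expansion: every proxy in strong linkage disequilibrium
#' (r2 strictly above `r2_min`, default 0.8) with a seed variant in the
#' requested population joins the variant set. Seeds are always retained;
#' no proxy-of-proxy chaining.
#'
#' @param seed a `variant_seed_set` or a character vector of rsIDs.
#' @param ld LD tibble (see [read_ld_table()]).
#' @param r2_min strict lower r2 bound in \[0, 1\].
#' @param population population code to match exactly (default `"ASN"`).
#' @return sorted character vector of rsIDs (seed plus qualifying proxies).
#' @export
expand_ld <- function(seed, ld, r2_min = 0.8, population = "ASN") {
  stopifnot(r2_min >= 0, r2_min <= 1)
  seed_ids <- if (inherits(seed, "variant_seed_set")) seed$variants else as.character(seed)
  hit <- ld$lead_variant %in% seed_ids & ld$r2 > r2_min & ld$population == population
  sort(unique(c(seed_ids, ld$proxy_variant[hit])))
}

#' Map an expanded variant set to risk genes
#'
#' Each LD row annotates its proxy variant to a gene (possibly empty).
#' A gene becomes a risk gene when at least one variant of the set
#' annotates to it; a variant may annotate to several genes and all are
#' credited. The per-gene missense flag is true when any contributing
#' variant of that gene carries a missense annotation.
#'
#' @param variants character vector of rsIDs (typically from [expand_ld()]).
#' @param ld LD tibble carrying the gene and missense annotations.
#' @return object of class `risk_gene_set` with elements `genes` (sorted
#'   character vector), `gene_to_variants` (named list gene -> rsIDs) and
#'   `gene_missense` (named logical).
#' @export
map_to_genes <- function(variants, ld) {
  hit <- ld[ld$proxy_variant %in% variants & nzchar(ld$gene), , drop = FALSE]
  genes <- sort(unique(hit$gene))
  gene_to_variants <- lapply(stats::setNames(genes, genes), function(g) {
    sort(unique(hit$proxy_variant[hit$gene == g]))
  })
  gene_missense <- vapply(stats::setNames(genes, genes), function(g) {
    any(hit$is_missense[hit$gene == g])
  }, logical(1))
  structure(list(genes = genes, gene_to_variants = gene_to_variants,
                 gene_missense = gene_missense),
            class = "risk_gene_set")
}

#' @export
print.risk_gene_set <- function(x, ...) {
  cat(sprintf("<risk_gene_set> %d genes (%d with missense annotation)\n",
              length(x$genes), sum(x$gene_missense)))
  invisible(x)
}
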