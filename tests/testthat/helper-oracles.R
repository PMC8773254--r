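# Independent oracles, deliberately naive: exact combinatorial ratios for
# the hypergeometric tail (choose() is exact in double for N <= 25), a
# subset-enumeration version for tiny N, and a literal step-up BH.

oracle_hypergeom_tail <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

oracle_hypergeom_enumerate <- function(k, K, n, N) {
  # enumerate every n-subset of 1:N; elements 1..K are "annotated"
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  qs <- vapply(seq_len(m), function(i) min(1, sorted[i:m] * m / (i:m)), numeric(1))
  out <- numeric(m)
  out[ord] <- qs
  out
}

# Small handmade tables reused across IO / harvest tests
make_assoc_tsv <- function(path, rows) {
  writeLines(c("variant_id\tsource\ttrait\tp_value", rows), path)
  path
}

make_ld_tibble <- function(...) {
  rows <- list(...)
  tibble::tibble(
    lead_variant = vapply(rows, `[[`, character(1), 1),
    proxy_variant = vapply(rows, `[[`, character(1), 2),
    r2 = vapply(rows, `[[`, numeric(1), 3),
    population = vapply(rows, `[[`, character(1), 4),
    gene = vapply(rows, `[[`, character(1), 5),
    is_missense = vapply(rows, `[[`, logical(1), 6)
  )
}

make_risk <- function(gene_to_variants, gene_missense) {
  genes <- sort(names(gene_to_variants))
  structure(list(
    genes = genes,
    gene_to_variants = gene_to_variants[genes],
    gene_missense = vapply(genes, function(g) isTRUE(gene_missense[[g]]), logical(1))
  ), class = "risk_gene_set")
}
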