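#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` are annotated.
#' This is the one-sided over-representation test statistic. Terms are
#' accumulated in log space via `lchoose` so universes of 10^4+ genes do
#' not overflow.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K annotated genes in the universe.
#' @param n query size.
#' @param N universe size.
#' @return probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (k < 0 || K < 0 || n < 0 || K > N || n > N || k > min(K, n)) {
    stop("hypergeom_upper_tail: arguments violate 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  if (k == 0) return(1)
  j <- k:min(K, n)
  log_terms <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(log_terms)
  min(exp(m + log(sum(exp(log_terms - m)))), 1)
}

#' Benjamini-Hochberg step-up q-values
#'
#' q_(i) = min_\{j >= i\} p_(j) * m / j over the sorted p-values, capped at
#' 1, returned in the input order. Ties need no special handling under
#' the step-up formula.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  stopifnot(all(p_values > 0), all(p_values <= 1))
  ord <- order(p_values, method = "radix")
  q_sorted <- rev(cummin(rev(p_values[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' Hypergeometric over-representation analysis of a gene list
#'
#' Tests each set of a collection for over-representation of the query
#' genes, with BH FDR control across all sets of the collection
#' (collections are tested separately, mirroring independent enrichment
#' runs per namespace). The universe defaults to all genes appearing in
#' at least one set of the collection (reference-set style background);
#' query genes outside the universe are dropped with a logged count, and
#' sets are clipped to the universe (sets that become empty are dropped).
#'
#' @param query character vector of gene symbols.
#' @param collection a `gene_set_collection`.
#' @param universe background gene symbols; `NULL` for the collection
#'   universe.
#' @param q_threshold FDR threshold for the `enriched` call, in (0, 1).
#' @return tibble with one row per tested set: `set_id`, `set_name`, `k`
#'   (overlap), `K` (set size), `n` (query size), `N` (universe size),
#'   `p_value`, `q_value`, `enriched`.
#' @export
run_ora <- function(query, collection, universe = NULL, q_threshold = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"),
            q_threshold > 0, q_threshold < 1)
  if (is.null(universe)) universe <- collection_universe(collection)
  universe <- unique(normalize_symbol(universe))
  if (length(universe) == 0) stop("run_ora: empty universe", call. = FALSE)
  query <- unique(normalize_symbol(query))
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    message(sprintf("run_ora [%s]: %d query gene(s) outside the universe dropped",
                    collection$namespace, length(dropped)))
  }
  query <- intersect(query, universe)
  if (length(query) == 0) stop("run_ora: empty query after clipping to universe", call. = FALSE)

  clipped <- lapply(collection$sets, function(s) intersect(s$genes, universe))
  keep <- vapply(clipped, length, integer(1)) > 0
  ids <- names(collection$sets)[keep]
  clipped <- clipped[keep]
  N <- length(universe); n <- length(query)
  res <- tibble::tibble(
    set_id = ids,
    set_name = vapply(collection$sets[keep], `[[`, character(1), "name"),
    k = vapply(clipped, function(g) length(intersect(g, query)), integer(1)),
    K = vapply(clipped, length, integer(1)),
    n = n, N = N
  )
  res$p_value <- vapply(seq_len(nrow(res)), function(i) {
    hypergeom_upper_tail(res$k[i], res$K[i], n, N)
  }, numeric(1))
  res$q_value <- bh_adjust(res$p_value)
  res$enriched <- res$q_value < q_threshold
  res
}

#' Write ORA results as TSV
#' @param ora tibble from [run_ora()].
#' @param path output path.
#' @export
write_ora_table <- function(ora, path) {
  readr::write_tsv(ora, path, progress = FALSE)
  invisible(path)
}

#' Phi correlation of two binary vectors
#'
#' The Pearson correlation specialized to 2x2 contingency counts:
#' phi = (n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0). When any margin is
#' zero (a constant vector) the coefficient is undefined and `NA` is
#' returned.
#'
#' @param x,y binary (0/1 or logical) vectors of equal length >= 2.
#' @return phi in \[-1, 1\], or `NA_real_` when undefined.
#' @export
phi_correlation <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y)) stop("phi_correlation: length mismatch", call. = FALSE)
  stopifnot(length(x) >= 2, all(x %in% 0:1), all(y %in% 0:1))
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  margins <- c(n11 + n10, n01 + n00, n11 + n01, n10 + n00)
  if (any(margins == 0)) return(NA_real_)
  (n11 * n00 - n10 * n01) / sqrt(prod(as.numeric(margins)))
}
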