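#' Apply source-specific significance filters to association records
#'
#' GWAS-catalog and PheWAS-catalog associations use very different
#' significance conventions, so each source gets its own p-value cutoff
#' (defaults: GWAS 1e-5, PheWAS 0.05). A record survives iff its p-value
#' is strictly below its source's cutoff; input order is preserved.
#'
#' @param records association tibble (see [read_association_table()]).
#' @param thresholds named numeric vector of per-source cutoffs; every
#'   source present in `records` must have an entry.
#' @return the surviving records, in input order.
#' @export
filter_by_source <- function(records,
                             thresholds = c(GWAS = 1e-5, PheWAS = 0.05)) {
  if (nrow(records) == 0) return(records)
  missing <- setdiff(unique(records$source), names(thresholds))
  if (length(missing) > 0) {
    stop(sprintf("no p-value threshold configured for source(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  keep <- records$p_value < unname(thresholds[records$source])
  records[keep, , drop = FALSE]
}

#' Merge filtered associations into a seed-variant set
#'
#' Deduplicates by rsID only (a variant reported for several traits or by
#' both catalogs counts once) while recording, per variant, every source
#' that contributed it.
#'
#' @param records threshold-filtered association tibble.
#' @return object of class `variant_seed_set` with elements `variants`
#'   (sorted character vector) and `provenance` (named list: rsID ->
#'   character vector of sources).
#' @export
merge_to_seed_set <- function(records) {
  variants <- sort(unique(records$variant_id))
  provenance <- lapply(stats::setNames(variants, variants), function(v) {
    sort(unique(records$source[records$variant_id == v]))
  })
  structure(list(variants = variants, provenance = provenance),
            class = "variant_seed_set")
}

#' @export
print.variant_seed_set <- function(x, ...) {
  cat(sprintf("<variant_seed_set> %d variants\n", length(x$variants)))
  invisible(x)
}
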