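CANONICAL_SOURCES <- c("GWAS", "PheWAS")
KNOWN_DRUG_GROUPS <- c("approved", "investigational", "experimental")

#' Normalize a p-value string to parseable numeric form
#'
#' Catalog exports print p-values in several dialects: plain decimals,
#' ASCII scientific notation (`1e-6`), and typeset scientific notation
#' such as `3.2 x 10-5` with a Unicode multiplication sign and a Unicode
#' minus (U+2212). All are normalized to ASCII `e`-notation before
#' parsing.
#'
#' @param x character vector of p-value strings.
#' @return numeric vector; `NA` where a string is unparseable.
#' @examples
#' parse_pvalue(c("1e-6", "3.2 × 10−5", "0.05"))
#' @export
parse_pvalue <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("−", "-", x)                       # Unicode minus
  x <- gsub("×", "x", x)                       # multiplication sign
  # "3.2 x 10^-5" / "3.2 x 10-5" -> "3.2e-5"
  x <- sub("^([0-9]*\\.?[0-9]+)\\s*[xX]\\s*10\\^?\\s*(-?[0-9]+)$", "\\1e\\2", x)
  # bare power "10^-5" / "10-5" -> "1e-5"
  x <- sub("^10\\^?(-[0-9]+)$", "1e\\1", x)
  suppressWarnings(as.numeric(x))
}

normalize_symbol <- function(x) toupper(trimws(as.character(x)))

parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0", "")] <- FALSE
  out
}

read_tsv_raw <- function(path) {
  stopifnot(file.exists(path))
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = character())
}

require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0) {
    stop(sprintf("file '%s' is missing mandatory column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(tab)
}

apply_dialect <- function(tab, dialect) {
  if (is.null(dialect)) return(tab)
  # dialect maps canonical name -> file column name
  for (canon in names(dialect)) {
    file_col <- dialect[[canon]]
    if (file_col %in% names(tab)) names(tab)[names(tab) == file_col] <- canon
  }
  tab
}

finalize_read <- function(records, rejections, strict, what) {
  rej <- tibble::tibble(
    line = as.integer(vapply(rejections, `[[`, integer(1), "line")),
    reason = vapply(rejections, `[[`, character(1), "reason")
  )
  if (strict && nrow(rej) > 0) {
    stop(sprintf("%s: line %d: %s", what, rej$line[1], rej$reason[1]), call. = FALSE)
  }
  if (nrow(rej) > 0) {
    message(sprintf("%s: skipped %d bad row(s); first: line %d: %s",
                    what, nrow(rej), rej$line[1], rej$reason[1]))
  }
  attr(records, "rejections") <- rej
  records
}

#' Rejected rows recorded by a reader
#'
#' Readers in lenient mode skip malformed rows rather than aborting; the
#' skipped rows are kept as an attribute so that
#' `rows_in == nrow(records) + nrow(rejections(records))` always holds.
#'
#' @param x a table returned by one of the `read_*` functions.
#' @return tibble with columns `line` (1-based data-row number) and `reason`.
#' @export
rejections <- function(x) {
  r <- attr(x, "rejections")
  if (is.null(r)) tibble::tibble(line = integer(), reason = character()) else r
}

#' Read a variant-trait association table
#'
#' Expects a TSV with header and columns `variant_id`, `source`, `trait`,
#' `p_value` (a `dialect` map can rename file columns to these canonical
#' names). Sources must be `GWAS` or `PheWAS`; p-values must lie in (0, 1]
#' and may be written in scientific notation, including the typeset
#' `a x 10-b` form (see [parse_pvalue()]).
#'
#' @param path TSV file path.
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(variant_id = "SNPS")`.
#' @param strict if `TRUE`, abort on the first malformed row; default
#'   `FALSE` logs and skips (catalog exports are dirty in practice).
#' @return tibble with columns `variant_id`, `source`, `trait`, `p_value`,
#'   in file order; rejected rows are available via [rejections()].
#' @export
read_association_table <- function(path, dialect = NULL, strict = FALSE) {
  tab <- apply_dialect(read_tsv_raw(path), dialect)
  require_columns(tab, c("variant_id", "source", "trait", "p_value"), path)
  keep <- logical(nrow(tab))
  rej <- list()
  p <- parse_pvalue(tab$p_value)
  vid <- trimws(tab$variant_id)
  src <- trimws(tab$source)
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(vid[i])) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "empty variant_id")
    } else if (!(src[i] %in% CANONICAL_SOURCES)) {
      rej[[length(rej) + 1]] <- list(line = i, reason = sprintf("unknown source '%s'", src[i]))
    } else if (is.na(p[i])) {
      rej[[length(rej) + 1]] <- list(line = i, reason = sprintf("unparseable p-value '%s'", tab$p_value[i]))
    } else if (p[i] <= 0 || p[i] > 1) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "p-value out of (0,1]")
    } else {
      keep[i] <- TRUE
    }
  }
  out <- tibble::tibble(variant_id = vid[keep], source = src[keep],
                        trait = trimws(tab$trait)[keep], p_value = p[keep])
  finalize_read(out, rej, strict, sprintf("associations '%s'", basename(path)))
}

#' Write an association table as TSV
#' @param records tibble as returned by [read_association_table()].
#' @param path output path.
#' @export
write_association_table <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read an LD proxy table (HaploReg-style export)
#'
#' Columns: `lead_variant`, `proxy_variant`, `r2`, `population`, `gene`
#' (may be empty), `is_missense`. Rows where the lead and proxy coincide
#' must carry r2 = 1.
#'
#' @inheritParams read_association_table
#' @return tibble of LD records; gene symbols upper-cased.
#' @export
read_ld_table <- function(path, dialect = NULL, strict = FALSE) {
  tab <- apply_dialect(read_tsv_raw(path), dialect)
  require_columns(tab, c("lead_variant", "proxy_variant", "r2", "population",
                         "gene", "is_missense"), path)
  r2 <- suppressWarnings(as.numeric(tab$r2))
  mis <- parse_flag(tab$is_missense)
  lead <- trimws(tab$lead_variant); proxy <- trimws(tab$proxy_variant)
  keep <- logical(nrow(tab)); rej <- list()
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(lead[i]) || !nzchar(proxy[i])) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "empty variant id")
    } else if (is.na(r2[i]) || r2[i] < 0 || r2[i] > 1) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "r2 out of [0,1]")
    } else if (lead[i] == proxy[i] && r2[i] != 1) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "self LD row with r2 != 1")
    } else if (is.na(mis[i])) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "unparseable is_missense flag")
    } else {
      keep[i] <- TRUE
    }
  }
  out <- tibble::tibble(
    lead_variant = lead[keep], proxy_variant = proxy[keep], r2 = r2[keep],
    population = trimws(tab$population)[keep],
    gene = normalize_symbol(tab$gene)[keep], is_missense = mis[keep]
  )
  finalize_read(out, rej, strict, sprintf("LD table '%s'", basename(path)))
}

#' @rdname read_ld_table
#' @param records tibble of LD records.
#' @export
write_ld_table <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a cis-eQTL table
#'
#' Columns: `variant_id`, `gene`, `tissue`, `is_significant`. Gene and
#' tissue must be non-empty.
#'
#' @inheritParams read_association_table
#' @return tibble of eQTL records.
#' @export
read_eqtl_table <- function(path, dialect = NULL, strict = FALSE) {
  tab <- apply_dialect(read_tsv_raw(path), dialect)
  require_columns(tab, c("variant_id", "gene", "tissue", "is_significant"), path)
  sig <- parse_flag(tab$is_significant)
  gene <- normalize_symbol(tab$gene); tissue <- trimws(tab$tissue)
  vid <- trimws(tab$variant_id)
  keep <- logical(nrow(tab)); rej <- list()
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(vid[i]) || !nzchar(gene[i]) || !nzchar(tissue[i])) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "empty variant/gene/tissue")
    } else if (is.na(sig[i])) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "unparseable is_significant flag")
    } else {
      keep[i] <- TRUE
    }
  }
  out <- tibble::tibble(variant_id = vid[keep], gene = gene[keep],
                        tissue = tissue[keep], is_significant = sig[keep])
  finalize_read(out, rej, strict, sprintf("eQTL table '%s'", basename(path)))
}

#' @rdname read_eqtl_table
#' @param records tibble of eQTL records.
#' @export
write_eqtl_table <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param namespace one of `"MP"`, `"GOBP"`, `"KEGG"`.
#' @param sets named list; each element a list with `name` (description)
#'   and `genes` (character vector of member symbols).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(namespace, sets) {
  namespace <- match.arg(namespace, c("MP", "GOBP", "KEGG"))
  stopifnot(is.list(sets))
  if (length(sets) > 0) {
    stopifnot(!is.null(names(sets)), !anyDuplicated(names(sets)))
    sets <- lapply(sets, function(s) {
      genes <- unique(normalize_symbol(s$genes))
      genes <- genes[nzchar(genes)]
      if (length(genes) == 0) stop("gene set with no members", call. = FALSE)
      list(name = as.character(s$name), genes = genes)
    })
  }
  structure(list(namespace = namespace, sets = sets),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> namespace %s: %d sets, %d distinct genes\n",
              x$namespace, length(x$sets), length(collection_universe(x))))
  invisible(x)
}

#' All genes appearing in at least one set of a collection
#' @param collection a `gene_set_collection`.
#' @return sorted character vector of gene symbols.
#' @export
collection_universe <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sort(unique(unlist(lapply(collection$sets, `[[`, "genes"), use.names = FALSE)))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `set_id<TAB>description<TAB>member...`. Duplicate members within a set
#' are collapsed; member symbols are upper-cased; lines with fewer than
#' three fields are a format error.
#'
#' @param path GMT file path.
#' @param namespace collection namespace (`"MP"`, `"GOBP"`, `"KEGG"`).
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path, namespace = "MP") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning(sprintf("GMT file '%s' is empty", basename(path)), call. = FALSE)
    return(gene_set_collection(namespace, stats::setNames(list(), character())))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT '%s' line %d: expected >= 3 tab-separated fields",
                   basename(path), i), call. = FALSE)
    }
    sets[[fields[1]]] <- list(name = fields[2], genes = fields[-(1:2)])
  }
  gene_set_collection(namespace, sets)
}

#' Write a gene-set collection as GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    paste(c(id, s$name, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug-target table (DrugBank-style extract)
#'
#' Columns: `drug_id`, `drug_name`, `target_gene`, `action`,
#' `has_pharmacological_action`, `groups` (a `|`-separated list drawn from
#' approved / investigational / experimental; unknown tokens are kept but
#' flagged with a warning), `indication_text`. Rows without a target gene
#' are rejected.
#'
#' @inheritParams read_association_table
#' @return tibble with `groups` as a list-column of character vectors.
#' @export
read_drug_target_table <- function(path, dialect = NULL, strict = FALSE) {
  tab <- apply_dialect(read_tsv_raw(path), dialect)
  require_columns(tab, c("drug_id", "drug_name", "target_gene", "action",
                         "has_pharmacological_action", "groups",
                         "indication_text"), path)
  pharm <- parse_flag(tab$has_pharmacological_action)
  gene <- normalize_symbol(tab$target_gene)
  keep <- logical(nrow(tab)); rej <- list()
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(trimws(tab$drug_id[i])) || !nzchar(trimws(tab$drug_name[i]))) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "empty drug id/name")
    } else if (!nzchar(gene[i])) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "missing target gene")
    } else if (is.na(pharm[i])) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "unparseable pharmacological-action flag")
    } else {
      keep[i] <- TRUE
    }
  }
  groups <- lapply(tab$groups, function(g) {
    toks <- tolower(trimws(strsplit(as.character(g), "|", fixed = TRUE)[[1]]))
    toks[nzchar(toks)]
  })
  unknown <- sort(unique(setdiff(unlist(groups[keep]), KNOWN_DRUG_GROUPS)))
  if (length(unknown) > 0) {
    warning(sprintf("drug-target table '%s': unknown group token(s) kept: %s",
                    basename(path), paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(
    drug_id = trimws(tab$drug_id)[keep], drug_name = trimws(tab$drug_name)[keep],
    target_gene = gene[keep], action = trimws(tab$action)[keep],
    has_pharmacological_action = pharm[keep], groups = groups[keep],
    indication_text = trimws(tab$indication_text)[keep]
  )
  attr(out, "unknown_groups") <- unknown
  finalize_read(out, rej, strict, sprintf("drug-target table '%s'", basename(path)))
}

#' @rdname read_drug_target_table
#' @param records tibble of drug-target records (as from
#'   [read_drug_target_table()]).
#' @export
write_drug_target_table <- function(records, path) {
  flat <- records
  flat$groups <- vapply(records$groups, paste, character(1), collapse = "|")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical/preclinical evidence table
#'
#' Columns: `drug_name`, `disease`, `kind` (`trial` | `publication`),
#' `registry_id`, `phase`, `pub_id`, `is_preclinical`. Trials must carry a
#' registry id, publications a publication id, and the preclinical flag is
#' only meaningful for publications.
#'
#' @inheritParams read_association_table
#' @return tibble of evidence records.
#' @export
read_evidence_table <- function(path, dialect = NULL, strict = FALSE) {
  tab <- apply_dialect(read_tsv_raw(path), dialect)
  require_columns(tab, c("drug_name", "disease", "kind", "registry_id",
                         "phase", "pub_id", "is_preclinical"), path)
  pre <- parse_flag(tab$is_preclinical)
  kind <- tolower(trimws(tab$kind))
  keep <- logical(nrow(tab)); rej <- list()
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(trimws(tab$drug_name[i]))) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "empty drug name")
    } else if (!(kind[i] %in% c("trial", "publication"))) {
      rej[[length(rej) + 1]] <- list(line = i, reason = sprintf("unknown evidence kind '%s'", kind[i]))
    } else if (kind[i] == "trial" && !nzchar(trimws(tab$registry_id[i]))) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "trial without registry id")
    } else if (kind[i] == "publication" && !nzchar(trimws(tab$pub_id[i]))) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "publication without pub id")
    } else if (is.na(pre[i]) || (pre[i] && kind[i] != "publication")) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "preclinical flag only valid for publications")
    } else {
      keep[i] <- TRUE
    }
  }
  out <- tibble::tibble(
    drug_name = trimws(tab$drug_name)[keep], disease = trimws(tab$disease)[keep],
    kind = kind[keep], registry_id = trimws(tab$registry_id)[keep],
    phase = trimws(tab$phase)[keep], pub_id = trimws(tab$pub_id)[keep],
    is_preclinical = pre[keep]
  )
  finalize_read(out, rej, strict, sprintf("evidence table '%s'", basename(path)))
}

#' @rdname read_evidence_table
#' @param records tibble of evidence records.
#' @export
write_evidence_table <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Write a gene-drug edge list as TSV
#'
#' A tabular stand-in for chord-diagram figures: one row per gene-drug
#' edge, sorted by gene then drug name then drug id so the output is
#' byte-identical regardless of input order.
#'
#' @param edges tibble with at least `gene`, `drug_id`, `drug_name`;
#'   additional columns (e.g. `action`, `tier`) are carried through.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(!is.null(edges))
  if (nrow(edges) > 0) {
    ord <- order(edges$gene, edges$drug_name, edges$drug_id, method = "radix")
    edges <- edges[ord, , drop = FALSE]
  }
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}
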