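REAL_SYMBOLS <- c("IL6R", "IL5", "HMGCR", "ADORA1", "CD86", "NOS1", "BCR", "PIK3CD")

#' Parameters for the synthetic mini-universe
#'
#' Defines the study conditions emulated by [generate_universe()]: a gene
#' universe, seed/decoy variants with catalog-style p-values, LD blocks,
#' per-criterion annotation flags, gene-set collections with one planted
#' enriched set each, and a drug-target table with an evidence tier mix.
#'
#' @param n_genes gene universe size.
#' @param n_seed_variants variants with genuine (sub-threshold) catalog
#'   associations; must be >= `planted_risk_genes`.
#' @param n_decoy_variants variants with null (super-threshold) p-values.
#' @param ld_block_size proxies per seed variant at `r2_high`.
#' @param r2_high r2 of true proxies (must exceed 0.8, the mapping cutoff).
#' @param r2_low r2 of decoy LD rows (must be <= 0.8, so they never map).
#' @param frac_missense,frac_eqtl probability that a planted missense /
#'   cis-eQTL membership is realized as a flag in the tables; 1 is the
#'   noise-free regime (the recorded ground truth is the realized
#'   membership).
#' @param n_sets_per_collection sets per namespace, planted set included.
#' @param set_size_range integer pair: min/max genes per set.
#' @param planted_risk_genes number of genes reachable from seed variants.
#' @param enrichment_strength target fold-enrichment (observed overlap
#'   over its null expectation) of the planted sets; 1 means the planted
#'   sets are drawn uniformly like the decoys (null universe).
#' @param n_drugs drugs targeting the planted biological genes.
#' @param tier_mix named proportions over approved / clinical /
#'   preclinical / novel; must sum to 1.
#' @param rng_seed integer seed governing all randomness.
#' @return validated `synthetic_params` list.
#' @export
synthetic_params <- function(n_genes = 800,
                             n_seed_variants = 40,
                             n_decoy_variants = 40,
                             ld_block_size = 3,
                             r2_high = 0.95,
                             r2_low = 0.5,
                             frac_missense = 1,
                             frac_eqtl = 1,
                             n_sets_per_collection = 25,
                             set_size_range = c(10, 25),
                             planted_risk_genes = 30,
                             enrichment_strength = 5,
                             n_drugs = 30,
                             tier_mix = c(approved = 0.15, clinical = 0.25,
                                          preclinical = 0.15, novel = 0.45),
                             rng_seed = 1) {
  p <- as.list(environment())
  stopifnot(p$n_genes >= length(REAL_SYMBOLS),
            p$planted_risk_genes >= 1,
            p$planted_risk_genes <= p$n_genes,
            p$planted_risk_genes <= p$n_seed_variants,
            p$ld_block_size >= 1,
            p$r2_high > 0.8, p$r2_high <= 1,
            p$r2_low >= 0, p$r2_low <= 0.8,
            p$frac_missense >= 0, p$frac_missense <= 1,
            p$frac_eqtl >= 0, p$frac_eqtl <= 1,
            p$n_sets_per_collection >= 2,
            length(p$set_size_range) == 2,
            p$set_size_range[1] >= 2,
            p$set_size_range[1] <= p$set_size_range[2],
            p$enrichment_strength >= 1,
            p$n_drugs >= 0)
  if (p$set_size_range[2] > p$n_genes - p$planted_risk_genes) {
    stop("infeasible params: set sizes exceed the non-planted gene pool", call. = FALSE)
  }
  stopifnot(setequal(names(p$tier_mix), DRUG_TIERS))
  if (abs(sum(p$tier_mix) - 1) > 1e-8) {
    stop("infeasible params: tier_mix proportions must sum to 1", call. = FALSE)
  }
  structure(p, class = "synthetic_params")
}

runif_log <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))

#' Generate a synthetic mini-universe with planted ground truth
#'
#' Emulates all six pipeline inputs offline. Seed variants carry
#' p-values drawn log-uniformly below a tenth of the per-source cutoff;
#' decoys above ten times the cutoff, so the harvest filter is
#' unambiguous. Each planted gene hangs off one seed variant with
#' `ld_block_size` proxies at `r2_high`; decoy LD rows sit at `r2_low` or
#' in a non-matching population. Criterion flags (missense, lung
#' cis-eQTL, membership in the planted enriched set of each namespace)
#' follow a per-gene planted criterion membership; the recorded ground
#' truth is the realized membership, so `planted_biological_genes` is
#' always `{g : |membership(g)| >= 2}`. Non-novel drugs receive matching
#' evidence records (trial registrations or preclinical publications) or
#' a disease-matching indication; novel drugs targeting a gene shared
#' with a non-novel drug are the planted repurposing candidates.
#'
#' When `enrichment_strength > 1`, decoy gene sets are drawn from the
#' non-planted gene pool so the planted signal is exactly separable; at
#' `enrichment_strength = 1` every set (planted included) is drawn
#' uniformly from the whole universe — the null regime.
#'
#' @param params a [synthetic_params()] object.
#' @return object of class `synthetic_universe`: `tables` (associations,
#'   ld, eqtl, gene_sets as a named list of `gene_set_collection`s,
#'   drug_targets, evidence), `truth` (planted ground truth), `params`.
#' @export
generate_universe <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "synthetic_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$rng_seed)

  genes <- c(REAL_SYMBOLS, sprintf("G%04d", seq_len(params$n_genes - length(REAL_SYMBOLS))))
  planted <- sort(sample(genes, params$planted_risk_genes))
  nonplanted <- setdiff(genes, planted)

  ## --- planted criterion memberships -------------------------------------
  membership <- lapply(stats::setNames(planted, planted), function(g) {
    size <- sample(0:5, 1, prob = c(0.12, 0.18, 0.30, 0.22, 0.12, 0.06))
    sort(sample(CRITERION_NAMES, size))
  })
  # each ORA namespace needs enough members for its planted set to be
  # detectable; top up to 5 (or all planted genes, if fewer)
  for (crit in c("ko_mouse", "ppi_gobp", "kegg")) {
    want <- min(5, length(planted))
    have <- names(membership)[vapply(membership, function(m) crit %in% m, logical(1))]
    if (length(have) < want) {
      add <- sample(setdiff(planted, have), want - length(have))
      for (g in add) membership[[g]] <- sort(c(membership[[g]], crit))
    }
  }
  # realize stochastic flag criteria; ground truth is the realized membership
  for (g in planted) {
    m <- membership[[g]]
    if ("missense" %in% m && stats::runif(1) >= params$frac_missense) m <- setdiff(m, "missense")
    if ("cis_eqtl" %in% m && stats::runif(1) >= params$frac_eqtl) m <- setdiff(m, "cis_eqtl")
    membership[[g]] <- m
  }
  # guarantee some biological genes so the drug stage is exercised
  n_bio_min <- min(5, length(planted))
  repeat {
    scores <- vapply(membership, length, integer(1))
    if (sum(scores >= 2) >= n_bio_min) break
    g <- names(scores)[scores < 2][1]
    membership[[g]] <- sort(union(membership[[g]], sample(setdiff(CRITERION_NAMES, membership[[g]]), 1)))
  }
  biological <- sort(names(membership)[vapply(membership, length, integer(1)) >= 2])

  ## --- variants and associations -----------------------------------------
  seeds <- sprintf("RSS%04d", seq_len(params$n_seed_variants))
  decoys <- sprintf("RSD%04d", seq_len(params$n_decoy_variants))
  gene_seed <- stats::setNames(seeds[seq_along(planted)], planted)
  thresholds <- c(GWAS = 1e-5, PheWAS = 0.05)
  traits <- c("asthma", "childhood asthma", "adult-onset asthma")

  seed_src <- rep(c("GWAS", "PheWAS"), length.out = length(seeds))
  seed_p <- vapply(seed_src, function(s) runif_log(1, 1e-12, thresholds[[s]] / 10), numeric(1))
  decoy_src <- rep(c("GWAS", "PheWAS"), length.out = length(decoys))
  decoy_p <- vapply(decoy_src, function(s) runif_log(1, min(thresholds[[s]] * 10, 0.99), 1), numeric(1))
  assoc <- tibble::tibble(
    variant_id = c(seeds, decoys),
    source = c(seed_src, decoy_src),
    trait = sample(traits, length(seeds) + length(decoys), replace = TRUE),
    p_value = c(seed_p, decoy_p)
  )
  # a few seeds reported by both catalogs, to exercise provenance merging
  dual <- seeds[seq_len(min(3, length(seeds)))]
  dual_src <- ifelse(seed_src[seq_along(dual)] == "GWAS", "PheWAS", "GWAS")
  assoc <- dplyr::bind_rows(assoc, tibble::tibble(
    variant_id = dual, source = dual_src, trait = "asthma",
    p_value = vapply(dual_src, function(s) runif_log(1, 1e-12, thresholds[[s]] / 10), numeric(1))
  ))

  ## --- LD table -----------------------------------------------------------
  pop <- "ASN"
  ld_rows <- list()
  for (i in seq_along(planted)) {
    g <- planted[i]; s <- gene_seed[[g]]
    has_missense <- "missense" %in% membership[[g]]
    proxies <- sprintf("%s_P%02d", s, seq_len(params$ld_block_size))
    ld_rows[[length(ld_rows) + 1]] <- tibble::tibble(
      lead_variant = s,
      proxy_variant = c(s, proxies),
      r2 = c(1, rep(params$r2_high, length(proxies))),
      population = pop,
      gene = g,
      is_missense = c(FALSE, has_missense, rep(FALSE, length(proxies) - 1))
    )
    # decoy rows: weak LD and wrong population never map
    ld_rows[[length(ld_rows) + 1]] <- tibble::tibble(
      lead_variant = s,
      proxy_variant = c(sprintf("%s_LOW", s), sprintf("%s_EUR", s)),
      r2 = c(params$r2_low, params$r2_high),
      population = c(pop, "EUR"),
      gene = sample(nonplanted, 2),
      is_missense = c(TRUE, FALSE)
    )
  }
  extra_seeds <- seeds[-seq_along(planted)]
  if (length(extra_seeds) > 0) {
    ld_rows[[length(ld_rows) + 1]] <- tibble::tibble(
      lead_variant = extra_seeds, proxy_variant = extra_seeds, r2 = 1,
      population = pop, gene = "", is_missense = FALSE
    )
  }
  ld <- dplyr::bind_rows(ld_rows)

  ## --- eQTL table ---------------------------------------------------------
  eqtl_rows <- lapply(planted, function(g) {
    s <- gene_seed[[g]]
    if ("cis_eqtl" %in% membership[[g]]) {
      tibble::tibble(variant_id = s, gene = g, tissue = "lung", is_significant = TRUE)
    } else {
      tibble::tibble(variant_id = c(s, s), gene = g,
                     tissue = c("lung", "whole blood"),
                     is_significant = c(FALSE, TRUE))
    }
  })
  # significant lung eQTL on a variant outside the gene's risk set: no credit
  eqtl_rows[[length(eqtl_rows) + 1]] <- tibble::tibble(
    variant_id = decoys[1], gene = planted[1], tissue = "lung", is_significant = TRUE
  )
  eqtl <- dplyr::bind_rows(eqtl_rows)

  ## --- gene-set collections ------------------------------------------------
  ns_crit <- c(MP = "ko_mouse", GOBP = "ppi_gobp", KEGG = "kegg")
  null_universe <- params$enrichment_strength == 1
  gene_sets <- lapply(names(ns_crit), function(ns) {
    crit <- ns_crit[[ns]]
    sets <- list()
    members <- sort(names(membership)[vapply(membership, function(m) crit %in% m, logical(1))])
    planted_id <- sprintf("%s_S001", ns)
    k_sizes <- sample(params$set_size_range[1]:params$set_size_range[2],
                      params$n_sets_per_collection, replace = TRUE)
    if (null_universe) {
      sets[[planted_id]] <- list(name = sprintf("%s planted set", ns),
                                 genes = sample(genes, k_sizes[1]))
    } else {
      # cap the set size so overlap/expectation stays >= enrichment_strength
      k_cap <- floor(length(members) * params$n_genes /
                       (params$enrichment_strength * params$planted_risk_genes))
      K <- max(min(k_sizes[1], k_cap), length(members))
      fillers <- sample(nonplanted, K - length(members))
      sets[[planted_id]] <- list(name = sprintf("%s planted set", ns),
                                 genes = c(members, fillers))
    }
    decoy_pool <- if (null_universe) genes else nonplanted
    for (j in 2:params$n_sets_per_collection) {
      sets[[sprintf("%s_S%03d", ns, j)]] <- list(
        name = sprintf("%s decoy set %d", ns, j),
        genes = sample(decoy_pool, k_sizes[j])
      )
    }
    gene_set_collection(ns, sets)
  })
  names(gene_sets) <- names(ns_crit)

  ## --- drugs and evidence ---------------------------------------------------
  counts <- floor(params$n_drugs * params$tier_mix[DRUG_TIERS])
  counts["novel"] <- counts["novel"] + params$n_drugs - sum(counts)
  tier_of <- rep(DRUG_TIERS, times = counts)
  drug_names <- sprintf("drug%03d", seq_len(params$n_drugs))
  drug_ids <- sprintf("DB%05d", seq_len(params$n_drugs))
  nonnovel <- which(tier_of != "novel")
  novel <- which(tier_of == "novel")
  target_of <- character(params$n_drugs)
  if (length(nonnovel) > 0) {
    target_of[nonnovel] <- sample(biological, length(nonnovel), replace = TRUE)
  }
  promising_pool <- sort(unique(target_of[nonnovel]))
  spare <- setdiff(biological, promising_pool)
  for (idx in seq_along(novel)) {
    i <- novel[idx]
    target_of[i] <- if (idx %% 2 == 1 && length(promising_pool) > 0) {
      sample(promising_pool, 1)
    } else if (length(spare) > 0) {
      sample(spare, 1)
    } else if (length(biological) > 0) {
      sample(biological, 1)
    } else {
      sample(genes, 1)
    }
  }
  planted_candidates <- sort(drug_names[novel][target_of[novel] %in% promising_pool])

  other_indications <- c("hypercholesterolemia", "rheumatoid arthritis",
                         "epilepsy", "tachycardia", "chronic myelogenous leukaemia")
  drug_targets <- tibble::tibble(
    drug_id = drug_ids, drug_name = drug_names, target_gene = target_of,
    action = sample(c("inhibitor", "agonist", "antagonist"), params$n_drugs, replace = TRUE),
    has_pharmacological_action = TRUE,
    groups = lapply(tier_of, function(t) {
      if (t == "novel") sample(list("investigational", "experimental",
                                    c("approved", "investigational")), 1)[[1]] else "approved"
    }),
    indication_text = ifelse(tier_of == "approved", "asthma maintenance therapy",
                             sample(other_indications, params$n_drugs, replace = TRUE))
  )
  if (params$n_drugs > 0) {
    # decoy rows: off-list target gene, and a target without pharmacological action
    drug_targets <- dplyr::bind_rows(drug_targets, tibble::tibble(
      drug_id = c("DB99998", "DB99999"), drug_name = c("decoy_offlist", "decoy_nopharm"),
      target_gene = c(sample(nonplanted, 1),
                      if (length(biological) > 0) biological[1] else sample(genes, 1)),
      action = "inhibitor",
      has_pharmacological_action = c(TRUE, FALSE),
      groups = list("approved", "approved"),
      indication_text = "hypertension"
    ))
  }

  ev_rows <- list()
  for (i in seq_len(params$n_drugs)) {
    if (tier_of[i] == "clinical") {
      ev_rows[[length(ev_rows) + 1]] <- tibble::tibble(
        drug_name = drug_names[i], disease = "asthma", kind = "trial",
        registry_id = sprintf("NCT%08d", i), phase = "Phase II",
        pub_id = "", is_preclinical = FALSE
      )
    } else if (tier_of[i] == "preclinical") {
      ev_rows[[length(ev_rows) + 1]] <- tibble::tibble(
        drug_name = drug_names[i], disease = "asthma", kind = "publication",
        registry_id = "", phase = "", pub_id = sprintf("%08d", 20000000 + i),
        is_preclinical = TRUE
      )
    }
  }
  evidence <- if (length(ev_rows) > 0) dplyr::bind_rows(ev_rows) else
    tibble::tibble(drug_name = character(), disease = character(), kind = character(),
                   registry_id = character(), phase = character(), pub_id = character(),
                   is_preclinical = logical())

  truth <- list(
    planted_genes = planted,
    criterion_membership = membership,
    planted_biological_genes = biological,
    planted_enriched_sets = stats::setNames(
      as.list(sprintf("%s_S001", names(ns_crit))), names(ns_crit)),
    promising_genes = promising_pool,
    planted_candidates = planted_candidates,
    tier_assignment = stats::setNames(tier_of, drug_names),
    seed_variants = seeds,
    gene_seed_variant = gene_seed
  )
  structure(list(
    tables = list(associations = assoc, ld = ld, eqtl = eqtl,
                  gene_sets = gene_sets, drug_targets = drug_targets,
                  evidence = evidence),
    truth = truth, params = params
  ), class = "synthetic_universe")
}

#' @export
print.synthetic_universe <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_universe> %d genes, %d planted risk genes ",
                     "(%d biological), %d drugs (%d planted candidates)\n"),
              x$params$n_genes, length(x$truth$planted_genes),
              length(x$truth$planted_biological_genes),
              x$params$n_drugs, length(x$truth$planted_candidates)))
  invisible(x)
}

format_pvalue_typeset <- function(p) {
  s <- strsplit(sprintf("%.3e", p), "e")[[1]]
  sprintf("%s × 10−%d", s[1], abs(as.integer(s[2])))
}

#' Write a synthetic universe to disk
#'
#' Writes the six input tables (TSV / GMT) plus `ground_truth.json` into
#' a directory. Every fifth association p-value is written in typeset
#' scientific notation (`a × 10−b`, Unicode minus) to exercise the
#' reader's normalization; the re-read value agrees to three significant
#' digits.
#'
#' @param universe a `synthetic_universe`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "synthetic_universe"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t <- universe$tables
  paths <- c(
    associations = file.path(dir, "associations.tsv"),
    ld = file.path(dir, "ld.tsv"),
    eqtl = file.path(dir, "eqtl.tsv"),
    MP = file.path(dir, "mp.gmt"),
    GOBP = file.path(dir, "gobp.gmt"),
    KEGG = file.path(dir, "kegg.gmt"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    evidence = file.path(dir, "evidence.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  assoc <- t$associations
  p_str <- sprintf("%.6g", assoc$p_value)
  typeset <- seq_len(nrow(assoc)) %% 5 == 0
  p_str[typeset] <- vapply(assoc$p_value[typeset], format_pvalue_typeset, character(1))
  assoc_out <- assoc
  assoc_out$p_value <- p_str
  readr::write_tsv(assoc_out, paths[["associations"]], progress = FALSE)
  write_ld_table(t$ld, paths[["ld"]])
  write_eqtl_table(t$eqtl, paths[["eqtl"]])
  for (ns in names(t$gene_sets)) write_gmt(t$gene_sets[[ns]], paths[[ns]])
  write_drug_target_table(t$drug_targets, paths[["drug_targets"]])
  write_evidence_table(t$evidence, paths[["evidence"]])
  jsonlite::write_json(universe$truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
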