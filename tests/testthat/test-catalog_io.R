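test_that("association reader maps rows, normalizes typeset scientific notation, rejects bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  make_assoc_tsv(f, c(
    "rs1\tGWAS\tasthma\t1e-6",
    "rs2\tPheWAS\tasthma\t3.2 × 10−5",
    "rs3\tGWAS\tasthma\t0",
    "rs4\tGWAS\tasthma\tnot_a_number"
  ))
  rec <- suppressMessages(read_association_table(f))
  expect_equal(nrow(rec), 2)
  expect_equal(rec$variant_id, c("rs1", "rs2"))
  expect_equal(rec$p_value, c(1e-6, 3.2e-5))
  rej <- rejections(rec)
  expect_equal(nrow(rej), 2)
  expect_match(rej$reason[1], "out of \\(0,1\\]")
  # accounting: rows in = records out + rejections
  expect_equal(4, nrow(rec) + nrow(rej))
  # strict mode aborts on the first bad row
  expect_error(read_association_table(f, strict = TRUE), "out of \\(0,1\\]")
})

test_that("missing mandatory column is a format error naming the column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tsource\ttrait", "rs1\tGWAS\tasthma"), f)
  expect_error(read_association_table(f), "p_value")
})

test_that("dialect maps file column names onto the canonical schema", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNPS\tsource\ttrait\tP-VALUE", "rs1\tGWAS\tasthma\t1e-8"), f)
  rec <- read_association_table(f, dialect = c(variant_id = "SNPS", p_value = "P-VALUE"))
  expect_equal(rec$variant_id, "rs1")
  expect_equal(rec$p_value, 1e-8)
})

test_that("p-value normalization handles the printed dialects", {
  expect_equal(parse_pvalue(c("1e-6", "3.2 × 10−5", "10−5", "0.05", "2 x 10^-7")),
               c(1e-6, 3.2e-5, 1e-5, 0.05, 2e-7))
  expect_true(is.na(parse_pvalue("?")))
})

test_that("GMT reader dedups members, rejects short lines, warns on empty file", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\ta", "S2\tdesc\tB\tC"), f)
  col <- read_gmt(f, "KEGG")
  expect_equal(col$sets$S1$genes, c("A", "B"))       # dedup incl. case folding
  expect_true("B" %in% col$sets$S2$genes)            # overlap across sets allowed
  writeLines("S1\tonly_two_fields", f)
  expect_error(read_gmt(f), "line 1")
  writeLines(character(0), f)
  expect_warning(col0 <- read_gmt(f), "empty")
  expect_length(col0$sets, 0)
})

test_that("drug-target reader parses groups, flags unknown tokens, rejects missing target", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "drug_id\tdrug_name\ttarget_gene\taction\thas_pharmacological_action\tgroups\tindication_text",
    "DB001\ttocilizumab\tIL6R\tinhibitor\tyes\tapproved\trheumatoid arthritis",
    "DB002\tx\tG1\tinhibitor\tno\tapproved|investigational\t-",
    "DB003\ty\tG2\tinhibitor\tyes\tapproved|withdrawn\t-",
    "DB004\tz\t\tinhibitor\tyes\tapproved\t-"
  ), f)
  expect_warning(suppressMessages(read_drug_target_table(f)), "withdrawn")
  rec <- suppressWarnings(suppressMessages(read_drug_target_table(f)))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$groups[[1]], "approved")
  expect_equal(rec$groups[[2]], c("approved", "investigational"))
  expect_true("withdrawn" %in% rec$groups[[3]])      # unknown token preserved
  expect_equal(nrow(rejections(rec)), 1)
  expect_match(rejections(rec)$reason, "target gene")
})

test_that("LD and eQTL readers enforce their invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "lead_variant\tproxy_variant\tr2\tpopulation\tgene\tis_missense",
    "rs1\trs2\t0.9\tASN\til6r\ttrue",
    "rs1\trs1\t0.7\tASN\tIL6R\tfalse",   # self row must have r2 = 1
    "rs1\trs3\t1.5\tASN\tX\tfalse"
  ), f)
  ld <- suppressMessages(read_ld_table(f))
  expect_equal(nrow(ld), 1)
  expect_equal(ld$gene, "IL6R")          # symbols upper-cased at read time
  expect_equal(nrow(rejections(ld)), 2)

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tgene\ttissue\tis_significant",
               "rs1\tIL6R\tlung\ttrue", "rs2\t\tlung\ttrue"), g)
  eq <- suppressMessages(read_eqtl_table(g))
  expect_equal(nrow(eq), 1)
  expect_equal(nrow(rejections(eq)), 1)
})

test_that("evidence reader enforces kind-dependent id requirements", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "drug_name\tdisease\tkind\tregistry_id\tphase\tpub_id\tis_preclinical",
    "a\tasthma\ttrial\tNCT1\tPhase II\t\tfalse",
    "b\tasthma\ttrial\t\tPhase II\t\tfalse",        # trial without registry id
    "c\tasthma\tpublication\t\t\t123\ttrue",
    "d\tasthma\tpublication\t\t\t\ttrue",            # publication without pub id
    "e\tasthma\ttrial\tNCT2\t\t\ttrue"               # preclinical flag on a trial
  ), f)
  ev <- suppressMessages(read_evidence_table(f))
  expect_equal(ev$drug_name, c("a", "c"))
  expect_equal(nrow(rejections(ev)), 3)
})

test_that("tables round-trip through their writers field by field", {
  dir <- withr::local_tempdir()
  u <- generate_universe(synthetic_params(n_genes = 60, n_seed_variants = 6,
                                          n_decoy_variants = 4, planted_risk_genes = 5,
                                          n_sets_per_collection = 4,
                                          set_size_range = c(3, 6), n_drugs = 8,
                                          rng_seed = 11))
  t <- u$tables
  p <- file.path(dir, "x.tsv")
  write_association_table(t$associations, p)
  expect_equal(as.data.frame(read_association_table(p)), as.data.frame(t$associations),
               ignore_attr = TRUE)
  write_ld_table(t$ld, p)
  expect_equal(as.data.frame(read_ld_table(p)), as.data.frame(t$ld), ignore_attr = TRUE)
  write_eqtl_table(t$eqtl, p)
  expect_equal(as.data.frame(read_eqtl_table(p)), as.data.frame(t$eqtl), ignore_attr = TRUE)
  write_drug_target_table(t$drug_targets, p)
  expect_equal(as.data.frame(read_drug_target_table(p)), as.data.frame(t$drug_targets),
               ignore_attr = TRUE)
  write_evidence_table(t$evidence, p)
  expect_equal(as.data.frame(read_evidence_table(p)), as.data.frame(t$evidence),
               ignore_attr = TRUE)
  g <- file.path(dir, "x.gmt")
  write_gmt(t$gene_sets$MP, g)
  expect_equal(read_gmt(g, "MP"), t$gene_sets$MP)
})

test_that("edge-list writer is canonical: shuffled input gives byte-identical output", {
  edges <- tibble::tibble(
    gene = c("B", "A", "A", "B"), drug_id = c("D2", "D1", "D2", "D1"),
    drug_name = c("y", "x", "y", "x"), tier = "novel"
  )
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_edge_list(edges, f1)
  write_edge_list(edges[sample(4), ], f2)
  expect_identical(readLines(f1), readLines(f2))
  # empty edges: header-only file
  f3 <- withr::local_tempfile()
  write_edge_list(edges[0, ], f3)
  expect_length(readLines(f3), 1)
})
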