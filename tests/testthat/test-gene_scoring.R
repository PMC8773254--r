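two_gene_risk <- function() {
  make_risk(
    gene_to_variants = list(IL6R = c("rs1", "rs2"), G0001 = "rs3", G0002 = "rs4"),
    gene_missense = list(IL6R = TRUE, G0001 = FALSE, G0002 = FALSE)
  )
}

test_that("missense criterion follows the per-gene flag", {
  risk <- two_gene_risk()
  expect_equal(criterion_missense(risk), "IL6R")
  empty <- make_risk(list(), list())
  expect_length(criterion_missense(empty), 0)
})

test_that("eQTL criterion requires significance, the right tissue, and the gene's own variant", {
  risk <- two_gene_risk()
  eqtl <- tibble::tibble(
    variant_id = c("rs1", "rs3", "rs4", "rs99"),
    gene = c("IL6R", "G0001", "G0002", "G0002"),
    tissue = c("lung", "liver", "lung", "lung"),
    is_significant = c(TRUE, TRUE, FALSE, TRUE)
  )
  # IL6R: significant lung eQTL on its own variant -> in
  # G0001: wrong tissue -> out; G0002: not significant, and the significant
  # lung record is on rs99 which is not among its risk variants -> out
  expect_equal(criterion_eqtl(risk, eqtl, "lung"), "IL6R")
})

test_that("ORA criterion credits members of enriched sets only", {
  risk <- two_gene_risk()
  col <- gene_set_collection("KEGG", list(
    S1 = list(name = "hit", genes = c("IL6R", "G0001", "ZZZ")),
    S2 = list(name = "miss", genes = "G0002")
  ))
  ora <- tibble::tibble(set_id = c("S1", "S2"), enriched = c(TRUE, FALSE))
  expect_setequal(criterion_ora(risk, col, ora), c("G0001", "IL6R"))
  ora$enriched <- FALSE
  expect_length(criterion_ora(risk, col, ora), 0)
})

test_that("matrix assembly: indicators, row-sum scores, and the consistency error", {
  risk <- two_gene_risk()
  crit <- list(missense = "IL6R", cis_eqtl = "IL6R", ko_mouse = character(0),
               ppi_gobp = c("IL6R", "G0001"), kegg = character(0))
  m <- build_matrix(risk, crit)
  expect_equal(m$score[m$gene == "IL6R"], 3L)
  expect_equal(m$score[m$gene == "G0001"], 1L)
  expect_equal(m$score[m$gene == "G0002"], 0L)
  expect_equal(m$score, as.integer(rowSums(m[c("missense", "cis_eqtl", "ko_mouse",
                                               "ppi_gobp", "kegg")])))
  crit$kegg <- "NOT_A_RISK_GENE"
  expect_error(build_matrix(risk, crit), "outside the risk set")
})

test_that("score decomposition holds on random criterion sets (independent recount)", {
  set.seed(9)
  genes <- sprintf("G%03d", 1:40)
  risk <- make_risk(stats::setNames(as.list(paste0("rs", 1:40)), genes),
                    stats::setNames(as.list(rep(FALSE, 40)), genes))
  for (rep in 1:10) {
    crit <- lapply(stats::setNames(1:5, c("missense", "cis_eqtl", "ko_mouse",
                                          "ppi_gobp", "kegg")),
                   function(i) sample(genes, sample(0:40, 1)))
    m <- build_matrix(risk, crit)
    recount <- vapply(m$gene, function(g) {
      sum(vapply(crit, function(s) g %in% s, logical(1)))
    }, integer(1))
    expect_equal(m$score, unname(recount))
    expect_true(all(m$score >= 0 & m$score <= 5))
    # selection at min_score = 2 equals the brute-force recount rule
    expect_setequal(select_biological(m, 2), m$gene[recount >= 2])
  }
})

test_that("biological selection is boundary-inclusive and ordered score-desc then symbol", {
  risk <- make_risk(list(A = "rs1", B = "rs2", C = "rs3", D = "rs4"),
                    list(A = TRUE, B = TRUE, C = FALSE, D = FALSE))
  crit <- list(missense = c("A", "B"), cis_eqtl = c("A", "B", "C"),
               ko_mouse = "A", ppi_gobp = character(0), kegg = character(0))
  m <- build_matrix(risk, crit)
  expect_equal(select_biological(m, 2), c("A", "B"))   # score-2 gene B included
  expect_equal(select_biological(m, 0), c("A", "B", "C", "D"))
  expect_length(select_biological(m, 4), 0)
})

test_that("score histogram sums to the number of genes", {
  risk <- two_gene_risk()
  m <- build_matrix(risk, list(missense = "IL6R", cis_eqtl = character(0),
                               ko_mouse = character(0), ppi_gobp = character(0),
                               kegg = character(0)))
  h <- score_histogram(m)
  expect_equal(sum(h$n_genes), nrow(m))
})

test_that("criterion correlogram is symmetric with unit diagonal and NA for constant columns", {
  set.seed(10)
  genes <- sprintf("G%03d", 1:30)
  risk <- make_risk(stats::setNames(as.list(paste0("rs", 1:30)), genes),
                    stats::setNames(as.list(rep(FALSE, 30)), genes))
  crit <- list(missense = sample(genes, 10), cis_eqtl = sample(genes, 10),
               ko_mouse = sample(genes, 10), ppi_gobp = sample(genes, 10),
               kegg = character(0))   # constant zero column
  m <- build_matrix(risk, crit)
  cg <- criterion_correlogram(m)
  expect_true(isSymmetric(cg))
  expect_equal(unname(diag(cg)[1:4]), rep(1, 4))
  expect_true(all(is.na(cg["kegg", ])))
  # two identical columns correlate perfectly
  crit$kegg <- crit$missense
  cg2 <- criterion_correlogram(build_matrix(risk, crit))
  expect_equal(cg2["missense", "kegg"], 1)
})
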