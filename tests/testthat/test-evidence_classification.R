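trial_row <- function(drug, disease = "asthma", id = "NCT00000001") {
  tibble::tibble(drug_name = drug, disease = disease, kind = "trial",
                 registry_id = id, phase = "Phase II", pub_id = "",
                 is_preclinical = FALSE)
}
pub_row <- function(drug, disease = "asthma", preclin = TRUE, id = "12345678") {
  tibble::tibble(drug_name = drug, disease = disease, kind = "publication",
                 registry_id = "", phase = "", pub_id = id,
                 is_preclinical = preclin)
}
no_ev <- trial_row("x")[0, ]

test_that("tier precedence: approved > clinical > preclinical > novel", {
  # indication mentions the disease: approved regardless of other evidence
  c1 <- classify_drug("theophylline", "Asthma and COPD maintenance", "ADORA1",
                      trial_row("theophylline"))
  expect_equal(c1$tier, "approved")
  # trial evidence without an asthma indication: clinical
  c2 <- classify_drug("tocilizumab", "rheumatoid arthritis", "IL6R",
                      dplyr::bind_rows(trial_row("tocilizumab", id = "ACTRN12614000123640"),
                                       pub_row("tocilizumab", preclin = TRUE)))
  expect_equal(c2$tier, "clinical")
  # preclinical publication only
  c3 <- classify_drug("pitavastatin", "hypercholesterolemia", "HMGCR",
                      pub_row("pitavastatin", id = "28729731"))
  expect_equal(c3$tier, "preclinical")
  # no matching evidence at all
  c4 <- classify_drug("sarilumab", "rheumatoid arthritis", "IL6R", no_ev)
  expect_equal(c4$tier, "novel")
  expect_equal(nrow(c4$supporting), 0)
})

test_that("disease matching is term-list, case-insensitive substring, on both fields", {
  ev <- trial_row("d", disease = "Severe ASTHMA exacerbation")
  expect_equal(classify_drug("d", "other", "G1", ev)$tier, "clinical")
  # a trial for a different disease does not count
  ev2 <- trial_row("d", disease = "psoriasis")
  expect_equal(classify_drug("d", "other", "G1", ev2)$tier, "novel")
  # a non-preclinical publication never upgrades past novel
  ev3 <- pub_row("d", preclin = FALSE)
  expect_equal(classify_drug("d", "other", "G1", ev3)$tier, "novel")
  # configurable term list
  expect_equal(classify_drug("d", "chronic obstructive pulmonary disease", "G1",
                             no_ev, disease_terms = c("asthma", "pulmonary"))$tier,
               "approved")
})

test_that("adding/removing evidence promotes/demotes without hysteresis", {
  base <- pub_row("d")
  expect_equal(classify_drug("d", "other", "G1", base)$tier, "preclinical")
  promoted <- classify_drug("d", "other", "G1", dplyr::bind_rows(base, trial_row("d")))
  expect_equal(promoted$tier, "clinical")
  demoted <- classify_drug("d", "other", "G1", base)
  expect_equal(demoted$tier, "preclinical")
})

test_that("promising targets and repurposing candidates follow the tier rules", {
  edges <- tibble::tibble(
    gene = c("IL6R", "IL6R", "HMGCR", "G0001"),
    drug_id = c("D1", "D2", "D3", "D4"),
    drug_name = c("tocilizumab", "sarilumab", "cerivastatin", "othernovel"),
    action = "inhibitor"
  )
  targets <- tibble::tibble(drug_name = edges$drug_name,
                            indication_text = "rheumatoid arthritis")
  evidence <- trial_row("tocilizumab")
  cls <- classify_drugs(edges, targets, evidence)
  expect_equal(tier_summary(cls), c(approved = 0L, clinical = 1L,
                                    preclinical = 0L, novel = 3L))
  prom <- promising_targets(cls, edges)
  expect_equal(prom, "IL6R")   # HMGCR and G0001 only have novel drugs
  cand <- repurposing_candidates(cls, prom, edges)
  expect_equal(cand$drug_name, "sarilumab")
  expect_equal(cand$matched_genes[[1]], "IL6R")
  expect_equal(cand$rationale_tiers[[1]], "clinical")
  # candidate soundness by brute-force join: novel tier + shared gene with non-novel
  tiers <- vapply(cls, `[[`, character(1), "tier")
  for (d in cand$drug_name) {
    expect_equal(tiers[[d]], "novel")
    shared <- edges$gene[edges$drug_name == d]
    co <- edges$drug_name[edges$gene %in% shared & edges$drug_name != d]
    expect_true(any(tiers[co] != "novel"))
  }
  expect_error(promising_targets(cls[1], edges), "missing")
})

test_that("tier counts partition the drug set", {
  u <- generate_universe(synthetic_params(rng_seed = 8))
  res <- suppressMessages(run_pipeline(tables = u$tables))
  ts <- tier_summary(res$classifications)
  expect_equal(sum(ts), length(res$classifications))
  expect_named(ts, c("approved", "clinical", "preclinical", "novel"))
  expect_equal(tier_summary(list()),
               c(approved = 0L, clinical = 0L, preclinical = 0L, novel = 0L))
})

test_that("the bundled 17-drug evidence example splits into 12 clinical and 5 preclinical", {
  ex <- load_evidence_example()
  expect_equal(nrow(ex$table), 17)
  # evidence expansion respects the id kinds
  expect_true(all(grepl("^(NCT|ACTRN)", ex$evidence$registry_id[ex$evidence$kind == "trial"])))
  expect_true(all(ex$evidence$pub_id[ex$evidence$kind == "publication"] != ""))
  out <- classify_evidence_example(ex)
  expect_equal(out$tiers, c(approved = 0L, clinical = 12L, preclinical = 5L, novel = 0L))
  expect_equal(sum(out$tiers), 17L)
  expect_equal(out$classifications$Tocilizumab$tier, "clinical")
  expect_equal(out$classifications$Pitavastatin$tier, "preclinical")
})
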