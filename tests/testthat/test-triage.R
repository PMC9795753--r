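# Rarity filter, protein-altering predicate, suspicious-VUS rules.

test_that("rarity is a strict comparison against the disease threshold", {
  reg <- test_registry()
  expect_true(meets_rarity(0, "HCM", reg))
  expect_true(meets_rarity(2e-5, "HCM", reg))
  expect_false(meets_rarity(1e-4, "HCM", reg))
  expect_false(meets_rarity(4e-5, "HCM", reg))   # boundary excluded
  expect_true(meets_rarity(0, "possible_HCM", reg))
  expect_false(meets_rarity(2e-5, "DCM", reg))   # stricter disease
  expect_error(meets_rarity(0, "notadisease", reg), "unknown disease")
})

test_that("protein-altering covers predicted-splice subtypes", {
  expect_true(is_protein_altering("missense"))
  expect_true(is_protein_altering("frameshift"))
  expect_true(is_protein_altering("synonymous_splice_predicted"))
  expect_true(is_protein_altering("deep_intronic_splice_predicted"))
  expect_false(is_protein_altering("synonymous"))
  expect_error(is_protein_altering("nonsense_mediated"), "unknown")
})

test_that("suspicious-VUS rules require every condition", {
  reg <- test_registry()
  obs <- make_variants("T001", gene = "MYBPC3", consequence = "missense",
                       popmax_af = 0, criteria = "PM2;PP3")

  r <- assess_suspicious_vus("VUS", obs, "HCM", reg)
  expect_true(r$suspicious)
  expect_true(any(grepl("definitive", r$reasons)))

  # only a VUS is eligible
  expect_false(assess_suspicious_vus("likely_pathogenic", obs, "HCM",
                                     reg)$suspicious)
  # possible_X matches X
  expect_true(assess_suspicious_vus("VUS", obs, "possible_HCM",
                                    reg)$suspicious)
  # discordant baseline disease
  expect_false(assess_suspicious_vus("VUS", obs, "DCM", reg)$suspicious)
  # gene with sub-definitive validity for the phenotype
  obs2 <- obs; obs2$gene <- "FHOD3"
  expect_false(assess_suspicious_vus("VUS", obs2, "HCM", reg)$suspicious)
  obs2$gene <- "OBSCN"
  expect_false(assess_suspicious_vus("VUS", obs2, "HCM", reg)$suspicious)
  # too common
  obs3 <- obs; obs3$popmax_af <- 1e-4
  expect_false(assess_suspicious_vus("VUS", obs3, "HCM", reg)$suspicious)
  # not protein-altering
  obs4 <- obs; obs4$consequence <- "synonymous"
  expect_false(assess_suspicious_vus("VUS", obs4, "HCM", reg)$suspicious)
  # no pathogenic-direction evidence at all
  obs5 <- obs; obs5$criteria <- ""
  expect_false(assess_suspicious_vus("VUS", obs5, "HCM", reg)$suspicious)
  # strong benign evidence blocks the flag
  obs6 <- obs; obs6$criteria <- "PM2;PP3;BS1"
  expect_false(assess_suspicious_vus("VUS", obs6, "HCM", reg)$suspicious)
  # undifferentiated baseline has no phenotype to match
  expect_false(assess_suspicious_vus("VUS", obs, "undiagnosed",
                                     reg)$suspicious)
  # optional stricter rule: evidence beyond PM2
  obs7 <- obs; obs7$criteria <- "PM2"
  expect_true(assess_suspicious_vus("VUS", obs7, "HCM", reg)$suspicious)
  expect_false(assess_suspicious_vus(
    "VUS", obs7, "HCM", reg,
    cy_config(require_nonfreq_criterion = TRUE))$suspicious)
  # unknown gene errors by name
  obs8 <- obs; obs8$gene <- "NOTAGENE"
  expect_error(assess_suspicious_vus("VUS", obs8, "HCM", reg), "NOTAGENE")
})

test_that("classify_variant composes combination, assertion and triage", {
  reg <- test_registry()
  obs <- make_variants("T001", criteria = "PM2;PP3")
  r <- classify_variant(obs, "HCM", reg)
  expect_equal(r$classification, "VUS")
  expect_true(r$suspicious_vus)

  obs_lp <- make_variants("T001", consequence = "frameshift",
                          criteria = "PVS1;PM2")
  r <- classify_variant(obs_lp, "HCM", reg)
  expect_equal(r$classification, "likely_pathogenic")
  expect_false(r$suspicious_vus)

  # asserted classification overrides the combiner, with provenance noted
  obs_a <- make_variants("T001", criteria = "PM2;PP3",
                         asserted = "pathogenic")
  r <- classify_variant(obs_a, "HCM", reg)
  expect_equal(r$classification, "pathogenic")
  expect_false(r$suspicious_vus)
  expect_true(any(grepl("asserted", r$triage_reasons)))
})

test_that("cohort-level classification keeps the suspicious=>VUS invariant", {
  reg <- test_registry()
  p <- make_probands(3)
  v <- make_variants(c("T001", "T002", "T003"),
                     gene = c("MYBPC3", "MYH7", "TTN"),
                     consequence = c("missense", "frameshift", "missense"),
                     criteria = c("PM2;PP3", "PVS1;PM2", "PM2;PP3"))
  cl <- classify_cohort_variants(v, p, reg)
  expect_equal(cl$classification, c("VUS", "likely_pathogenic", "VUS"))
  # TTN VUS: gene definitive for DCM, not the HCM baseline
  expect_equal(cl$suspicious_vus, c(TRUE, FALSE, FALSE))
  expect_error(
    classify_cohort_variants(make_variants("ghost"), p, reg), "ghost")
})
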