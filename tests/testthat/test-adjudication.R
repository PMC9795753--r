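# Best-variant selection, concordance, the flow categories, eras.

classify_for <- function(p, v, reg = test_registry()) {
  classify_cohort_variants(v, p, reg)
}

test_that("best-variant selection is deterministic and order-independent", {
  reg <- test_registry()
  p <- make_probands(1)
  v <- make_variants(rep("T001", 3),
                     gene = c("MYH7", "MYBPC3", "TTN"),
                     consequence = c("frameshift", "missense", "missense"),
                     criteria = c("PVS1;PM2", "PM2;PP3", "PM2"))
  cl <- classify_for(p, v)
  expect_equal(select_best_variant(cl)$gene, "MYH7")  # LP beats VUS
  expect_null(select_best_variant(cl[0, ]))

  # suspicious VUS beats plain VUS, under every row ordering
  v2 <- make_variants(rep("T001", 2),
                      gene = c("TTN", "MYBPC3"),
                      consequence = "missense", criteria = "PM2;PP3")
  cl2 <- classify_for(p, v2)
  for (perm in list(1:2, 2:1)) {
    best <- select_best_variant(cl2[perm, ])
    expect_equal(best$gene, "MYBPC3")
    expect_true(best$suspicious_vus)
  }
  # full tie: lexicographic gene symbol
  v3 <- make_variants(rep("T001", 2), gene = c("MYH7", "MYBPC3"),
                      consequence = "missense", criteria = "PM2;PP3")
  cl3 <- classify_for(p, v3)
  for (perm in list(1:2, 2:1)) {
    expect_equal(select_best_variant(cl3[perm, ])$gene, "MYBPC3")
  }
})

test_that("concordance follows gene-disease validity, with diagnosis supplied for undifferentiated phenotypes", {
  reg <- test_registry()
  expect_true(concordant("HCM", "MYBPC3", reg))
  expect_true(concordant("possible_HCM", "MYBPC3", reg))
  expect_true(concordant("HCM", "FHOD3", reg))       # moderate counts
  expect_false(concordant("HCM", "OBSCN", reg))      # limited does not
  expect_false(concordant("LQTS", "MYBPC3", reg))
  expect_true(concordant("undiagnosed", "TTN", reg))
  expect_true(concordant("unexplained_SCA", "TTN", reg))
  expect_false(concordant("undiagnosed", "FHOD3", reg))  # needs definitive
  expect_error(concordant("HCM", "NOTAGENE", reg), "NOTAGENE")
})

adjudicate_one <- function(p, v, reg = test_registry()) {
  adj <- run_cohort_pipeline(p, v, reg)
  adj[, c("category", "diagnosis_change", "final_disease")]
}

test_that("the flow assigns each situation its category", {
  reg <- test_registry()
  # concordant LP/P, clinical testing
  r <- adjudicate_one(make_probands(1),
                      make_variants("T001", consequence = "frameshift",
                                    criteria = "PVS1;PM2"))
  expect_equal(r$category, "solved_baseline")
  expect_equal(r$diagnosis_change, "none")

  # research provenance: solved on review
  r <- adjudicate_one(make_probands(1, provenance = "research_tier2"),
                      make_variants("T001", gene = "FHOD3",
                                    consequence = "frameshift",
                                    criteria = "PVS1;PM2"))
  expect_equal(r$category, "solved_on_review")

  # borderline diagnosis confirmed by the result: clarified
  r <- adjudicate_one(make_probands(1, diagnosis = "possible_HCM",
                                    provenance = "research_tier2"),
                      make_variants("T001", gene = "FHOD3",
                                    consequence = "frameshift",
                                    criteria = "PVS1;PM2"))
  expect_equal(r$category, "solved_on_review")
  expect_equal(r$diagnosis_change, "clarified")

  # undifferentiated phenotype given a diagnosis: changed
  r <- adjudicate_one(make_probands(1, diagnosis = "undiagnosed"),
                      make_variants("T001", gene = "TTN",
                                    consequence = "frameshift",
                                    criteria = "PVS1;PM2"))
  expect_equal(r$category, "solved_baseline")
  expect_equal(r$diagnosis_change, "changed")
  expect_equal(r$final_disease, "DCM")

  # curated final diagnosis different from a definite baseline: changed
  p <- make_probands(1); p$final_diagnosis <- "DCM"
  r <- adjudicate_one(p, make_variants("T001", gene = "TTN",
                                       consequence = "frameshift",
                                       criteria = "PVS1;PM2"))
  expect_equal(r$category, "solved_baseline")
  expect_equal(r$diagnosis_change, "changed")

  # discordant LP/P is reviewable, never silently solved
  r <- adjudicate_one(make_probands(1, diagnosis = "LQTS"),
                      make_variants("T001", consequence = "frameshift",
                                    criteria = "PVS1;PM2"))
  expect_equal(r$category, "discordant_LPP")

  # suspicious VUS is its own category, not unsolved
  r <- adjudicate_one(make_probands(1), make_variants("T001"))
  expect_equal(r$category, "suspicious_vus")

  # no variant: unsolved split by score
  r <- adjudicate_one(make_probands(1, age = 45), make_variants(character()))
  expect_equal(r$category, "unsolved_likely_complex")
  r <- adjudicate_one(make_probands(1, age = 25, relatives = 1),
                      make_variants(character()))
  expect_equal(r$category, "unsolved_likely_monogenic")

  # exclusion flags pass through
  p <- make_probands(1); p$exclusion_reason <- "no_testing"
  r <- adjudicate_one(p, make_variants(character()))
  expect_equal(r$category, "excluded_no_testing")
})

test_that("time to diagnosis and era follow year first seen", {
  p <- make_probands(1)
  p$year_first_seen <- 2004; p$year_genetic_diagnosis <- 2016
  t <- time_to_diagnosis(p)
  expect_equal(t$years, 12)
  expect_equal(t$era, "e2002_2010")
  p$year_first_seen <- 2015; p$year_genetic_diagnosis <- 2017
  t <- time_to_diagnosis(p)
  expect_equal(t$years, 2)
  expect_equal(t$era, "e2011_2020")
  p$year_genetic_diagnosis <- 2015
  expect_equal(time_to_diagnosis(p)$years, 0)
  p$year_genetic_diagnosis <- NA
  expect_true(is.na(time_to_diagnosis(p)$years))
})

test_that("adjudication partitions a random cohort exactly", {
  sim <- simulate_cohort(sim_config(n_probands = 600, seed = 202))
  adj <- run_cohort_pipeline(sim$probands, sim$variants)
  expect_equal(nrow(adj), 600)
  expect_false(anyNA(adj$category))
  fc <- flow_counts(adj)
  expect_equal(fc$n_included,
               fc$n_solved_baseline_lpp + fc$n_solved_on_review +
                 fc$n_suspicious_vus + fc$n_discordant_lpp +
                 fc$n_unsolved)
  # no LP/P carrier is unsolved; no variant-free proband is solved
  unsolved <- adj[startsWith(adj$category, "unsolved_"), ]
  expect_false(any(unsolved$best_classification %in%
                     c("likely_pathogenic", "pathogenic")))
  solved <- adj[startsWith(adj$category, "solved_"), ]
  expect_false(anyNA(solved$best_classification))
})
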