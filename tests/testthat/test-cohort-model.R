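# Table readers/writers, schema validation, registry, VCF ingestion.

unclass_df <- function(d) { class(d) <- "data.frame"; d }

test_that("proband table round-trips through TSV with missing values", {
  d <- make_probands(3)
  d$age_at_diagnosis[2] <- NA
  d$final_diagnosis[3] <- "DCM"
  d$year_genetic_diagnosis[1] <- 2015
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(d, path)
  d2 <- read_proband_table(path)
  expect_equal(as.data.frame(d2), as.data.frame(d))
  # "." encodes the missing value on disk
  expect_true(any(grepl("\t\\.\t", readLines(path)[3])))
})

test_that("variant table round-trips and criteria re-render canonically", {
  v <- make_variants(c("T001", "T002"),
                     criteria = c("PM2;PP3;PS4_moderate", "PVS1;PM2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(v, path)
  v2 <- read_variant_table(path)
  expect_equal(as.data.frame(v2), as.data.frame(v))
  for (s in v2$criteria) {
    expect_identical(paste(format_criteria(parse_criteria_field(s)),
                           collapse = ";"), s)
  }
})

test_that("schema violations raise row-level errors naming the problem", {
  d <- make_probands(3)
  path <- withr::local_tempfile(fileext = ".tsv")

  bad <- d; bad$age_at_diagnosis[2] <- -4
  write_cohort_table(unclass_df(bad), path)
  expect_error(read_proband_table(path), "row 2.*age_at_diagnosis")

  bad <- d; bad$clinical_diagnosis[1] <- "HCMX"
  write_cohort_table(unclass_df(bad), path)
  expect_error(read_proband_table(path), "clinical_diagnosis.*row 1")

  # certainty must agree with the diagnosis form
  bad <- d; bad$diagnosis_certainty[3] <- "uncertain"
  write_cohort_table(unclass_df(bad), path)
  expect_error(read_proband_table(path), "row 3")

  write_cohort_table(d[, setdiff(names(d), "ancestry")], path)
  expect_error(read_proband_table(path), "ancestry")

  v <- make_variants("T001", criteria = "PX9")
  write_cohort_table(v, path)
  expect_error(read_variant_table(path), "row 1.*PX9")
})

test_that("gene registry loads from JSON and YAML with validation", {
  reg <- default_gene_registry()
  expect_s3_class(reg, "gene_registry")
  expect_equal(gene_tier(reg, "MYBPC3"), "tier1")
  expect_equal(gene_tier(reg, "FHOD3"), "tier2")
  expect_equal(max_credible_af(reg, "HCM"), 4e-5)
  expect_equal(max_credible_af(reg, "possible_HCM"), 4e-5)
  expect_equal(max_credible_af(reg, "CPVT"), 1e-5)
  expect_error(max_credible_af(reg, "nonsense"), "unknown disease")
  expect_error(gene_tier(reg, "NOTAGENE"), "NOTAGENE")

  # same document via YAML
  ypath <- withr::local_tempfile(fileext = ".yaml")
  doc <- jsonlite::read_json(cy_example("gene_registry.json"))
  yaml::write_yaml(doc, ypath)
  reg2 <- load_gene_registry(ypath)
  expect_equal(gene_diseases(reg2, "SCN5A", "definitive"),
               gene_diseases(reg, "SCN5A", "definitive"))

  # tier1 without a definitive association is rejected
  expect_error(gene_registry(list(genes = list(
    FHOD3 = list(tier = "tier1",
                 associations = list(list(disease = "HCM",
                                          validity = "moderate")))))),
    "definitive")
  # tier2 with no associations at all is rejected too
  expect_error(gene_registry(list(genes = list(
    FHOD3 = list(tier = "tier2")))), "no disease associations")
  expect_error(load_gene_registry("no/such/file.json"), "not found")
})

write_toy_vcf <- function(path, records,
                          samples = "P1",
                          info_lines = c(
  '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
  '##INFO=<ID=CSQT,Number=1,Type=String,Description="c">',
  '##INFO=<ID=POPMAX_AF,Number=1,Type=Float,Description="af">',
  '##INFO=<ID=ACMG,Number=.,Type=String,Description="crit">')) {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1,length=1000000>", info_lines,
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  writeLines(c(header, records), path)
}

test_that("VCF ingestion maps INFO keys and genotypes to observations", {
  skip_if_not_installed("VariantAnnotation")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, c(
    "1\t100\t.\tA\tG\t.\tPASS\tGENE=MYBPC3;CSQT=missense;POPMAX_AF=1e-05;ACMG=PM2,PP3\tGT\t0/1",
    "1\t200\t.\tC\tT\t.\tPASS\tGENE=MYH7;CSQT=frameshift;ACMG=PVS1,PM2\tGT\t1/1"))
  obs <- ingest_vcf(path)
  expect_equal(nrow(obs), 2)
  expect_equal(obs$proband_id, c("P1", "P1"))
  expect_equal(obs$gene, c("MYBPC3", "MYH7"))
  expect_equal(obs$popmax_af, c(1e-5, 0))
  # missing AF key is assumed absent from the reference database
  expect_equal(obs$af_assumed_absent, c(FALSE, TRUE))
  expect_equal(obs$criteria, c("PM2;PP3", "PVS1;PM2"))
  expect_equal(attr(obs, "n_skipped"), 0L)

  # multi-sample: the record goes to carriers of the alternate allele
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path2, paste0(
    "1\t100\t.\tA\tG\t.\tPASS\t",
    "GENE=MYBPC3;CSQT=missense;POPMAX_AF=0;ACMG=PM2\tGT\t0/1\t0/0"),
    samples = c("P1", "P2"))
  obs2 <- ingest_vcf(path2)
  expect_equal(obs2$proband_id, "P1")
})

test_that("VCF ingestion skips key-less records and rejects malformed files", {
  skip_if_not_installed("VariantAnnotation")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, c(
    "1\t100\t.\tA\tG\t.\tPASS\tCSQT=missense;POPMAX_AF=0;ACMG=PM2\tGT\t0/1",
    "1\t200\t.\tC\tT\t.\tPASS\tGENE=MYH7;CSQT=missense;ACMG=PM2\tGT\t0/1"))
  expect_warning(obs <- ingest_vcf(path), "skipped")
  expect_equal(nrow(obs), 1)
  expect_equal(attr(obs, "n_skipped"), 1L)

  garbled <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "at all"), garbled)
  expect_error(ingest_vcf(garbled), "malformed VCF")
})
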