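#' Proband and variant tables
#'
#' Cohort data travel as UTF-8 TSV files with a header row; "." denotes a
#' missing value. One row per proband (phenotype, family history, ancestry,
#' testing provenance) and one row per reported variant observation (gene,
#' consequence, popmax allele frequency, applied ACMG/AMP criterion codes).
#' Probands and variants are linked by `proband_id`; a proband may carry
#' zero or more variants.
#'
#' @name cohort_io
NULL

CY_PROBAND_REQUIRED <- c(
  "proband_id", "clinical_diagnosis", "diagnosis_certainty",
  "age_at_diagnosis", "n_affected_relatives", "ancestry",
  "year_first_seen", "year_genetic_diagnosis", "testing_provenance"
)
CY_SEVERE_LOGICAL <- c(
  "scd_or_resuscitated_arrest", "sustained_vt", "appropriate_icd_shock",
  "cardiac_transplant", "lvad"
)
CY_SEVERE_NUMERIC <- c("ejection_fraction_pct", "max_lvh_mm", "qtc_ms")
CY_PROBAND_OPTIONAL <- c(
  CY_SEVERE_LOGICAL, CY_SEVERE_NUMERIC,
  "expanded_testing", "final_diagnosis", "exclusion_reason"
)

CY_VARIANT_REQUIRED <- c(
  "proband_id", "gene", "variant_label", "consequence", "popmax_af",
  "criteria"
)
CY_VARIANT_OPTIONAL <- c("asserted_classification", "af_assumed_absent")

read_tsv_dots <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", na.strings = NULL,
                    check.names = FALSE, quote = "", comment.char = "",
                    fileEncoding = "UTF-8")
}

dot_na <- function(x) { x[x == "."] <- NA_character_; x }

parse_num <- function(x, col, rows) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad)) {
    stop("column '", col, "' row ", rows[bad[1]], ": unparseable number '",
         x[bad[1]], "'")
  }
  v
}

parse_flag <- function(x, col, rows) {
  x2 <- toupper(x)
  v <- rep(NA, length(x))
  v[x2 %in% c("TRUE", "T", "1", "YES")] <- TRUE
  v[x2 %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad)) {
    stop("column '", col, "' row ", rows[bad[1]], ": unparseable flag '",
         x[bad[1]], "'")
  }
  v
}

check_enum <- function(x, levels, col, rows) {
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad)) {
    stop("column '", col, "' row ", rows[bad[1]], ": invalid value '",
         x[bad[1]], "'")
  }
  x
}

#' Read a proband table
#'
#' Required columns: `proband_id`, `clinical_diagnosis`,
#' `diagnosis_certainty`, `age_at_diagnosis`, `n_affected_relatives`,
#' `ancestry`, `year_first_seen`, `year_genetic_diagnosis`,
#' `testing_provenance`. Optional columns: the severe-phenotype flags and
#' measurements, `expanded_testing` (tier-2 gene-list analysis performed),
#' `final_diagnosis` (curated post-review diagnosis) and
#' `exclusion_reason`. Unknown enum values and invariant violations raise
#' row-numbered errors.
#'
#' @param path TSV file path.
#' @return A `proband_table` data.frame, one row per proband.
#' @export
read_proband_table <- function(path) {
  raw <- read_tsv_dots(path)
  missing_cols <- setdiff(CY_PROBAND_REQUIRED, names(raw))
  if (length(missing_cols)) {
    stop("proband table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rows <- seq_len(nrow(raw))
  d <- data.frame(proband_id = dot_na(raw$proband_id),
                  stringsAsFactors = FALSE)
  d$clinical_diagnosis <- check_enum(dot_na(raw$clinical_diagnosis),
                                     cy_diagnosis_levels(),
                                     "clinical_diagnosis", rows)
  d$diagnosis_certainty <- check_enum(dot_na(raw$diagnosis_certainty),
                                      c("definite", "uncertain"),
                                      "diagnosis_certainty", rows)
  d$age_at_diagnosis <- parse_num(dot_na(raw$age_at_diagnosis),
                                  "age_at_diagnosis", rows)
  d$n_affected_relatives <- parse_num(dot_na(raw$n_affected_relatives),
                                      "n_affected_relatives", rows)
  d$ancestry <- check_enum(dot_na(raw$ancestry), CY_ANCESTRIES,
                           "ancestry", rows)
  d$year_first_seen <- parse_num(dot_na(raw$year_first_seen),
                                 "year_first_seen", rows)
  d$year_genetic_diagnosis <- parse_num(dot_na(raw$year_genetic_diagnosis),
                                        "year_genetic_diagnosis", rows)
  d$testing_provenance <- check_enum(dot_na(raw$testing_provenance),
                                     CY_PROVENANCE, "testing_provenance",
                                     rows)
  for (col in CY_SEVERE_LOGICAL) {
    d[[col]] <- if (col %in% names(raw)) {
      parse_flag(dot_na(raw[[col]]), col, rows)
    } else NA
  }
  for (col in CY_SEVERE_NUMERIC) {
    d[[col]] <- if (col %in% names(raw)) {
      parse_num(dot_na(raw[[col]]), col, rows)
    } else NA_real_
  }
  d$expanded_testing <- if ("expanded_testing" %in% names(raw)) {
    parse_flag(dot_na(raw$expanded_testing), "expanded_testing", rows)
  } else NA
  d$final_diagnosis <- if ("final_diagnosis" %in% names(raw)) {
    check_enum(dot_na(raw$final_diagnosis), cy_diagnosis_levels(),
               "final_diagnosis", rows)
  } else NA_character_
  d$exclusion_reason <- if ("exclusion_reason" %in% names(raw)) {
    dot_na(raw$exclusion_reason)
  } else NA_character_
  validate_probands(d)
}

CY_PROBAND_COLUMNS <- c(
  "proband_id", "clinical_diagnosis", "diagnosis_certainty",
  "age_at_diagnosis", "n_affected_relatives",
  CY_SEVERE_LOGICAL, CY_SEVERE_NUMERIC,
  "ancestry", "year_first_seen", "year_genetic_diagnosis",
  "testing_provenance", "expanded_testing", "final_diagnosis",
  "exclusion_reason")

#' Validate a proband data.frame against the schema invariants
#'
#' Also normalises the column order, so any valid table round-trips
#' identically through [write_cohort_table()] / [read_proband_table()].
#'
#' @param d A data.frame with proband columns.
#' @return The validated `proband_table`.
#' @export
validate_probands <- function(d) {
  d <- d[, c(intersect(CY_PROBAND_COLUMNS, names(d)),
             setdiff(names(d), CY_PROBAND_COLUMNS)), drop = FALSE]
  rows <- seq_len(nrow(d))
  if (anyNA(d$proband_id) || anyDuplicated(d$proband_id)) {
    stop("proband_id must be present and unique")
  }
  bad <- which(!is.na(d$age_at_diagnosis) & d$age_at_diagnosis < 0)
  if (length(bad)) {
    stop("row ", bad[1], ": age_at_diagnosis must be >= 0")
  }
  bad <- which(!is.na(d$n_affected_relatives) &
               (d$n_affected_relatives < 0 |
                d$n_affected_relatives != floor(d$n_affected_relatives)))
  if (length(bad)) {
    stop("row ", bad[1], ": n_affected_relatives must be a non-negative count")
  }
  both <- !is.na(d$year_first_seen) & !is.na(d$year_genetic_diagnosis)
  bad <- which(both & d$year_genetic_diagnosis < d$year_first_seen)
  if (length(bad)) {
    stop("row ", bad[1], ": year_genetic_diagnosis before year_first_seen")
  }
  # certainty = uncertain iff the diagnosis itself is an uncertain form
  unc_dx <- cy_is_uncertain_dx(d$clinical_diagnosis)
  bad <- which(!is.na(d$diagnosis_certainty) &
               (d$diagnosis_certainty == "uncertain") != unc_dx)
  if (length(bad)) {
    stop("row ", bad[1], ": diagnosis_certainty inconsistent with '",
         d$clinical_diagnosis[bad[1]], "'")
  }
  bad <- which(!is.na(d$ejection_fraction_pct) &
               (d$ejection_fraction_pct < 0 | d$ejection_fraction_pct > 100))
  if (length(bad)) {
    stop("row ", bad[1], ": ejection_fraction_pct must be in [0,100]")
  }
  for (col in c("max_lvh_mm", "qtc_ms")) {
    bad <- which(!is.na(d[[col]]) & d[[col]] < 0)
    if (length(bad)) stop("row ", bad[1], ": ", col, " must be >= 0")
  }
  class(d) <- c("proband_table", "data.frame")
  d
}

#' Read a variant observation table
#'
#' The `criteria` column is a semicolon-separated list of criterion tokens
#' (e.g. `"PM2;PP3;PS4_moderate"`); tokens are parsed into evidence criteria
#' at their effective strengths. A missing popmax allele frequency (".") is
#' coded 0 — absent from the reference database — and flagged in
#' `af_assumed_absent`.
#'
#' @param path TSV file path.
#' @return A `variant_table` data.frame.
#' @export
read_variant_table <- function(path) {
  raw <- read_tsv_dots(path)
  missing_cols <- setdiff(CY_VARIANT_REQUIRED, names(raw))
  if (length(missing_cols)) {
    stop("variant table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rows <- seq_len(nrow(raw))
  d <- data.frame(proband_id = dot_na(raw$proband_id),
                  gene = dot_na(raw$gene),
                  variant_label = dot_na(raw$variant_label),
                  stringsAsFactors = FALSE)
  d$consequence <- check_enum(dot_na(raw$consequence), CY_CONSEQUENCES,
                              "consequence", rows)
  af_raw <- dot_na(raw$popmax_af)
  d$popmax_af <- parse_num(af_raw, "popmax_af", rows)
  # "." means no popmax entry: absent from the reference database, coded 0.
  # A written table may carry the provenance flag explicitly.
  d$af_assumed_absent <- if ("af_assumed_absent" %in% names(raw)) {
    parse_flag(dot_na(raw$af_assumed_absent), "af_assumed_absent", rows)
  } else {
    is.na(d$popmax_af)
  }
  d$popmax_af[is.na(d$popmax_af)] <- 0
  if (any(d$popmax_af < 0 | d$popmax_af > 1)) {
    stop("popmax_af must be in [0,1]")
  }
  d$criteria <- dot_na(raw$criteria)
  d$criteria[is.na(d$criteria)] <- ""
  for (i in rows) {
    tryCatch(parse_criteria_field(d$criteria[i]),
             error = function(e) {
               stop("variant table row ", i, ": ", conditionMessage(e),
                    call. = FALSE)
             })
  }
  d$asserted_classification <- if ("asserted_classification" %in% names(raw)) {
    check_enum(dot_na(raw$asserted_classification), CY_CLASSIFICATIONS,
               "asserted_classification", rows)
  } else NA_character_
  class(d) <- c("variant_table", "data.frame")
  d
}

fmt_dots <- function(x) {
  out <- as.character(x)
  out[is.na(x)] <- "."
  if (is.logical(x)) out[!is.na(x)] <- ifelse(x[!is.na(x)], "TRUE", "FALSE")
  out
}

#' Write a proband or variant table as TSV (missing values as ".")
#'
#' @param d A data.frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_table <- function(d, path) {
  out <- as.data.frame(lapply(d, fmt_dots), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(d)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
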