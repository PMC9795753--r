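#' The monogenic disease score
#'
#' An additive points score ranking each proband's likelihood of a
#' monogenic (single-gene) aetiology, computed from three features of the
#' family unit: positive family history (2 points), severe phenotype
#' (1 point), and young age at diagnosis (< 30 years: 1 point; < 10 years:
#' 2 points, bands taken as a maximum, not summed). Totals range 0-5 and
#' are bucketed 0/1/2/3/>=4 for reporting. Genetically unsolved probands
#' scoring >= 1 are called "likely monogenic", those scoring 0 "likely
#' complex".
#'
#' @name monogenic_score
NULL

CY_BUCKETS <- c("s0", "s1", "s2", "s3", "s4plus")

#' Severe-phenotype determination
#'
#' True if any event flag is set (SCD/resuscitated arrest, sustained VT,
#' appropriate ICD shock, transplant, LVAD) or a measurement crosses its
#' configured extreme: ejection fraction < 30\%, maximal LVH >= 30 mm,
#' QTc >= 500 ms. Missing flags and measurements contribute FALSE.
#'
#' @param flags One proband row (or any list) with the severe-feature
#'   fields.
#' @param config A [cy_config()].
#' @return Logical.
#' @export
severe_phenotype <- function(flags, config = cy_config()) {
  event <- vapply(CY_SEVERE_LOGICAL,
                  function(f) isTRUE(flags[[f]]), logical(1))
  ef <- flags[["ejection_fraction_pct"]]
  lvh <- flags[["max_lvh_mm"]]
  qtc <- flags[["qtc_ms"]]
  any(event) ||
    (!is.null(ef) && !is.na(ef) && ef < config$ef_severe_below) ||
    (!is.null(lvh) && !is.na(lvh) && lvh >= config$lvh_severe_at_least) ||
    (!is.null(qtc) && !is.na(qtc) && qtc >= config$qtc_severe_at_least)
}

#' Age-at-diagnosis points
#'
#' 2 points below the very-young cutoff (default < 10 y), else 1 point
#' below the young cutoff (default < 30 y), else 0. Bands are strict by
#' default (`age_strict`); missing age scores 0 and is flagged by
#' [compute_score()].
#'
#' @param age_at_diagnosis Age in years, possibly NA.
#' @param config A [cy_config()].
#' @return 0, 1 or 2.
#' @export
age_points <- function(age_at_diagnosis, config = cy_config()) {
  if (is.na(age_at_diagnosis)) return(0L)
  if (age_at_diagnosis < 0) stop("age_at_diagnosis must be >= 0")
  lt <- if (isTRUE(config$age_strict)) `<` else `<=`
  if (lt(age_at_diagnosis, config$age_cutoff_very_young)) return(2L)
  if (lt(age_at_diagnosis, config$age_cutoff_young)) return(1L)
  0L
}

#' Family-history points
#'
#' Familial disease means the family unit holds more than one affected
#' member; with the default `fh_min_relatives = 1` a single affected
#' relative beyond the proband scores the full 2 points (set 2 to require
#' two additional relatives).
#'
#' @param n_affected_relatives Count of affected relatives beyond the
#'   proband; NA treated as unassessed (0 points).
#' @param config A [cy_config()].
#' @return 0 or 2 (the configured `fh_points`).
#' @export
family_history_points <- function(n_affected_relatives,
                                  config = cy_config()) {
  if (is.na(n_affected_relatives)) return(0L)
  if (n_affected_relatives >= config$fh_min_relatives) {
    as.integer(config$fh_points)
  } else 0L
}

#' Compute the score breakdown for one proband
#'
#' @param proband One row of a `proband_table`.
#' @param config A [cy_config()].
#' @return List with `family_history_points`, `severe_points`,
#'   `age_points`, `total`, `bucket`, and `flags` noting missing inputs
#'   scored as 0.
#' @export
compute_score <- function(proband, config = cy_config()) {
  fh <- family_history_points(proband$n_affected_relatives, config)
  sv <- if (severe_phenotype(proband, config)) {
    as.integer(config$severe_points)
  } else 0L
  ag <- age_points(proband$age_at_diagnosis, config)
  total <- fh + sv + ag
  flags <- character()
  if (is.na(proband$n_affected_relatives)) flags <- c(flags, "fh_unassessed")
  if (is.na(proband$age_at_diagnosis)) flags <- c(flags, "age_missing")
  list(family_history_points = fh, severe_points = sv, age_points = ag,
       total = total, bucket = CY_BUCKETS[min(total, 4L) + 1L],
       flags = flags)
}

#' Score every proband in a cohort
#'
#' @param probands A `proband_table`.
#' @param config A [cy_config()].
#' @return The table with `fh_points`, `severe_points`, `age_pts`,
#'   `score_total`, `score_bucket` and `score_flags` columns appended.
#' @export
score_cohort <- function(probands, config = cy_config()) {
  n <- nrow(probands)
  fh <- integer(n); sv <- integer(n); ag <- integer(n); fl <- character(n)
  fields <- c("n_affected_relatives", "age_at_diagnosis",
              CY_SEVERE_LOGICAL, CY_SEVERE_NUMERIC)
  for (i in seq_len(n)) {
    row <- lapply(probands[fields], `[`, i)
    s <- compute_score(row, config)
    fh[i] <- s$family_history_points
    sv[i] <- s$severe_points
    ag[i] <- s$age_points
    fl[i] <- paste(s$flags, collapse = ";")
  }
  probands$fh_points <- fh
  probands$severe_points <- sv
  probands$age_pts <- ag
  probands$score_total <- fh + sv + ag
  probands$score_bucket <- CY_BUCKETS[pmin(probands$score_total, 4L) + 1L]
  probands$score_flags <- fl
  probands
}

#' Likely-monogenic vs likely-complex dichotomy for unsolved probands
#'
#' @param score_total Monogenic disease score total.
#' @param solved Logical; calling this on a solved proband is a contract
#'   violation and errors.
#' @return `"likely_monogenic"` (score >= 1) or `"likely_complex"`
#'   (score 0).
#' @export
likelihood_class <- function(score_total, solved) {
  if (isTRUE(solved)) {
    stop("likelihood_class applies to unsolved probands only")
  }
  if (score_total >= 1) "likely_monogenic" else "likely_complex"
}
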