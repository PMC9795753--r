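#' Controlled vocabularies
#'
#' Enumerations used throughout the package: clinical diagnoses (including
#' their "possible_" borderline forms), ancestry groups, variant
#' consequences, classification tiers and evidence-strength labels.
#'
#' @name vocab
#' @keywords internal
NULL

# Base (definite) clinical diagnoses. "possible_<dx>" forms are accepted for
# any of these; "undiagnosed" and "unexplained_SCA" are intrinsically
# uncertain and have no possible_ form.
CY_BASE_DIAGNOSES <- c(
  "HCM", "DCM", "LVNC", "ACM", "BrS", "LQTS", "CPVT", "RCM",
  "NoonanLVH", "SSS"
)
CY_UNCERTAIN_ONLY <- c("undiagnosed", "unexplained_SCA")

CY_ANCESTRIES <- c(
  "European", "EastAsian", "SouthCentralAsian",
  "MiddleEasternNorthAfrican", "Other", "Unknown"
)

CY_CONSEQUENCES <- c(
  "missense", "nonsense", "frameshift", "canonical_splice",
  "splice_region_predicted", "deep_intronic_splice_predicted",
  "synonymous", "synonymous_splice_predicted", "inframe_indel", "structural"
)

CY_PROVENANCE <- c("clinical", "research_tier2", "none")

CY_CLASSIFICATIONS <- c(
  "benign", "likely_benign", "VUS", "likely_pathogenic", "pathogenic"
)

CY_STRENGTHS <- c(
  "supporting", "moderate", "strong", "very_strong", "stand_alone"
)

CY_VALIDITY <- c("definitive", "moderate", "limited")

#' All diagnosis labels accepted by the proband schema
#' @return Character vector of valid `clinical_diagnosis` values.
#' @export
cy_diagnosis_levels <- function() {
  c(CY_BASE_DIAGNOSES, CY_UNCERTAIN_ONLY,
    paste0("possible_", CY_BASE_DIAGNOSES))
}

# Strip a possible_ prefix; undiagnosed/unexplained_SCA pass through.
cy_base_diagnosis <- function(dx) {
  sub("^possible_", "", dx)
}

cy_is_uncertain_dx <- function(dx) {
  dx %in% CY_UNCERTAIN_ONLY | startsWith(dx, "possible_")
}

# Diagnoses where the genetic result supplies the diagnosis outright.
cy_is_undifferentiated_dx <- function(dx) {
  dx %in% CY_UNCERTAIN_ONLY
}

classification_rank <- function(x) {
  match(x, CY_CLASSIFICATIONS)
}

is_lpp <- function(x) {
  x %in% c("likely_pathogenic", "pathogenic")
}

#' Default analysis configuration
#'
#' Tunable thresholds for the monogenic disease score, suspicious-VUS triage
#' and reporting, with the clinic's published defaults:
#' \itemize{
#'   \item age bands: onset < 30 y scores 1 point, < 10 y scores 2 points
#'     (strict inequalities);
#'   \item family history: >= 1 affected relative beyond the proband scores
#'     2 points (`fh_min_relatives = 1`; set 2 to require two relatives);
#'   \item severe phenotype: any ventricular-arrhythmia or heart-failure
#'     event flag, or EF < 30\%, max LVH >= 30 mm, QTc >= 500 ms;
#'   \item rarity: default maximum credible popmax allele frequency 4e-5 for
#'     HCM and 1e-5 for all less prevalent diseases (registry can override);
#'   \item percentages rounded half-away-from-zero to integers.
#' }
#'
#' @param ... Named overrides of any default listed above.
#' @return A list of configuration values (class `cy_config`).
#' @examples
#' cfg <- cy_config(fh_min_relatives = 2)
#' cfg$age_cutoff_young
#' @export
cy_config <- function(...) {
  cfg <- list(
    age_cutoff_young = 30,
    age_cutoff_very_young = 10,
    age_strict = TRUE,           # strict "<" comparisons on the age bands
    fh_min_relatives = 1,
    fh_points = 2,
    severe_points = 1,
    ef_severe_below = 30,
    lvh_severe_at_least = 30,
    qtc_severe_at_least = 500,
    default_max_af = 1e-5,       # diseases without a registry threshold
    hcm_max_af = 4e-5,
    require_nonfreq_criterion = FALSE,  # suspicious VUS: demand evidence beyond PM2
    rounding = "half_away"       # or "half_even"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "cy_config")
}

# Percentage rounding used in every report table.
round_pct <- function(x, rounding = "half_away") {
  if (identical(rounding, "half_even")) return(round(x))
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
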