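#' Headline cohort metrics
#'
#' Convenience summary of the quantities a clinic audit reports: overall
#' LP/P and suspicious-VUS yields, the likely-monogenic share of unsolved
#' probands, stratified LP/P yields (score buckets, feature combinations,
#' uncertain diagnoses, ancestry groups), the incremental yield of tier-2
#' gene-list analysis, and the share of variant-positive probands whose
#' diagnosis the genetic result changed or clarified. All percentages are
#' integer-rounded under the configured rounding rule.
#'
#' @param adjudicated Output of [adjudicate_cohort()] /
#'   [run_cohort_pipeline()].
#' @param config A [cy_config()].
#' @return Named list of percentages (plus the denominator `n_*` counts).
#' @export
cohort_headline_metrics <- function(adjudicated, config = cy_config()) {
  a <- adjudicated[!startsWith(adjudicated$category, "excluded_"), ]
  rp <- function(num, den) {
    if (den == 0) NA_real_ else round_pct(100 * num / den, config$rounding)
  }
  fc <- flow_counts(adjudicated)
  ys <- yield_by_score(adjudicated, config)
  yf <- yield_by_feature_combination(adjudicated, config)
  ya <- yield_by_ancestry(adjudicated, config)$table
  cell <- function(tab, stratum, col, certainty = NULL) {
    r <- if (is.null(certainty)) tab[tab$stratum == stratum, ]
         else tab[tab$stratum == stratum & tab$certainty == certainty, ]
    if (nrow(r) != 1) NA_real_ else r[[col]]
  }

  tier2_den <- sum(a$expanded_testing %in% TRUE &
                     !a$category %in% c("solved_baseline",
                                        "suspicious_vus"))
  tier2_num <- sum(a$expanded_testing %in% TRUE &
                     a$category == "solved_on_review")
  carriers <- fc$n_genetic_cause
  changed <- sum(a$diagnosis_change %in% c("changed", "clarified"))

  list(
    n_included = fc$n_included,
    pct_lpp = rp(fc$n_lpp, fc$n_included),
    pct_suspicious_vus = rp(fc$n_suspicious_vus, fc$n_included),
    pct_unsolved_likely_monogenic = rp(fc$n_unsolved_likely_monogenic,
                                       fc$n_unsolved),
    pct_lpp_score0 = cell(ys, "s0", "pct_LPP", "total"),
    pct_lpp_score4plus = cell(ys, "s4plus", "pct_LPP", "total"),
    pct_lpp_fh_severe = cell(yf, "fh_severe", "pct_LPP"),
    pct_lpp_fh_young = cell(yf, "fh_young", "pct_LPP"),
    pct_lpp_uncertain_dx = cell(ys, "all", "pct_LPP", "uncertain"),
    n_tier2_analysed = tier2_den,
    pct_tier2_incremental = rp(tier2_num, tier2_den),
    pct_diagnosis_changed_or_clarified = rp(changed, carriers),
    pct_svus_european = cell(ya, "European", "pct_suspicious_VUS"),
    pct_lpp_mena = cell(ya, "MiddleEasternNorthAfrican", "pct_LPP")
  )
}
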