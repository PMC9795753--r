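#' Stratified diagnostic-yield tables and test statistics
#'
#' Yield tables report, per stratum, the number of probands, the number and
#' percentage with an LP/P best variant, and the number and percentage with
#' a suspicious VUS. Percentages are rounded to integers half-away-from-zero
#' by default; empty strata render percentages as NA (printed "—").
#'
#' @name cohort_stats
NULL

yield_row <- function(stratum, d, rounding) {
  n <- nrow(d)
  n_lpp <- sum(is_lpp(d$best_classification), na.rm = TRUE)
  n_svus <- sum(d$category == "suspicious_vus")
  stopifnot(n_lpp + n_svus <= n)
  data.frame(
    stratum = stratum, n = n, n_LPP = n_lpp, n_suspicious_VUS = n_svus,
    pct_LPP = if (n == 0) NA_real_ else round_pct(100 * n_lpp / n, rounding),
    pct_suspicious_VUS = if (n == 0) NA_real_
                         else round_pct(100 * n_svus / n, rounding),
    stringsAsFactors = FALSE)
}

included <- function(adjudicated) {
  adjudicated[!startsWith(adjudicated$category, "excluded_"), , drop = FALSE]
}

#' Yield by monogenic-score bucket, split by diagnosis certainty
#'
#' One row per score bucket (0, 1, 2, 3, >= 4) within each certainty
#' stratum (`definite`, `uncertain`, `total`), plus an `overall` row.
#'
#' @param adjudicated Output of [adjudicate_cohort()].
#' @param config A [cy_config()] (rounding rule).
#' @return A `yield_table` data.frame with a `certainty` column.
#' @export
yield_by_score <- function(adjudicated, config = cy_config()) {
  a <- included(adjudicated)
  groups <- list(definite = a[a$diagnosis_certainty == "definite", ],
                 uncertain = a[a$diagnosis_certainty == "uncertain", ],
                 total = a)
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    for (b in CY_BUCKETS) {
      r <- yield_row(b, d[d$score_bucket == b, , drop = FALSE],
                     config$rounding)
      r$certainty <- g
      rows[[length(rows) + 1L]] <- r
    }
    r <- yield_row("all", d, config$rounding)
    r$certainty <- g
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  # stratum counts must sum to the declared denominator
  tot <- out[out$certainty == "total" & out$stratum != "all", ]
  stopifnot(sum(tot$n) == nrow(a))
  class(out) <- c("yield_table", "data.frame")
  out
}

# Feature flags implied by the score components.
feature_combo <- function(adjudicated) {
  fh <- adjudicated$fh_points > 0
  sv <- adjudicated$severe_points > 0
  yo <- adjudicated$age_pts > 0
  ifelse(!fh & !sv & !yo, "none",
  ifelse(!fh & sv & !yo, "severe_only",
  ifelse(!fh & !sv & yo, "young_only",
  ifelse(!fh & sv & yo, "severe_young",
  ifelse(fh & !sv & !yo, "fh_only",
  ifelse(fh & !sv & yo, "fh_young",
  ifelse(fh & sv & !yo, "fh_severe", "fh_severe_young")))))))
}

CY_COMBOS <- c("severe_only", "young_only", "severe_young", "fh_only",
               "fh_young", "fh_severe", "fh_severe_young")

#' Yield over the seven non-empty combinations of the score features
#'
#' Strata are the combinations of positive family history, severe
#' phenotype and young onset (at least one feature present).
#'
#' @inheritParams yield_by_score
#' @return A `yield_table` data.frame.
#' @export
yield_by_feature_combination <- function(adjudicated,
                                         config = cy_config()) {
  a <- included(adjudicated)
  combo <- feature_combo(a)
  rows <- lapply(CY_COMBOS, function(cb) {
    yield_row(cb, a[combo == cb, , drop = FALSE], config$rounding)
  })
  out <- do.call(rbind, rows)
  stopifnot(sum(out$n) == sum(combo != "none"))
  class(out) <- c("yield_table", "data.frame")
  out
}

#' Yield by ancestry group, with suspicious-VUS comparisons vs Europeans
#'
#' Probands of unknown ancestry are excluded from the table (their count is
#' attached as the `n_unknown` attribute). For every non-European group a
#' 2x2 Pearson chi-squared test compares its suspicious-VUS proportion with
#' the European group.
#'
#' @inheritParams yield_by_score
#' @return List with `table` (a `yield_table`) and `tests` (one
#'   [chi_squared_2x2()] result per compared group).
#' @export
yield_by_ancestry <- function(adjudicated, config = cy_config()) {
  a <- included(adjudicated)
  known <- a[a$ancestry != "Unknown", , drop = FALSE]
  groups <- setdiff(CY_ANCESTRIES, "Unknown")
  rows <- list(); tests <- list()
  eur <- known[known$ancestry == "European", , drop = FALSE]
  for (g in groups) {
    d <- known[known$ancestry == g, , drop = FALSE]
    if (nrow(d) == 0) {
      warning("ancestry group with no probands skipped: ", g)
      next
    }
    rows[[length(rows) + 1L]] <- yield_row(g, d, config$rounding)
    if (g != "European" && nrow(eur) > 0) {
      sv_g <- sum(d$category == "suspicious_vus")
      sv_e <- sum(eur$category == "suspicious_vus")
      tests[[g]] <- tryCatch(
        chi_squared_2x2(sv_e, nrow(eur) - sv_e, sv_g, nrow(d) - sv_g),
        error = function(e) NULL)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    yield_row("European", known[0, , drop = FALSE], config$rounding)[0, ]
  class(out) <- c("yield_table", "data.frame")
  attr(out, "n_unknown") <- sum(a$ancestry == "Unknown")
  list(table = out, tests = tests)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Continuity correction is off by default, matching a plain Pearson
#' statistic; p-value from the chi-squared survival function with 1 df.
#'
#' @param a,b,c,d Cell counts, rows = groups, columns = outcome.
#' @param continuity_correction Apply Yates' correction.
#' @return List with `test`, `statistic`, `df`, `p_value`.
#' @export
chi_squared_2x2 <- function(a, b, c, d, continuity_correction = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("cell counts must be non-negative with a positive total")
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-squared undefined: zero marginal total")
  }
  h <- suppressWarnings(
    stats::chisq.test(m, correct = continuity_correction))
  list(test = "chi_squared", statistic = unname(h$statistic),
       df = unname(h$parameter), p_value = unname(h$p.value))
}

#' Two-sample t-test (Student's pooled-variance by default)
#'
#' @param xs,ys Numeric samples, each of length >= 2.
#' @param pooled Use the pooled-variance Student statistic (default);
#'   FALSE gives Welch.
#' @return List with `test`, `statistic`, `df`, `p_value`.
#' @export
t_test_two_sample <- function(xs, ys, pooled = TRUE) {
  if (length(xs) < 2 || length(ys) < 2) {
    stop("each sample needs n >= 2")
  }
  h <- stats::t.test(xs, ys, var.equal = pooled)
  list(test = "t_test", statistic = unname(h$statistic),
       df = unname(h$parameter), p_value = unname(h$p.value))
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance Student's t computed from (n, mean, sd) summaries;
#' reproduces [t_test_two_sample()] exactly when fed a sample's own
#' summaries. Provided because published group summaries often arrive
#' without raw data.
#'
#' @param n1,mean1,sd1 First group summaries.
#' @param n2,mean2,sd2 Second group summaries.
#' @return List with `test`, `statistic`, `df`, `p_value`.
#' @export
t_test_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(test = "t_test", statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Write the report artefacts for an adjudicated cohort
#'
#' Emits deterministic TSV and JSON files with fixed column order:
#' `yield_by_score.tsv`, `yield_by_feature.tsv`, `yield_by_ancestry.tsv`,
#' `flow_counts.json`, `tests.json` and `report_meta.json` (rounding rule
#' and declared denominators). Empty-stratum percentages are written "—".
#'
#' @param adjudicated Output of [adjudicate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param config A [cy_config()].
#' @return Invisibly, the list of written paths.
#' @export
render_report <- function(adjudicated, out_dir, config = cy_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_yield <- function(tab, path) {
    out <- tab[, c("certainty"[("certainty" %in% names(tab))], "stratum",
                   "n", "n_LPP", "n_suspicious_VUS", "pct_LPP",
                   "pct_suspicious_VUS")]
    for (col in c("pct_LPP", "pct_suspicious_VUS")) {
      out[[col]] <- ifelse(is.na(out[[col]]), "—",
                           as.character(out[[col]]))
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    path
  }
  ys <- yield_by_score(adjudicated, config)
  yf <- yield_by_feature_combination(adjudicated, config)
  ya <- yield_by_ancestry(adjudicated, config)
  paths <- c(
    write_yield(ys, file.path(out_dir, "yield_by_score.tsv")),
    write_yield(yf, file.path(out_dir, "yield_by_feature.tsv")),
    write_yield(ya$table, file.path(out_dir, "yield_by_ancestry.tsv"))
  )
  fc_path <- file.path(out_dir, "flow_counts.json")
  jsonlite::write_json(flow_counts(adjudicated), fc_path,
                       auto_unbox = TRUE, pretty = TRUE)
  tests_path <- file.path(out_dir, "tests.json")
  jsonlite::write_json(
    list(suspicious_vus_vs_european = ya$tests,
         note = "nominal p-values; no multiple-testing correction"),
    tests_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  meta_path <- file.path(out_dir, "report_meta.json")
  jsonlite::write_json(
    list(rounding = config$rounding,
         n_included = nrow(included(adjudicated)),
         n_unknown_ancestry = attr(ya$table, "n_unknown")),
    meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, fc_path, tests_path, meta_path))
}
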