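#' Adjudication: the final per-proband flow category
#'
#' Every included proband lands in exactly one category:
#' `solved_baseline` (concordant LP/P from clinical-provenance testing),
#' `solved_on_review` (concordant LP/P requiring research effort),
#' `suspicious_vus` (best variant a suspicious VUS — not counted as
#' unsolved), `unsolved_likely_monogenic` / `unsolved_likely_complex`
#' (no causal-grade result, split by monogenic score >= 1 vs 0),
#' `discordant_LPP` (an LP/P the registry cannot reconcile with the
#' baseline or curated diagnosis — held for manual review, never silently
#' solved), or `excluded_<reason>`.
#'
#' @name adjudication
NULL

#' Select a proband's best variant
#'
#' Deterministic: highest classification wins; among equals the suspicious
#' flag breaks ties, then lexicographic gene symbol, then variant label.
#'
#' @param classified A `variant_table` slice with `classification` and
#'   `suspicious_vus` columns (0..n rows, one proband).
#' @return The winning row, or NULL when no variants were reported.
#' @export
select_best_variant <- function(classified) {
  if (is.null(classified) || nrow(classified) == 0) return(NULL)
  o <- order(-classification_rank(classified$classification),
             -as.integer(classified$suspicious_vus),
             classified$gene, classified$variant_label)
  classified[o[1], , drop = FALSE]
}

#' Concordance of a genetic finding with a clinical diagnosis
#'
#' TRUE iff the gene carries a definitive or moderate association with the
#' proband's diagnosis (`possible_X` matches `X`). For probands with no
#' differentiated phenotype (`undiagnosed`, `unexplained_SCA`) any
#' definitive cardiac association is concordant — the genetic result
#' supplies the diagnosis.
#'
#' @param diagnosis A diagnosis label.
#' @param gene Gene symbol (must be in the registry).
#' @param registry A `gene_registry`.
#' @return Logical.
#' @export
concordant <- function(diagnosis, gene, registry) {
  if (cy_is_undifferentiated_dx(diagnosis)) {
    return(length(gene_diseases(registry, gene, "definitive")) > 0)
  }
  validity <- gene_disease_validity(registry, gene,
                                    cy_base_diagnosis(diagnosis))
  !is.na(validity) && validity %in% c("definitive", "moderate")
}

# The disease a concordant finding implies: the curated final diagnosis if
# supplied, else the baseline base disease, else the gene's first
# definitive association (for undifferentiated phenotypes).
implied_disease <- function(proband, gene, registry) {
  if (!is.na(proband$final_diagnosis)) {
    return(cy_base_diagnosis(proband$final_diagnosis))
  }
  if (cy_is_undifferentiated_dx(proband$clinical_diagnosis)) {
    return(sort(gene_diseases(registry, gene, "definitive"))[1])
  }
  cy_base_diagnosis(proband$clinical_diagnosis)
}

#' Adjudicate one proband
#'
#' An LP/P best variant is tested for concordance against the curated
#' `final_diagnosis` when present, else the baseline diagnosis; concordant
#' LP/P resolves to solved (by testing provenance), discordant LP/P is
#' flagged `discordant_LPP`. `diagnosis_change` is `changed` when the
#' implied disease is a different entity from the baseline (including an
#' undifferentiated baseline now given a diagnosis), `clarified` when an
#' uncertain `possible_X` baseline is confirmed as `X`, else `none`.
#' Diagnosis change attaches only to LP/P results — a VUS cannot formally
#' change a diagnosis.
#'
#' @param proband One row of a scored `proband_table`.
#' @param best_variant Output of [select_best_variant()] (or NULL).
#' @param score_total The proband's monogenic score total.
#' @param registry A `gene_registry`.
#' @return List with `category`, `diagnosis_change`, `final_disease`.
#' @export
adjudicate <- function(proband, best_variant, score_total, registry) {
  if (!is.na(proband$exclusion_reason)) {
    return(list(category = paste0("excluded_", proband$exclusion_reason),
                diagnosis_change = "none", final_disease = NA_character_))
  }
  has_lpp <- !is.null(best_variant) && is_lpp(best_variant$classification)
  if (has_lpp) {
    target_dx <- if (!is.na(proband$final_diagnosis)) {
      proband$final_diagnosis
    } else {
      proband$clinical_diagnosis
    }
    if (!concordant(target_dx, best_variant$gene, registry)) {
      return(list(category = "discordant_LPP", diagnosis_change = "none",
                  final_disease = NA_character_))
    }
    category <- if (identical(proband$testing_provenance, "research_tier2")) {
      "solved_on_review"
    } else {
      "solved_baseline"
    }
    disease <- implied_disease(proband, best_variant$gene, registry)
    change <-
      if (cy_is_undifferentiated_dx(proband$clinical_diagnosis)) {
        "changed"
      } else if (!identical(cy_base_diagnosis(proband$clinical_diagnosis),
                            disease)) {
        "changed"
      } else if (startsWith(proband$clinical_diagnosis, "possible_")) {
        "clarified"
      } else {
        "none"
      }
    return(list(category = category, diagnosis_change = change,
                final_disease = disease))
  }
  if (!is.null(best_variant) && isTRUE(best_variant$suspicious_vus)) {
    return(list(category = "suspicious_vus", diagnosis_change = "none",
                final_disease = NA_character_))
  }
  list(category = paste0("unsolved_",
                         likelihood_class(score_total, solved = FALSE)),
       diagnosis_change = "none", final_disease = NA_character_)
}

#' Time to genetic diagnosis and presentation era
#'
#' @param proband One proband row with `year_first_seen` and
#'   `year_genetic_diagnosis`.
#' @return List with `years` (NA when either year is missing) and `era`
#'   (`"e2002_2010"` / `"e2011_2020"` by year first seen).
#' @export
time_to_diagnosis <- function(proband) {
  y0 <- proband$year_first_seen
  y1 <- proband$year_genetic_diagnosis
  era <- if (is.na(y0)) NA_character_
         else if (y0 <= 2010) "e2002_2010" else "e2011_2020"
  years <- if (is.na(y0) || is.na(y1)) NA_real_ else y1 - y0
  list(years = years, era = era)
}

#' Adjudicate a whole cohort
#'
#' Joins scored probands to their classified variants, selects each
#' proband's best variant, assigns the flow category and diagnosis-change
#' verdict, and asserts the partition invariants (each proband in exactly
#' one category; no concordant LP/P carrier unsolved; no variant-free
#' proband solved; every suspicious flag on a rarity-passing VUS).
#'
#' @param scored A `proband_table` after [score_cohort()].
#' @param classified A `variant_table` after [classify_cohort_variants()].
#' @param registry A `gene_registry`.
#' @return The proband table with `category`, `diagnosis_change`,
#'   `final_disease`, `best_classification`, `best_gene`,
#'   `best_suspicious`, `time_to_diagnosis_years` and `era` appended.
#' @export
adjudicate_cohort <- function(scored, classified, registry) {
  n <- nrow(scored)
  # best variant per proband, vectorized: sort by the tie-break order and
  # keep the first row per proband_id
  best_of <- list()
  if (nrow(classified)) {
    o <- order(classified$proband_id,
               -classification_rank(classified$classification),
               -as.integer(classified$suspicious_vus),
               classified$gene, classified$variant_label)
    first <- o[!duplicated(classified$proband_id[o])]
    best_of <- lapply(first, function(j)
      list(classification = classified$classification[j],
           suspicious_vus = classified$suspicious_vus[j],
           gene = classified$gene[j],
           variant_label = classified$variant_label[j]))
    names(best_of) <- classified$proband_id[first]
  }
  category <- character(n); change <- character(n); final <- character(n)
  bcls <- character(n); bgene <- character(n); bsusp <- logical(n)
  tdy <- numeric(n); era <- character(n)
  prow_fields <- c("clinical_diagnosis", "final_diagnosis",
                   "testing_provenance", "exclusion_reason",
                   "year_first_seen", "year_genetic_diagnosis")
  for (i in seq_len(n)) {
    pid <- scored$proband_id[i]
    best <- best_of[[pid]]
    prow <- lapply(scored[prow_fields], `[`, i)
    a <- adjudicate(prow, best, scored$score_total[i], registry)
    category[i] <- a$category
    change[i] <- a$diagnosis_change
    final[i] <- a$final_disease
    bcls[i] <- if (is.null(best)) NA_character_ else best$classification
    bgene[i] <- if (is.null(best)) NA_character_ else best$gene
    bsusp[i] <- if (is.null(best)) FALSE else isTRUE(best$suspicious_vus)
    t <- time_to_diagnosis(prow)
    tdy[i] <- t$years
    era[i] <- t$era
  }
  scored$category <- category
  scored$diagnosis_change <- change
  scored$final_disease <- final
  scored$best_classification <- bcls
  scored$best_gene <- bgene
  scored$best_suspicious <- bsusp
  scored$time_to_diagnosis_years <- tdy
  scored$era <- era

  # Partition invariants, asserted on every run.
  stopifnot(
    !anyNA(category),
    all(!is_lpp(bcls[startsWith(category, "unsolved_")]) |
          is.na(bcls[startsWith(category, "unsolved_")])),
    all(!is.na(bcls[startsWith(category, "solved_")])),
    all(category[bsusp & !startsWith(category, "solved_") &
                   !startsWith(category, "excluded_")] == "suspicious_vus" |
          is_lpp(bcls[bsusp & !startsWith(category, "solved_") &
                        !startsWith(category, "excluded_")]))
  )
  class(scored) <- c("adjudicated_cohort", class(scored))
  scored
}

#' Flow-diagram counts for an adjudicated cohort
#'
#' Mirrors the clinic flow: included probands, those with any genetic cause
#' (LP/P or suspicious VUS), LP/P and suspicious-VUS carriers, solved at
#' baseline (reported both as concordant clinical LP/P alone and rolled up
#' with suspicious-VUS carriers), solved on review, unsolved and its
#' likely-monogenic / likely-complex split, plus any discordant or excluded
#' counts.
#'
#' @param adjudicated Output of [adjudicate_cohort()].
#' @return Named list of integer counts.
#' @export
flow_counts <- function(adjudicated) {
  a <- adjudicated[!startsWith(adjudicated$category, "excluded_"), ]
  lpp <- sum(is_lpp(a$best_classification), na.rm = TRUE)
  svus <- sum(a$category == "suspicious_vus")
  counts <- list(
    n_included = nrow(a),
    n_lpp = lpp,
    n_suspicious_vus = svus,
    n_genetic_cause = lpp + svus,
    n_solved_baseline_lpp = sum(a$category == "solved_baseline"),
    n_solved_baseline_incl_svus =
      sum(a$category == "solved_baseline") + svus,
    n_solved_on_review = sum(a$category == "solved_on_review"),
    n_discordant_lpp = sum(a$category == "discordant_LPP"),
    n_unsolved = sum(startsWith(a$category, "unsolved_")),
    n_unsolved_likely_monogenic =
      sum(a$category == "unsolved_likely_monogenic"),
    n_unsolved_likely_complex =
      sum(a$category == "unsolved_likely_complex"),
    n_excluded = sum(startsWith(adjudicated$category, "excluded_"))
  )
  stopifnot(counts$n_unsolved_likely_monogenic +
              counts$n_unsolved_likely_complex == counts$n_unsolved)
  counts
}
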