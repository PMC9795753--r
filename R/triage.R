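#' Variant triage: classification and suspicious-VUS rules
#'
#' A reported variant is combined to a five-tier classification from its
#' evidence codes (or taken from an asserted classification when supplied
#' with provenance). Variants of uncertain significance are additionally
#' screened by the suspicious-VUS rules: rare below the disease-specific
#' maximum credible popmax frequency, in a gene with a definitive
#' disease association concordant with the proband's baseline phenotype,
#' predicted to alter the protein sequence, and carrying some (but
#' insufficient) pathogenic-direction evidence with no stand-alone or
#' default-strength strong benign evidence.
#'
#' @name variant_triage
NULL

#' Rarity filter against the disease-specific frequency threshold
#'
#' @param popmax_af Popmax allele fraction in [0,1]; 0 encodes absent.
#' @param disease Disease label (a `possible_` prefix is stripped).
#' @param registry A `gene_registry`.
#' @return TRUE iff `popmax_af` is strictly below the disease's maximum
#'   credible popmax allele frequency.
#' @examples
#' reg <- default_gene_registry()
#' meets_rarity(0, "HCM", reg)        # TRUE
#' meets_rarity(4e-5, "HCM", reg)     # FALSE: strict inequality
#' @export
meets_rarity <- function(popmax_af, disease, registry) {
  stopifnot(popmax_af >= 0, popmax_af <= 1)
  popmax_af < max_credible_af(registry, disease)
}

#' Does a consequence alter the protein sequence?
#'
#' Predicted-splice subtypes count as protein-altering (including
#' splice-affecting synonymous and deep-intronic variants); only plain
#' synonymous changes do not.
#'
#' @param consequence One of the consequence vocabulary values.
#' @return Logical.
#' @export
is_protein_altering <- function(consequence) {
  if (!consequence %in% CY_CONSEQUENCES) {
    stop("unknown consequence: ", consequence)
  }
  consequence != "synonymous"
}

#' Apply the suspicious-VUS rules to a classified observation
#'
#' @param classification A five-tier classification value.
#' @param observation One row of a `variant_table`.
#' @param baseline_diagnosis The proband's baseline clinical diagnosis;
#'   `possible_X` matches `X`.
#' @param registry A `gene_registry`.
#' @param config A [cy_config()]; `require_nonfreq_criterion = TRUE` demands
#'   at least one pathogenic criterion beyond population rarity (PM2).
#' @return List with `suspicious` (logical) and `reasons` (character vector
#'   of every rule consulted and its outcome).
#' @export
assess_suspicious_vus <- function(classification, observation,
                                  baseline_diagnosis, registry,
                                  config = cy_config()) {
  reasons <- character()
  note <- function(ok, what) {
    reasons <<- c(reasons, paste0(if (ok) "pass: " else "fail: ", what))
    ok
  }
  criteria <- parse_criteria_field(observation$criteria)

  ok <- note(identical(classification, "VUS"),
             paste0("classification is VUS (", classification, ")"))
  base_dx <- cy_base_diagnosis(baseline_diagnosis)
  if (cy_is_undifferentiated_dx(baseline_diagnosis)) {
    # no baseline phenotype to match against
    ok <- note(FALSE, paste0("baseline phenotype '", baseline_diagnosis,
                             "' has no disease to match")) && ok
  } else {
    validity <- gene_disease_validity(registry, observation$gene, base_dx)
    ok <- note(identical(validity, "definitive"),
               paste0("gene ", observation$gene,
                      " definitive for baseline disease ", base_dx,
                      " (validity: ", validity %||% "none", ")")) && ok
    rare <- meets_rarity(observation$popmax_af, base_dx, registry)
    ok <- note(rare, sprintf("popmax AF %.3g below %s threshold %.3g",
                             observation$popmax_af, base_dx,
                             max_credible_af(registry, base_dx))) && ok
  }
  ok <- note(is_protein_altering(observation$consequence),
             paste0("protein-altering consequence (",
                    observation$consequence, ")")) && ok

  path <- criteria[criteria$direction == "pathogenic", , drop = FALSE]
  if (isTRUE(config$require_nonfreq_criterion)) {
    path <- path[path$base_code != "PM2", , drop = FALSE]
  }
  ok <- note(nrow(path) >= 1, "some pathogenic-direction evidence") && ok

  ben <- criteria[criteria$direction == "benign", , drop = FALSE]
  blocking <- any(ben$strength %in% c("stand_alone", "strong", "very_strong"))
  ok <- note(!blocking, "no stand-alone/strong benign evidence") && ok

  list(suspicious = ok, reasons = reasons)
}

#' Classify one variant observation
#'
#' Combines the observation's criteria (or honours an asserted
#' classification, flagged in the reasons) and applies the suspicious-VUS
#' screen.
#'
#' @param observation One row of a `variant_table`.
#' @param baseline_diagnosis The proband's baseline clinical diagnosis.
#' @param registry A `gene_registry`.
#' @param config A [cy_config()].
#' @return List with `classification`, `suspicious_vus`, `triage_reasons`.
#' @export
classify_variant <- function(observation, baseline_diagnosis, registry,
                             config = cy_config()) {
  asserted <- observation$asserted_classification
  if (!is.null(asserted) && !is.na(asserted)) {
    classification <- asserted
    reasons <- "classification asserted upstream (provenance: input table)"
  } else {
    classification <- combine_criteria(
      parse_criteria_field(observation$criteria))
    reasons <- paste0("combined from criteria: ",
                      ifelse(nzchar(observation$criteria),
                             observation$criteria, "(none)"))
  }
  s <- assess_suspicious_vus(classification, observation,
                             baseline_diagnosis, registry, config)
  list(classification = classification,
       suspicious_vus = s$suspicious,
       triage_reasons = c(reasons, s$reasons))
}

#' Classify every variant in a cohort
#'
#' @param variants A `variant_table`.
#' @param probands A `proband_table` (supplies each variant's baseline
#'   diagnosis via `proband_id`).
#' @param registry A `gene_registry`.
#' @param config A [cy_config()].
#' @return The variant table with `classification`, `suspicious_vus` and
#'   `triage_reasons` columns appended.
#' @export
classify_cohort_variants <- function(variants, probands, registry,
                                     config = cy_config()) {
  idx <- match(variants$proband_id, probands$proband_id)
  if (anyNA(idx)) {
    orphan <- variants$proband_id[which(is.na(idx))[1]]
    stop("variant references unknown proband_id: ", orphan)
  }
  n <- nrow(variants)
  cls <- character(n); susp <- logical(n); reasons <- character(n)
  for (i in seq_len(n)) {
    obs <- list(gene = variants$gene[i],
                consequence = variants$consequence[i],
                popmax_af = variants$popmax_af[i],
                criteria = variants$criteria[i],
                asserted_classification = variants$asserted_classification[i])
    r <- classify_variant(obs,
                          probands$clinical_diagnosis[idx[i]],
                          registry, config)
    cls[i] <- r$classification
    susp[i] <- r$suspicious_vus
    reasons[i] <- paste(r$triage_reasons, collapse = " | ")
  }
  variants$classification <- cls
  variants$suspicious_vus <- susp
  variants$triage_reasons <- reasons
  # invariant: suspicious only ever flags a VUS
  stopifnot(all(variants$classification[variants$suspicious_vus] == "VUS"))
  variants
}
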