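# Shared fixtures and independent oracles.

# ---- brute-force combining-rule oracle -------------------------------------
# Independent of combine_criteria(): the published rule table written as an
# explicit pattern list, matched by componentwise subset comparison on the
# effective-strength tallies.

oracle_patterns <- list(
  pathogenic = list(
    c(vs = 2),
    c(vs = 1, s = 1), c(vs = 1, m = 2), c(vs = 1, m = 1, p = 1),
    c(vs = 1, p = 2),
    c(s = 2),
    c(s = 1, m = 3), c(s = 1, m = 2, p = 2), c(s = 1, m = 1, p = 4)),
  likely_pathogenic = list(
    c(vs = 1, m = 1),
    c(s = 1, m = 1), c(s = 1, p = 2),
    c(m = 3), c(m = 2, p = 2), c(m = 1, p = 4)),
  benign = list(c(ba = 1), c(bs = 2)),
  likely_benign = list(c(bs = 1, bp = 1), c(bp = 2)))

oracle_combine <- function(tokens) {
  full <- c(vs = 0, s = 0, m = 0, p = 0, ba = 0, bs = 0, bp = 0)
  for (tok in tokens) {
    parts <- strsplit(tok, "_", fixed = TRUE)[[1]]
    code <- parts[1]
    strength <- if (length(parts) > 1) paste(parts[-1], collapse = "_")
                else NA
    fam <- sub("[0-9]+$", "", code)
    if (is.na(strength)) {
      strength <- c(PVS = "very_strong", PS = "strong", PM = "moderate",
                    PP = "supporting", BA = "stand_alone", BS = "strong",
                    BP = "supporting")[[fam]]
    }
    slot <- if (fam %in% c("PVS", "PS", "PM", "PP")) {
      c(very_strong = "vs", strong = "s", moderate = "m",
        supporting = "p")[[strength]]
    } else {
      c(stand_alone = "ba", very_strong = "bs", strong = "bs",
        moderate = "bp", supporting = "bp")[[strength]]
    }
    full[slot] <- full[slot] + 1
  }
  hits <- vapply(oracle_patterns, function(pats) {
    any(vapply(pats, function(pp) all(full[names(pp)] >= pp), logical(1)))
  }, logical(1))
  path <- hits[["pathogenic"]] || hits[["likely_pathogenic"]]
  ben <- hits[["benign"]] || hits[["likely_benign"]]
  if (path && ben) return("VUS")
  for (cls in names(hits)) if (hits[[cls]]) return(cls)
  "VUS"
}

# All criterion tokens observed in suspicious-VUS / solved reporting,
# including the strength-shifted forms.
observed_tokens <- list(
  PVS1 = c("PVS1", "PVS1_moderate"),
  PS1 = "PS1",
  PS3 = "PS3_supporting",
  PS4 = c("PS4", "PS4_moderate", "PS4_supporting"),
  PM1 = c("PM1", "PM1_supporting"),
  PM2 = "PM2",
  PM6 = "PM6",
  PP1 = "PP1",
  PP3 = "PP3",
  BA1 = "BA1",
  BS1 = "BS1",
  BP4 = "BP4")

# Enumerate every multiset of <= max_size criteria with distinct base codes,
# one strength variant per code.
enumerate_criterion_sets <- function(max_size = 5) {
  sets <- list(character())
  for (code in names(observed_tokens)) {
    new_sets <- sets
    for (tok in observed_tokens[[code]]) {
      for (s in sets) {
        if (length(s) < max_size) new_sets[[length(new_sets) + 1]] <- c(s, tok)
      }
    }
    sets <- new_sets
  }
  sets
}

# ---- quick cohort constructors ---------------------------------------------

make_probands <- function(n = 1, diagnosis = "HCM", certainty = NULL,
                          age = 45, relatives = 0, severe = FALSE,
                          ancestry = "European", provenance = "clinical",
                          ...) {
  if (is.null(certainty)) {
    certainty <- ifelse(grepl("^possible_|^undiagnosed$|^unexplained_SCA$",
                              diagnosis), "uncertain", "definite")
  }
  d <- data.frame(
    proband_id = sprintf("T%03d", seq_len(n)),
    clinical_diagnosis = diagnosis,
    diagnosis_certainty = certainty,
    age_at_diagnosis = age,
    n_affected_relatives = relatives,
    scd_or_resuscitated_arrest = FALSE,
    sustained_vt = severe,
    appropriate_icd_shock = FALSE,
    cardiac_transplant = FALSE,
    lvad = FALSE,
    ejection_fraction_pct = 60,
    max_lvh_mm = 18,
    qtc_ms = 430,
    ancestry = ancestry,
    year_first_seen = 2010,
    year_genetic_diagnosis = NA_real_,
    testing_provenance = provenance,
    expanded_testing = FALSE,
    final_diagnosis = NA_character_,
    exclusion_reason = NA_character_,
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) d[[nm]] <- extra[[nm]]
  validate_probands(d)
}

make_variants <- function(proband_id, gene = "MYBPC3",
                          consequence = "missense", popmax_af = 0,
                          criteria = "PM2;PP3", asserted = NA_character_) {
  n <- length(proband_id)
  d <- data.frame(
    proband_id = proband_id, gene = rep_len(gene, n),
    variant_label = sprintf("v%03d", seq_along(proband_id)),
    consequence = rep_len(consequence, n),
    popmax_af = rep_len(popmax_af, n),
    af_assumed_absent = rep_len(popmax_af == 0, n),
    criteria = rep_len(criteria, n),
    asserted_classification = rep_len(asserted, n),
    stringsAsFactors = FALSE)
  class(d) <- c("variant_table", "data.frame")
  d
}

test_registry <- function() {
  gene_registry(list(
    genes = list(
      MYBPC3 = list(tier = "tier1",
                    associations = list(list(disease = "HCM",
                                             validity = "definitive"))),
      MYH7 = list(tier = "tier1",
                  associations = list(list(disease = "HCM",
                                           validity = "definitive"))),
      TTN = list(tier = "tier1",
                 associations = list(list(disease = "DCM",
                                          validity = "definitive"))),
      FHOD3 = list(tier = "tier2",
                   associations = list(list(disease = "HCM",
                                            validity = "moderate"))),
      OBSCN = list(tier = "tier2",
                   associations = list(list(disease = "HCM",
                                            validity = "limited")))),
    max_credible_popmax_af = list(HCM = 4e-5, DCM = 1e-5)))
}

# Independent naive tabulator for yield tables: plain subset-and-count.
naive_yield <- function(adj, group) {
  lpp <- adj$best_classification %in% c("likely_pathogenic", "pathogenic")
  svus <- adj$category == "suspicious_vus"
  do.call(rbind, lapply(sort(unique(group)), function(g) {
    k <- group == g
    data.frame(stratum = g, n = sum(k), n_LPP = sum(lpp & k),
               n_suspicious_VUS = sum(svus & k), stringsAsFactors = FALSE)
  }))
}
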