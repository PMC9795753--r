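---
title: "Adjudicating diagnostic yield in an inherited cardiac conditions clinic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjudicating diagnostic yield in an inherited cardiac conditions clinic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioyield)
```

## The problem

Specialised cardiac genetic clinics see consecutive probands — the first
affected member of each family — with inherited cardiomyopathies (HCM, DCM,
LVNC, ACM, RCM), arrhythmia syndromes (LQTS, BrS, CPVT), or undifferentiated
presentations such as unexplained resuscitated cardiac arrest. Genetic
testing solves only a minority of these families, and the audit questions a
clinic actually asks are: what fraction of probands receive a causative
(likely pathogenic or pathogenic, LP/P) result; which uncertain results are
worth pursuing; which unsolved probands most likely harbour an undiscovered
monogenic cause; and how equitable the yield is across ancestry groups.
`cardioyield` implements that audit as a reproducible pipeline: variant
triage, a monogenic disease score, a solved/unsolved adjudication flow, and
stratified yield statistics, plus a simulator and a deterministic reference
cohort so every stage is testable without access to patient data.

## Variant triage

Evidence for each reported variant arrives as ACMG/AMP criterion codes,
possibly strength-shifted (`PS4_moderate`, `PVS1_moderate`,
`PM1_supporting`, ...). `combine_criteria()` applies the standard
categorical combining rules with *strength substitution*: a criterion counts
at its effective strength, whatever its code family. We deliberately
implement the published categorical table (plus the natural "two very-strong
is pathogenic" extension) rather than later point-based refinements, because
strength-shifted categorical codes are what clinical reports carry.
Conflicting pathogenic and benign evidence yields `VUS`, never an error.
Benign evidence has no canonical "moderate" tier; a benign code shifted to
moderate is counted at supporting strength (the conservative reading). The
test suite proves the combiner equivalent to an independent brute-force
pattern-matching oracle over every criterion multiset of size up to five
drawn from the codes observed in practice, and checks monotonicity: adding
pathogenic evidence, or raising a criterion's strength, never lowers the
classification.

A VUS is flagged **suspicious** when all of the following hold
(`assess_suspicious_vus()` records each rule consulted):

* popmax allele frequency strictly below the disease's maximum credible
  frequency — 4e-5 for HCM, 1e-5 for the rarer diseases by default,
  per-disease overridable in the registry. An AF absent from the reference
  database is coded 0 and flagged `af_assumed_absent`, since absence
  satisfies rarity;
* the gene has a *definitive* disease association concordant with the
  proband's baseline phenotype (`possible_X` matches `X`; undifferentiated
  phenotypes have nothing to match and are never flagged);
* the consequence is protein-altering, where predicted splice-affecting
  synonymous and deep-intronic variants count as altering — solved-on-review
  experience shows such variants are causal;
* at least one pathogenic-direction criterion is applied. PM2 alone
  qualifies by default (in practice every suspicious VUS carries PM2);
  `cy_config(require_nonfreq_criterion = TRUE)` demands evidence beyond
  rarity. Stand-alone or default-strength strong benign evidence blocks the
  flag.

## The monogenic disease score

Additive points over the family unit: positive family history 2, severe
phenotype 1, young onset 1 (< 30 years) or 2 (< 10 years). Age bands take
the maximum, not the sum, so totals span 0–5 and are reported in buckets
0/1/2/3/≥4. Unsolved probands scoring ≥ 1 are "likely monogenic", 0 "likely
complex".

Choices a user can revisit, with defaults and rationale:

* **Age comparisons are strict** (`< 30`, `< 10`), following the score's
  definition; descriptive tables elsewhere sometimes print `≤ 30`. Both the
  cutoffs and strictness are configurable (`age_cutoff_young`,
  `age_strict`).
* **"Familial disease" means the family unit holds more than one affected
  member**: one affected relative beyond the proband scores the 2 points
  (`fh_min_relatives = 1`). The defining sentence is ambiguous between
  "more than one member" and "more than one relative"; we adopt the former
  and expose the knob.
* **Severe phenotype** is any ventricular-arrhythmia or heart-failure event
  flag, or a measurement extreme: EF < 30 %, maximal LVH ≥ 30 mm (inclusive),
  QTc ≥ 500 ms — thresholds configurable. Missing measurements contribute
  false; missing age or unassessed family history score 0 and are flagged
  in the output for sensitivity analysis.

## Adjudication flow

Each included proband lands in exactly one category. The best variant
(highest classification; suspicious flag, then gene symbol, then label as
deterministic tie-breaks) drives the flow:

* concordant LP/P from clinical-provenance testing → `solved_baseline`;
* concordant LP/P requiring research effort (`testing_provenance =
  research_tier2`) → `solved_on_review`. Provenance is the machine-readable
  proxy for "solved on review": narrative case review cannot be automated;
* suspicious VUS → `suspicious_vus`, a separate category that is *not*
  counted as unsolved. Flow counts report both rollups (LP/P-only
  "solved at baseline" and the rollup including suspicious-VUS carriers)
  because audit conventions differ;
* otherwise `unsolved_likely_monogenic` / `unsolved_likely_complex` by the
  score dichotomy.

Concordance requires a definitive or moderate gene–disease association with
the proband's diagnosis; for `undiagnosed` and `unexplained_SCA` probands
any definitive association is concordant — the genetic result supplies the
diagnosis. An LP/P the registry cannot reconcile with either the baseline
or a curated `final_diagnosis` is `discordant_LPP`: held for manual review,
never silently solved, because real discordant findings (incidental or
secondary) were adjudicated in multidisciplinary meetings.

`diagnosis_change` attaches to LP/P results only — a VUS cannot formally
change a diagnosis. It is `changed` when the implied disease is a different
entity from baseline (including an undifferentiated baseline now given a
diagnosis, or a curated `final_diagnosis` differing from a definite
baseline), `clarified` when a `possible_X` baseline is confirmed as `X`.
Re-diagnosis of definite-baseline cases enters through the curated
`final_diagnosis` input column, mirroring clinical review, rather than
being inferred from the registry: automatic reassignment would silently
solve genuinely discordant findings.

## Reporting

Yield tables count, per stratum, probands, LP/P carriers and
suspicious-VUS carriers, with percentages rounded half-away-from-zero to
integers (`rounding = "half_even"` available). Counts always accompany
percentages because published tables occasionally round differently
(e.g. 21/47 printed as 44 %). Strata: score bucket × diagnosis certainty;
the seven non-empty combinations of family history/severe/young; ancestry
group (unknown ancestry excluded and counted). Suspicious-VUS proportions
are compared per ancestry group against Europeans with 2×2 Pearson
chi-squared tests (no continuity correction, df = 1, nominal p-values, no
multiple-testing correction — matching the audit's own analysis). The
t-test is Student's pooled-variance by default, Welch by flag, and a
summary-statistic entry point reproduces the raw-data result exactly —
needed because published group summaries (e.g. time-to-diagnosis by era)
arrive without raw data.

## The simulator and what a green test establishes

`simulate_cohort()` draws each proband's aetiology Bernoulli(π), phenotype
features from aetiology-specific distributions, and pushes monogenic
probands through detection → classifiability → tier-2 rescue. Defaults are
fixed once to echo the clinic cohort's marginal structure: π = 0.45;
HCM-dominant diagnosis mix; onset truncated-normal (monogenic 35 ± 15 y,
complex 55 ± 12 y, bracketing the cohort's 41.6 ± 16.6); family history
50 % vs 20 % (overall ≈ 32 %); severe 40 % vs 25 % (overall ≈ 31 %);
detectability 0.9; LP/P classifiability 0.92 for Europeans vs 0.6
elsewhere (the reference-database inequity knob); tier-2 rescue 0.25. The
implied LP/P yield, `expected_lpp_yield()`, is ≈ 0.35 at these defaults.

The simulator emulates marginal structure and conditional independence
given aetiology; it does not model pedigree transmission, polygenic scores,
variant nomenclature, or correlated feature noise. A green recovery test
therefore establishes that the pipeline is an unbiased estimator of the
generator's signal — not that the generator is the clinic. The
deterministic reference cohort (`build_reference_cohort()`) serves the
complementary purpose: a constructed, not simulated, 888-proband table
whose printed margins are realised exactly through the real pipeline.
Printed margins admit many joint tables; ours is one fixed assignment, and
three published counts are internally inconsistent by one or a few units
(a score-1 LP/P cell, the uncertain likely-monogenic count, the ancestry
denominators). The construction follows the reading that keeps all
cross-margins simultaneously consistent; where two published figures
disagree by two probands (score-1 stratum 162 vs feature cells 82 + 82),
exactly two "young only" probands are given onset < 10 years.

## Numerical details and limitations

Rarity is a strict inequality at the threshold. Percentages for empty
strata are undefined and render as "—". Two runs with identical inputs and
config produce identical output bytes; the run manifest carries the only
timestamp. Known limitations: evidence criteria are inputs, not derived
(no annotation, no HGVS validation); impact tags and exclusion reasons are
curated inputs, only tabulated; the packaged gene registry is illustrative,
not an authoritative curation; and the score is fixed-weight by design —
no calibration is attempted.
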