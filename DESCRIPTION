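Package: cardioyield
Title: Diagnostic Yield Analysis for Inherited Cardiac Condition Cohorts
Version: 0.1.0
Authors@R:
    person("Cardiogenetics", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for adjudicating cohorts of probands referred to a
    specialised cardiac genetic clinic. Combines ACMG/AMP evidence codes
    (including strength-modified criteria) into a five-tier classification,
    triages suspicious variants of uncertain significance, computes a
    points-based monogenic disease score (family history, severe phenotype,
    young onset), assigns each proband a final solved/unsolved flow category,
    and produces stratified diagnostic-yield tables with chi-squared and
    t-test comparisons. Includes a seeded synthetic-cohort simulator and a
    deterministic reference cohort for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
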