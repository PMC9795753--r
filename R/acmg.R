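#' ACMG/AMP evidence codes and the categorical combining rules
#'
#' Evidence criteria are written as a base code (`PVS1`, `PS1`..`PS4`,
#' `PM1`..`PM6`, `PP1`..`PP5`, `BA1`, `BS1`..`BS4`, `BP1`..`BP7`) optionally
#' followed by a strength modifier, e.g. `PS4_moderate` or `PVS1_moderate`.
#' A criterion counts toward the combining rules at its *effective* strength:
#' the canonical strength of its code family unless a modifier shifts it.
#'
#' @name acmg
NULL

CY_PATH_CODES <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5)
)
CY_BENIGN_CODES <- c("BA1", paste0("BS", 1:4), paste0("BP", 1:7))
CY_ALL_CODES <- c(CY_PATH_CODES, CY_BENIGN_CODES)

canonical_strength <- function(code) {
  prefix <- sub("[0-9]+$", "", code)
  switch(prefix,
    PVS = "very_strong",
    PS  = "strong",
    PM  = "moderate",
    PP  = "supporting",
    BA  = "stand_alone",
    BS  = "strong",
    BP  = "supporting",
    stop("unknown criterion code: ", code)
  )
}

criterion_direction <- function(code) {
  if (code %in% CY_PATH_CODES) "pathogenic" else "benign"
}

#' Parse a criterion string into code + effective strength
#'
#' @param x Character vector of criterion tokens such as `"PM2"` or
#'   `"PS4_moderate"`.
#' @return A data.frame with columns `base_code`, `strength`, `direction`.
#'   Unknown codes or strength modifiers raise an error naming the token.
#' @examples
#' parse_criteria(c("PM2", "PP3", "PS4_moderate"))
#' @export
parse_criteria <- function(x) {
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (!length(x)) {
    return(data.frame(base_code = character(), strength = character(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  parts <- regmatches(x, regexec("^([A-Z]+[0-9]+)(?:_([a-z_]+))?$", x))
  out <- lapply(seq_along(x), function(i) {
    m <- parts[[i]]
    if (length(m) == 0 || !nzchar(m[2]) || !(m[2] %in% CY_ALL_CODES)) {
      stop("unknown criterion code: '", x[i], "'")
    }
    code <- m[2]
    strength <- if (nzchar(m[3])) m[3] else canonical_strength(code)
    if (!strength %in% CY_STRENGTHS) {
      stop("unknown strength modifier in '", x[i], "'")
    }
    data.frame(base_code = code, strength = strength,
               direction = criterion_direction(code),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Render criteria back to canonical strings
#'
#' The strength suffix is written only when it differs from the code's
#' canonical strength, so parsing and formatting round-trip exactly.
#'
#' @param criteria A data.frame from [parse_criteria()].
#' @return Character vector of canonical tokens.
#' @export
format_criteria <- function(criteria) {
  if (!nrow(criteria)) return(character())
  vapply(seq_len(nrow(criteria)), function(i) {
    code <- criteria$base_code[i]
    s <- criteria$strength[i]
    if (identical(s, canonical_strength(code))) code
    else paste0(code, "_", s)
  }, character(1))
}

#' Parse a semicolon-separated criteria field
#'
#' Splits `"PM2;PP3;PS4_moderate"` into its criteria via
#' [parse_criteria()]; `"."`, `""` and NA give an empty set. Memoized:
#' cohorts reuse a handful of distinct criteria strings.
#'
#' @param s A single criteria string.
#' @return A criteria data.frame.
#' @export
parse_criteria_field <- local({
  cache <- new.env(parent = emptyenv())
  function(s) {
    if (is.na(s) || s %in% c("", ".")) return(parse_criteria(character()))
    hit <- cache[[s]]
    if (!is.null(hit)) return(hit)
    out <- parse_criteria(strsplit(s, ";", fixed = TRUE)[[1]])
    cache[[s]] <- out
    out
  }
})

# Tally effective strengths by direction. Benign evidence has no canonical
# "moderate" tier; a benign criterion shifted to moderate is counted at
# supporting strength (conservative).
strength_counts <- function(criteria) {
  path <- criteria[criteria$direction == "pathogenic", , drop = FALSE]
  ben <- criteria[criteria$direction == "benign", , drop = FALSE]
  list(
    vs = sum(path$strength == "very_strong"),
    s  = sum(path$strength == "strong"),
    m  = sum(path$strength == "moderate"),
    p  = sum(path$strength == "supporting"),
    ba = sum(ben$strength == "stand_alone"),
    bs = sum(ben$strength %in% c("strong", "very_strong")),
    bp = sum(ben$strength %in% c("supporting", "moderate"))
  )
}

#' Combine evidence criteria into a five-tier classification
#'
#' Implements the published categorical combining rules with strength
#' substitution: each criterion counts at its effective strength, so e.g.
#' `PVS1_moderate` contributes one moderate. Pathogenic requires one
#' very-strong plus (>=1 strong | >=2 moderate | 1 moderate + 1 supporting |
#' >=2 supporting), or >=2 very-strong, or >=2 strong, or 1 strong plus
#' (>=3 moderate | 2 moderate + >=2 supporting | 1 moderate + >=4
#' supporting). Likely pathogenic requires 1 very-strong + 1 moderate,
#' 1 strong + 1-2 moderate, 1 strong + >=2 supporting, >=3 moderate,
#' 2 moderate + >=2 supporting, or 1 moderate + >=4 supporting. Benign is
#' stand-alone evidence or >=2 benign-strong; likely benign is 1
#' benign-strong + 1 benign-supporting or >=2 benign-supporting. When both a
#' pathogenic-direction and a benign-direction rule fire, the evidence is
#' conflicting and the result is `VUS`; with insufficient evidence the
#' result is `VUS`.
#'
#' @param criteria A data.frame from [parse_criteria()], or a character
#'   vector of criterion tokens.
#' @return One of `"pathogenic"`, `"likely_pathogenic"`, `"VUS"`,
#'   `"likely_benign"`, `"benign"`.
#' @examples
#' combine_criteria(c("PVS1", "PM2"))       # pathogenic
#' combine_criteria(c("PS1", "PM2"))        # likely_pathogenic
#' combine_criteria(c("PM2", "PP3"))        # VUS
#' combine_criteria("BA1")                  # benign
#' @export
combine_criteria <- function(criteria) {
  if (is.character(criteria)) criteria <- parse_criteria(criteria)
  if (anyDuplicated(criteria$base_code)) {
    dup <- unique(criteria$base_code[duplicated(criteria$base_code)])
    stop("duplicate criterion code(s): ", paste(dup, collapse = ", "))
  }
  n <- strength_counts(criteria)

  pathogenic <-
    n$vs >= 2 ||
    (n$vs == 1 && (n$s >= 1 || n$m >= 2 || (n$m >= 1 && n$p >= 1) || n$p >= 2)) ||
    n$s >= 2 ||
    (n$s == 1 && (n$m >= 3 || (n$m >= 2 && n$p >= 2) || (n$m >= 1 && n$p >= 4)))

  likely_pathogenic <-
    (n$vs >= 1 && n$m >= 1) ||
    (n$s >= 1 && n$m >= 1) ||
    (n$s >= 1 && n$p >= 2) ||
    n$m >= 3 ||
    (n$m >= 2 && n$p >= 2) ||
    (n$m >= 1 && n$p >= 4)

  benign <- n$ba >= 1 || n$bs >= 2
  likely_benign <- (n$bs >= 1 && n$bp >= 1) || n$bp >= 2

  path_met <- pathogenic || likely_pathogenic
  ben_met <- benign || likely_benign
  if (path_met && ben_met) return("VUS")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "VUS"
}
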