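#' Gene registry: tiers, disease validity, rarity thresholds
#'
#' The registry records, per gene, its analysis tier (tier 1 = robust
#' clinical validity, tier 2 = less well-characterised) and its
#' disease associations with a validity level (`definitive`, `moderate`,
#' `limited`), plus per-disease maximum credible popmax allele frequencies
#' used by the rarity filter.
#'
#' @name gene_registry
NULL

#' Load a gene registry from JSON or YAML
#'
#' The document has two top-level sections: `genes` (name -> `tier` and
#' `associations`, each association a `disease` + `validity`) and
#' `max_credible_popmax_af` (disease -> allele fraction). A default HCM
#' threshold of 4e-5 is supplied unless overridden; all other diseases
#' default to the more stringent 1e-5 at query time.
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` registry file.
#' @param config A [cy_config()] supplying default thresholds.
#' @return A validated `gene_registry` object.
#' @examples
#' reg <- load_gene_registry(cy_example("gene_registry.json"))
#' gene_tier(reg, "MYBPC3")
#' @export
load_gene_registry <- function(path, config = cy_config()) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  gene_registry(doc, config = config)
}

#' Construct and validate a gene registry from a list
#'
#' @param doc List with `genes` and optional `max_credible_popmax_af`.
#' @param config A [cy_config()].
#' @return A `gene_registry` object.
#' @export
gene_registry <- function(doc, config = cy_config()) {
  if (is.null(doc$genes) || !length(doc$genes)) {
    stop("registry has no 'genes' section")
  }
  genes <- lapply(doc$genes, function(g) {
    tier <- g$tier
    if (is.null(tier) || !tier %in% c("tier1", "tier2")) {
      stop("gene tier must be 'tier1' or 'tier2'")
    }
    assoc <- lapply(g$associations %||% list(), function(a) {
      if (is.null(a$disease) || is.null(a$validity)) {
        stop("association needs 'disease' and 'validity'")
      }
      if (!a$validity %in% CY_VALIDITY) {
        stop("unknown validity level: ", a$validity)
      }
      if (!a$disease %in% CY_BASE_DIAGNOSES) {
        stop("unknown disease in association: ", a$disease)
      }
      list(disease = a$disease, validity = a$validity)
    })
    if (!length(assoc)) stop("gene with no disease associations")
    list(tier = tier, associations = assoc)
  })
  # tier1 genes must carry at least one definitive association
  for (g in names(genes)) {
    if (genes[[g]]$tier == "tier1") {
      v <- vapply(genes[[g]]$associations, `[[`, "", "validity")
      if (!any(v == "definitive")) {
        stop("tier1 gene without a definitive association: ", g)
      }
    }
  }
  thr <- vapply(doc$max_credible_popmax_af %||% list(), as.numeric, 0)
  if (!"HCM" %in% names(thr)) thr[["HCM"]] <- config$hcm_max_af
  if (any(thr < 0 | thr > 1)) stop("allele-frequency thresholds must be in [0,1]")
  structure(list(genes = genes, max_af = as.list(thr),
                 default_max_af = config$default_max_af),
            class = "gene_registry")
}

#' @export
print.gene_registry <- function(x, ...) {
  cat("gene_registry:", length(x$genes), "genes,",
      length(x$max_af), "disease thresholds\n")
  invisible(x)
}

registry_gene <- function(registry, gene) {
  g <- registry$genes[[gene]]
  if (is.null(g)) stop("gene not in registry: ", gene)
  g
}

#' @rdname gene_registry
#' @param registry A `gene_registry`.
#' @param gene Gene symbol.
#' @return `gene_tier`: `"tier1"` or `"tier2"`.
#' @export
gene_tier <- function(registry, gene) {
  registry_gene(registry, gene)$tier
}

# Validity of the gene-disease pair, or NA if unlisted.
gene_disease_validity <- function(registry, gene, disease) {
  a <- registry_gene(registry, gene)$associations
  for (x in a) if (x$disease == disease) return(x$validity)
  NA_character_
}

#' Diseases associated with a gene at the given validity levels
#' @param validity Validity levels to include.
#' @rdname gene_registry
#' @export
gene_diseases <- function(registry, gene, validity = CY_VALIDITY) {
  a <- registry_gene(registry, gene)$associations
  unlist(lapply(a, function(x) if (x$validity %in% validity) x$disease))
}

#' Maximum credible popmax allele frequency for a disease
#'
#' @param registry A `gene_registry`.
#' @param disease A base disease label.
#' @return Allele fraction; the registry's entry or the stringent default.
#' @export
max_credible_af <- function(registry, disease) {
  disease <- cy_base_diagnosis(disease)
  if (!disease %in% CY_BASE_DIAGNOSES) {
    stop("unknown disease: ", disease)
  }
  registry$max_af[[disease]] %||% registry$default_max_af
}

#' Path to a packaged example data file
#' @param file File name under the package's `extdata/`.
#' @return Absolute path.
#' @export
cy_example <- function(file) {
  system.file("extdata", file, package = "cardioyield", mustWork = TRUE)
}

#' The packaged default gene registry
#'
#' An illustrative registry covering the sarcomere and arrhythmia genes used
#' by the simulator and reference cohort. It is not an authoritative gene
#' curation.
#'
#' @param config A [cy_config()].
#' @return A `gene_registry`.
#' @export
default_gene_registry <- function(config = cy_config()) {
  load_gene_registry(cy_example("gene_registry.json"), config = config)
}
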