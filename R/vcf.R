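#' Ingest variant observations from an annotated VCF
#'
#' Reads a VCF 4.x file (via Bioconductor's VariantAnnotation) whose INFO
#' field carries the gene symbol, consequence, popmax allele frequency and
#' applied criterion codes under configurable key names. Each record is
#' attributed to the sample(s) carrying a non-reference genotype (or to the
#' single sample when the file has exactly one). Coordinates are 1-based per
#' the VCF convention and are carried only inside the opaque
#' `variant_label`.
#'
#' Records missing the gene or consequence key are skipped with a warning
#' and counted in the `n_skipped` attribute. A missing popmax-AF key is
#' treated as absent from the reference database: `popmax_af = 0` with
#' `af_assumed_absent = TRUE`.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param info_key_map Named list mapping the roles `gene`, `consequence`,
#'   `popmax_af`, `criteria` to INFO key names.
#' @return A `variant_table` data.frame (see [read_variant_table()]).
#' @export
ingest_vcf <- function(path,
                       info_key_map = list(gene = "GENE",
                                           consequence = "CSQT",
                                           popmax_af = "POPMAX_AF",
                                           criteria = "ACMG")) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF ingestion requires the VariantAnnotation package")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  needed <- c("gene", "consequence", "popmax_af", "criteria")
  if (!all(needed %in% names(info_key_map))) {
    stop("info_key_map must name keys for: ", paste(needed, collapse = ", "))
  }
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  n <- length(vcf)
  if (n == 0) {
    out <- data.frame(proband_id = character(), gene = character(),
                      variant_label = character(), consequence = character(),
                      popmax_af = numeric(), af_assumed_absent = logical(),
                      criteria = character(),
                      asserted_classification = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("variant_table", "data.frame")
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  info <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  labels <- sprintf("%s:%d:%s>%s",
                    as.character(GenomicRanges::seqnames(rr)),
                    GenomicRanges::start(rr),
                    as.character(rr$REF),
                    vapply(rr$ALT, function(a) paste(as.character(a),
                                                     collapse = ","),
                           character(1)))
  get_key <- function(role, i, all = FALSE) {
    key <- info_key_map[[role]]
    if (!key %in% names(info)) return(NULL)
    v <- info[[key]][i]
    if (is.list(v) || inherits(v, "List")) v <- unlist(v)
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    if (all) paste(v, collapse = ";") else v[1]
  }
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(n)) {
    gene <- get_key("gene", i)
    csq <- get_key("consequence", i)
    if (is.null(gene) || is.null(csq)) {
      warning("record ", i, " (", labels[i],
              "): missing gene/consequence INFO key, skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    if (!csq %in% CY_CONSEQUENCES) {
      warning("record ", i, ": unknown consequence '", csq, "', skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    af <- get_key("popmax_af", i)
    assumed <- is.null(af)
    af <- if (assumed) 0 else as.numeric(af)
    crit <- get_key("criteria", i, all = TRUE) %||% ""
    crit <- gsub(",", ";", crit, fixed = TRUE)
    parse_criteria_field(crit)  # validate codes; errors name the token
    carriers <- if (length(samples) == 1) samples else {
      has_alt <- !is.na(gt[i, ]) & !gt[i, ] %in% c("0/0", "0|0", "./.", ".")
      samples[has_alt]
    }
    for (s in carriers) {
      rows[[length(rows) + 1L]] <- data.frame(
        proband_id = s, gene = gene, variant_label = labels[i],
        consequence = csq, popmax_af = af, af_assumed_absent = assumed,
        criteria = crit, asserted_classification = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(proband_id = character(), gene = character(),
               variant_label = character(), consequence = character(),
               popmax_af = numeric(), af_assumed_absent = logical(),
               criteria = character(),
               asserted_classification = character(),
               stringsAsFactors = FALSE)
  }
  class(out) <- c("variant_table", "data.frame")
  attr(out, "n_skipped") <- n_skipped
  out
}
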