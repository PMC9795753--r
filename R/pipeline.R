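#' End-to-end pipeline and command-line interface
#'
#' `run_cohort_pipeline()` chains triage -> score -> adjudication on
#' in-memory tables; `run_pipeline()` is the file-based wrapper that also
#' writes the report directory and a machine-readable run manifest.
#' `cy_cli()` exposes the stages as subcommands
#' (`simulate | triage | score | adjudicate | report | run`) for use from
#' `Rscript -e 'cardioyield::cy_cli()'`.
#'
#' @name cli
NULL

#' Run triage, scoring and adjudication on in-memory tables
#'
#' @param probands A `proband_table`.
#' @param variants A `variant_table`.
#' @param registry A `gene_registry`.
#' @param config A [cy_config()].
#' @return An adjudicated cohort data.frame.
#' @export
run_cohort_pipeline <- function(probands, variants,
                                registry = default_gene_registry(),
                                config = cy_config()) {
  classified <- classify_cohort_variants(variants, probands, registry,
                                         config)
  scored <- score_cohort(probands, config)
  adjudicate_cohort(scored, classified, registry)
}

#' Run the full file-based pipeline
#'
#' Reads the proband/variant tables and registry, runs the pipeline,
#' writes the adjudicated per-proband TSV, the score TSV, the report
#' tables and a run manifest (package version, config, input hashes) into
#' `out_dir`. Output bytes are deterministic for identical inputs and
#' config; the manifest carries the only timestamp.
#'
#' @param probands_path,variants_path TSV inputs.
#' @param registry_path JSON/YAML registry (NULL for the packaged
#'   default).
#' @param out_dir Output directory.
#' @param config A [cy_config()].
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Invisibly, the adjudicated cohort.
#' @export
run_pipeline <- function(probands_path, variants_path,
                         registry_path = NULL, out_dir = "cy_report",
                         config = cy_config(), seed = NULL) {
  probands <- read_proband_table(probands_path)
  variants <- read_variant_table(variants_path)
  registry <- if (is.null(registry_path)) default_gene_registry(config)
              else load_gene_registry(registry_path, config)
  adj <- run_cohort_pipeline(probands, variants, registry, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  score_cols <- c("proband_id", "fh_points", "severe_points", "age_pts",
                  "score_total", "score_bucket", "score_flags")
  write_cohort_table(adj[, score_cols],
                     file.path(out_dir, "scores.tsv"))
  adj_cols <- c("proband_id", "clinical_diagnosis", "diagnosis_certainty",
                "score_total", "score_bucket", "category",
                "diagnosis_change", "final_disease", "best_classification",
                "best_gene", "best_suspicious", "time_to_diagnosis_years",
                "era")
  write_cohort_table(adj[, adj_cols],
                     file.path(out_dir, "adjudication.tsv"))
  render_report(adj, out_dir, config)

  manifest <- list(
    package = "cardioyield",
    version = as.character(utils::packageVersion("cardioyield")),
    generated = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = unclass(config),
    inputs = list(
      probands = unname(tools::md5sum(probands_path)),
      variants = unname(tools::md5sum(variants_path)),
      registry = if (is.null(registry_path)) "packaged default"
                 else unname(tools::md5sum(registry_path))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(adj)
}

parse_cli_args <- function(args) {
  opts <- list(); positional <- character()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1
      } else {
        opts[[key]] <- args[i + 1]
        i <- i + 2
      }
    } else {
      positional <- c(positional, a)
      i <- i + 1
    }
  }
  list(opts = opts, positional = positional)
}

cli_config <- function(opts) {
  cfg <- list()
  if (!is.null(opts$rounding)) cfg$rounding <- opts$rounding
  if (!is.null(opts[["age-cutoff"]])) {
    cfg$age_cutoff_young <- as.numeric(opts[["age-cutoff"]])
  }
  if (!is.null(opts[["fh-min-relatives"]])) {
    cfg$fh_min_relatives <- as.numeric(opts[["fh-min-relatives"]])
  }
  do.call(cy_config, cfg)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --seed S --n N --out-dir D`;
#' `run --probands P --variants V [--registry R] --out D` (also available
#' as `triage` / `score` / `adjudicate` / `report`, which run the same
#' pipeline and differ only in which outputs matter to the caller).
#' Common flags: `--rounding half_away|half_even`, `--age-cutoff`,
#' `--fh-min-relatives`. Diagnostics go to stderr; outputs only to files.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Exit status, invisibly (0 on success).
#' @export
cy_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cardioyield <simulate|run|triage|score|adjudicate|report>",
    "[--probands F] [--variants F] [--registry F] [--out D] [--seed N]",
    "[--n N] [--rounding half_away|half_even] [--age-cutoff A]",
    "[--fh-min-relatives K]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  parsed <- parse_cli_args(args[-1])
  opts <- parsed$opts
  status <- tryCatch({
    if (cmd == "simulate") {
      cfg_args <- list()
      if (!is.null(opts$seed)) cfg_args$seed <- as.integer(opts$seed)
      if (!is.null(opts$n)) cfg_args$n_probands <- as.integer(opts$n)
      scfg <- do.call(sim_config, cfg_args)
      out_dir <- opts[["out-dir"]] %||% opts$out %||% "sim_cohort"
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      sim <- simulate_cohort(scfg)
      write_cohort_table(sim$probands, file.path(out_dir, "probands.tsv"))
      write_cohort_table(sim$variants, file.path(out_dir, "variants.tsv"))
      message("simulated ", nrow(sim$probands), " probands -> ", out_dir)
      0L
    } else if (cmd %in% c("run", "triage", "score", "adjudicate",
                          "report")) {
      if (is.null(opts$probands) || is.null(opts$variants)) {
        stop("--probands and --variants are required")
      }
      adj <- run_pipeline(opts$probands, opts$variants, opts$registry,
                          opts$out %||% "cy_report", cli_config(opts),
                          seed = if (!is.null(opts$seed))
                            as.integer(opts$seed))
      message("adjudicated ", nrow(adj), " probands -> ",
              opts$out %||% "cy_report")
      0L
    } else {
      message(usage)
      1L
    }
  }, error = function(e) {
    message("error [", cmd, "]: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
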