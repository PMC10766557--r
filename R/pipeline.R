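#' Pipeline configuration
#'
#' Assembles (and validates) the single configuration object driving
#' [run_pipeline()]: input location and dialect, cohort and window settings,
#' every screening threshold, and the output directory. All validation
#' failures are reported at once.
#'
#' @param input Path to the input file(s): a report-table TSV, a named list
#'   `list(demo=, drug=, reac=, outc=)` of FAERS ASCII paths, or an
#'   `ae_reports` object used directly.
#' @param dialect `"report_table"`, `"faers_ascii"` or `"reports"` (in-memory).
#' @param output_dir Directory for stage outputs and the manifest.
#' @param cohorts Named list of [cohort_spec()]s (default: the overall cohort
#'   only; use [default_cohorts()] for the demographic set).
#' @param year_pair Integer `c(comparator, pandemic)`, default `c(2019, 2020)`.
#' @param n_min Minimum per-event count for Step 1 (default 3).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param paeai_base PAEAI logarithm base (default 10).
#' @param ratio Matching ratio (default 10).
#' @param gamma_counts `"matched"` or `"cohort"`.
#' @param exclude_aes Event ids excluded after Step 1 (default the
#'   pathogen-named terms).
#' @param bootstrap_B,seed Bootstrap resamples and RNG seed recorded in the
#'   manifest.
#' @param ae_map_path,drug_map_path Optional mapping-table paths for the
#'   FAERS dialect.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, dialect = c("report_table", "faers_ascii", "reports"),
                            output_dir = tempfile("paesignal_run_"),
                            cohorts = list(overall = cohort_spec()),
                            year_pair = c(2019L, 2020L), n_min = 3L,
                            alpha = 0.05, paeai_base = 10, ratio = 10L,
                            gamma_counts = "matched",
                            exclude_aes = COVID_AE_TERMS,
                            bootstrap_B = 1000L, seed = 1L,
                            ae_map_path = NULL, drug_map_path = NULL) {
  dialect <- match.arg(dialect)
  errs <- character()
  if (!(alpha > 0 && alpha < 1)) errs <- c(errs, "alpha must be in (0, 1)")
  if (ratio < 1) errs <- c(errs, "matching ratio must be >= 1")
  if (n_min < 1) errs <- c(errs, "n_min must be >= 1")
  if (paeai_base <= 0 || paeai_base == 1) errs <- c(errs, "paeai_base must be a valid log base")
  if (bootstrap_B < 1) errs <- c(errs, "bootstrap_B must be >= 1")
  if (length(year_pair) != 2L) errs <- c(errs, "year_pair must have two years")
  if (dialect == "report_table" && (!is.character(input) || !file.exists(input))) {
    errs <- c(errs, "input must be an existing report-table path")
  }
  if (dialect == "faers_ascii" &&
      (!is.list(input) || !all(c("demo", "drug", "reac", "outc") %in% names(input)))) {
    errs <- c(errs, "faers_ascii input must be list(demo=, drug=, reac=, outc=)")
  }
  if (dialect == "reports" && !inherits(input, "ae_reports")) {
    errs <- c(errs, "reports dialect requires an ae_reports object")
  }
  if (!is.list(cohorts) || length(cohorts) == 0L ||
      !all(vapply(cohorts, inherits, logical(1), "cohort_spec"))) {
    errs <- c(errs, "cohorts must be a non-empty list of cohort_spec objects")
  }
  if (length(errs) > 0L) {
    stop("invalid pipeline configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(
    list(input = input, dialect = dialect, output_dir = output_dir,
         cohorts = cohorts, year_pair = as.integer(year_pair),
         n_min = as.integer(n_min), alpha = alpha, paeai_base = paeai_base,
         ratio = as.integer(ratio), gamma_counts = gamma_counts,
         exclude_aes = exclude_aes, bootstrap_B = as.integer(bootstrap_B),
         seed = as.integer(seed), ae_map_path = ae_map_path,
         drug_map_path = drug_map_path),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads the scalar keys of [pipeline_config()] from a YAML file; cohort
#' entries are lists of [cohort_spec()] arguments.
#'
#' @param path YAML file path.
#' @param input Optional override of the input (e.g. an in-memory
#'   `ae_reports`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, input = NULL) {
  y <- yaml::read_yaml(path)
  cohorts <- if (is.null(y$cohorts)) list(overall = cohort_spec()) else {
    lapply(y$cohorts, function(args) do.call(cohort_spec, args))
  }
  pipeline_config(
    input = input %||% y$input,
    dialect = y$dialect %||% "report_table",
    output_dir = y$output_dir %||% tempfile("paesignal_run_"),
    cohorts = cohorts,
    year_pair = y$year_pair %||% c(2019L, 2020L),
    n_min = y$n_min %||% 3L,
    alpha = y$alpha %||% 0.05,
    paeai_base = y$paeai_base %||% 10,
    ratio = y$ratio %||% 10L,
    gamma_counts = y$gamma_counts %||% "matched",
    exclude_aes = y$exclude_aes %||% COVID_AE_TERMS,
    bootstrap_B = y$bootstrap_B %||% 1000L,
    seed = y$seed %||% 1L,
    ae_map_path = y$ae_map_path,
    drug_map_path = y$drug_map_path
  )
}

#' Run the full pipeline from one configuration
#'
#' Ingest, deduplicate, screen each configured cohort through the three
#' stages, and write all stage outputs plus a JSON manifest (configuration
#' echo, input hash, seed, and the per-cohort survivor funnel) under the
#' configured output directory. The funnel is monotone non-increasing by
#' construction: each stage only filters the previous stage's survivors.
#'
#' @param config A [pipeline_config()] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with `results` (per-cohort [run_screens()]
#'   bundles), `manifest` and `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  reports <- switch(
    config$dialect,
    report_table = read_report_table(config$input),
    faers_ascii = read_faers_ascii(
      config$input$demo, config$input$drug, config$input$reac, config$input$outc,
      ae_map = if (is.null(config$ae_map_path)) NULL else read_mapping(config$ae_map_path),
      drug_map = if (is.null(config$drug_map_path)) NULL else read_mapping(config$drug_map_path)
    ),
    reports = as_ae_reports(config$input)
  )
  n_ingested <- nrow(reports)
  reports <- deduplicate_reports(reports)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  results <- run_cohort_pipeline(
    reports, cohort_specs = config$cohorts, year_pair = config$year_pair,
    n_min = config$n_min, alpha = config$alpha,
    exclude_aes = config$exclude_aes, paeai_base = config$paeai_base,
    ratio = config$ratio, gamma_counts = config$gamma_counts
  )
  write_tsv <- function(df, name, cohort) {
    if (is.null(df)) return(invisible())
    flat <- as.data.frame(lapply(df, function(col) {
      if (is.list(col)) vapply(col, paste, character(1), collapse = ";") else col
    }))
    utils::write.table(flat, file.path(config$output_dir,
                                       sprintf("%s_%s.tsv", cohort, name)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(results)) {
    res <- results[[nm]]
    write_tsv(res$step1, "step1_disproportionality", nm)
    write_tsv(res$step2, "step2_trajectory", nm)
    if (!is.null(res$step3$gamma)) write_tsv(res$step3$gamma, "step3_gamma", nm)
    if (!is.null(res$step3$delta)) write_tsv(res$step3$delta, "step3_delta", nm)
    write_tsv(res$step3$attribution, "step3_attribution", nm)
  }
  input_hash <- if (config$dialect == "report_table") {
    as.character(tools::md5sum(config$input))
  } else if (config$dialect == "faers_ascii") {
    unname(vapply(config$input, function(p) as.character(tools::md5sum(p)),
                  character(1)))
  } else {
    sprintf("in-memory:%d-reports", n_ingested)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("paesignal")),
    dialect = config$dialect,
    input_hash = input_hash,
    seed = config$seed,
    n_reports_ingested = n_ingested,
    n_reports_deduplicated = nrow(reports),
    parameters = list(
      year_pair = config$year_pair, n_min = config$n_min, alpha = config$alpha,
      paeai_base = config$paeai_base, ratio = config$ratio,
      gamma_counts = config$gamma_counts, bootstrap_B = config$bootstrap_B,
      exclude_aes = config$exclude_aes,
      age_groups = lapply(config$cohorts, function(s) s$age_group)
    ),
    funnel = lapply(results, function(r) as.list(r$funnel)),
    final_aes = lapply(results, function(r) r$final_aes)
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest,
                 output_dir = config$output_dir))
}
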