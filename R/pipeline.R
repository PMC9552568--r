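#' Read a run configuration file
#'
#' A single structured YAML file drives every pipeline stage, so a run is
#' fully described by config + seed. Recognised top-level fields: `data_dir`,
#' `index_dir`, `report_dir`, `seed`, `window_days`, `generator` (fields of
#' [generator_config()]), `linkage` (fields of [linkage_config()]) and
#' `report` (`year`, `migration_adjust`). Relative paths resolve against the
#' config file's directory.
#'
#' @param path Path to the YAML file.
#' @param seed Optional seed overriding the file's.
#' @return List of class `scd_run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p, default) {
    p <- p %||% default
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  gen_args <- raw$generator %||% list()
  for (f in c("source_coverage", "genotype_props", "migration_rates",
              "death_hazard")) {
    if (!is.null(gen_args[[f]])) gen_args[[f]] <- unlist(gen_args[[f]])
  }
  gen_args$seed <- seed %||% raw$seed %||% gen_args$seed %||% 1L
  link_args <- raw$linkage %||% list()
  for (f in c("m_probs", "u_probs")) {
    if (!is.null(link_args[[f]])) link_args[[f]] <- unlist(link_args[[f]])
  }
  structure(list(
    data_dir = resolve(raw$data_dir, "data"),
    index_dir = resolve(raw$index_dir, "index"),
    report_dir = resolve(raw$report_dir, "reports"),
    seed = as.integer(gen_args$seed),
    window_days = as.integer(raw$window_days %||% 1826L),
    generator = do.call(generator_config, gen_args),
    linkage = do.call(linkage_config, link_args),
    report_year = raw$report$year %||% NULL,
    migration_adjust = raw$report$migration_adjust %||% TRUE
  ), class = "scd_run_config")
}

#' Run the whole pipeline in memory
#'
#' Generate (or accept) a source bundle, build the master index, classify
#' every person, and compute the standard outputs: the cumulative report over
#' the surveillance period, the annual report for the final year, truth-based
#' case-finding metrics, and pairwise linkage quality. This is the one-call
#' surface used by simulation studies and the evaluation suite.
#'
#' @param gen_config A [generator_config()]; ignored when `bundle` is given.
#' @param link_config A [linkage_config()].
#' @param bundle Optional pre-built `scd_source_bundle`.
#' @param window_days Rolling window for the probable case tier.
#' @return List of class `scd_run`: `bundle`, `index` (classified),
#'   `cumulative`, `annual`, `evaluation`, `linkage_quality`.
#' @examples
#' \donttest{
#' run <- run_pipeline(generator_config(n_population = 300, seed = 2))
#' run$cumulative
#' }
#' @export
run_pipeline <- function(gen_config = generator_config(),
                         link_config = linkage_config(),
                         bundle = NULL, window_days = 1826L) {
  if (is.null(bundle)) {
    truth <- generate_truth(gen_config)
    bundle <- emit_source_records(truth, gen_config)
  }
  period <- bundle$config$period
  index <- build_master_index(bundle$sources, link_config, period = period)
  index <- classify_index(index, bundle$sources, window_days)
  structure(list(
    bundle = bundle,
    index = index,
    cumulative = cumulative_report(index, bundle$sources, period),
    annual = annual_report(index, bundle$sources, period[2], period),
    evaluation = evaluate_against_truth(index, bundle$truth,
                                        bundle$provenance),
    linkage_quality = linkage_metrics(index, bundle$provenance)
  ), class = "scd_run")
}

#' @export
print.scd_run <- function(x, ...) {
  cat("<scd_run>\n")
  print(x$index)
  m <- x$evaluation$metrics
  cat(sprintf("  case finding: sens %.3f  spec %.3f  ppv %.3f  npv %.3f\n",
              m[["sensitivity"]], m[["specificity"]], m[["ppv"]],
              m[["npv"]]))
  lq <- x$linkage_quality
  cat(sprintf("  linkage:      precision %.3f  recall %.3f  F1 %.3f\n",
              lq[["precision"]], lq[["recall"]], lq[["f1"]]))
  invisible(x)
}

#' @noRd
write_stage_manifest <- function(dir, cfg, stage) {
  jsonlite::write_json(list(stage = stage, seed = cfg$seed,
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       file.path(dir, "stage_manifest.json"),
                       auto_unbox = TRUE)
}

#' Pipeline stage commands
#'
#' File-based counterparts of the in-memory pipeline, used by the shipped
#' command-line entry point: `cmd_generate()` writes the synthetic source
#' files, `cmd_build()` builds and persists the master index,
#' `cmd_classify()` fills case status, `cmd_report()` writes the requested
#' report, and `cmd_evaluate()` writes truth-based metrics. Every stage
#' records the run seed in its output manifest.
#'
#' @param cfg A `scd_run_config` from [read_run_config()].
#' @return The principal output of the stage, invisibly.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_generate <- function(cfg) {
  truth <- generate_truth(cfg$generator)
  bundle <- emit_source_records(truth, cfg$generator)
  write_source_files(bundle, cfg$data_dir)
  invisible(bundle)
}

#' @rdname pipeline-commands
#' @export
cmd_build <- function(cfg) {
  if (!file.exists(file.path(cfg$data_dir, "manifest.json"))) {
    scdlink_abort(sprintf("no source data found in %s: run `generate` first",
                          cfg$data_dir),
                  class = "scdlink_cli_error")
  }
  bundle <- read_source_files(cfg$data_dir)
  index <- build_master_index(bundle$sources, cfg$linkage,
                              period = bundle$config$period)
  write_master_index(index, cfg$index_dir)
  readr::write_tsv(index$quarantine, file.path(cfg$index_dir, "quarantine.tsv"),
                   na = "")
  write_stage_manifest(cfg$index_dir, cfg, "build")
  invisible(index)
}

#' @rdname pipeline-commands
#' @export
cmd_classify <- function(cfg) {
  if (!file.exists(file.path(cfg$index_dir, "persons.tsv"))) {
    scdlink_abort(sprintf("no master index found in %s: run `build` first",
                          cfg$index_dir),
                  class = "scdlink_cli_error")
  }
  bundle <- read_source_files(cfg$data_dir)
  index <- read_master_index(cfg$index_dir)
  index <- classify_index(index, bundle$sources, cfg$window_days)
  write_master_index(index, cfg$index_dir)
  write_stage_manifest(cfg$index_dir, cfg, "classify")
  invisible(index)
}

#' @rdname pipeline-commands
#' @param mode `"cumulative"`, `"annual"` or `"strata"`.
#' @param year Report year for annual/strata modes.
#' @export
cmd_report <- function(cfg, mode = c("cumulative", "annual", "strata"),
                       year = NULL) {
  mode <- match.arg(mode)
  bundle <- read_source_files(cfg$data_dir)
  index <- read_master_index(cfg$index_dir)
  if (all(is.na(index$persons$case_status))) {
    scdlink_abort("master index is unclassified: run `classify` first",
                  class = "scdlink_cli_error")
  }
  period <- bundle$config$period
  year <- year %||% cfg$report_year %||% period[2]
  rpt <- switch(mode,
    cumulative = cumulative_report(index, bundle$sources, period),
    annual = annual_report(index, bundle$sources, year, period,
                           cfg$migration_adjust),
    strata = stratified_report(index, bundle$sources, year,
                               cfg$migration_adjust))
  dir.create(cfg$report_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::as_tibble(rpt),
                   file.path(cfg$report_dir, paste0(mode, ".tsv")), na = "")
  write_stage_manifest(cfg$report_dir, cfg, paste0("report-", mode))
  invisible(rpt)
}

#' @rdname pipeline-commands
#' @export
cmd_evaluate <- function(cfg) {
  bundle <- read_source_files(cfg$data_dir)
  index <- read_master_index(cfg$index_dir)
  if (all(is.na(index$persons$case_status))) {
    scdlink_abort("master index is unclassified: run `classify` first",
                  class = "scdlink_cli_error")
  }
  ev <- evaluate_against_truth(index, bundle$truth, bundle$provenance)
  lq <- linkage_metrics(index, bundle$provenance)
  dir.create(cfg$report_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(seed = cfg$seed,
                            counts = as.list(ev$counts),
                            metrics = as.list(ev$metrics),
                            linkage = as.list(lq)),
                       file.path(cfg$report_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(evaluation = ev, linkage_quality = lq))
}
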