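#' Pipeline configuration
#'
#' A YAML-backed configuration tying the pipeline stages together:
#' input/output paths, filtration thresholds, recurrence-candidate
#' thresholds, simulation parameters, and the master seed. The config
#' round-trips losslessly through its file format.
#'
#' @param calls path to the canonical calls TSV (input of
#'   [run_filter()], output of [run_simulate()])
#' @param panel path to a panel TSV; `NULL` selects the packaged CAGP
#' @param out_dir output directory (created on demand)
#' @param filter named list of [filter_config()] overrides
#' @param recurrence named list of [select_candidates()] threshold
#'   overrides
#' @param simulation named list of [sim_params()] overrides
#' @param seed master seed
#' @param verbose print progress lines (default TRUE)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(calls = NULL, panel = NULL,
                            out_dir = ".", filter = list(),
                            recurrence = list(), simulation = list(),
                            seed = 1L, verbose = TRUE) {
  structure(list(calls = calls, panel = panel, out_dir = out_dir,
                 filter = filter, recurrence = recurrence,
                 simulation = simulation, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

cfg_filter <- function(config) do.call(filter_config, config$filter)

cfg_panel <- function(config) {
  if (is.null(config$panel)) cagp_panel() else read_gene_panel(config$panel)
}

cfg_say <- function(config, fmt, ...) {
  if (config$verbose) message(sprintf(fmt, ...))
}

out_path <- function(config, name) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$out_dir, name)
}

#' Run the pipeline stages from a configuration
#'
#' File-based stage commands mirroring the three-step analysis:
#' `run_simulate()` writes a synthetic cohort (`simulated_calls.tsv`)
#' and its generation truth (`simulated_truth.json`); `run_filter()`
#' applies stage-1 and cohort-recurrence filtration plus
#' categorisation, writing exome-wide and panel-restricted retained
#' calls, the filter report and both count matrices; `run_burden()`
#' writes the exome- and panel-wide burden tables; `run_recurrence()`
#' writes PDAV records, gene-level recurrence with candidate flags, and
#' the cohort PDAV summary. Each command logs the thresholds it
#' applies and returns the written paths invisibly; re-running
#' overwrites outputs identically.
#'
#' @param config a [pipeline_config]
#' @return named character vector of output paths, invisibly
#' @export
run_simulate <- function(config) {
  sim_args <- config$simulation
  if (is.null(sim_args$seed)) sim_args$seed <- config$seed
  params <- do.call(sim_params, sim_args)
  cfg_say(config, "simulate: %d cases, %d controls, seed %d",
          params$n_cases, params$n_controls, params$seed)
  sim <- simulate_cohort(params, cfg_panel(config))
  calls_path <- out_path(config, "simulated_calls.tsv")
  write_calls(sim$cohort, calls_path)
  truth_path <- out_path(config, "simulated_truth.json")
  truth <- sim$truth
  truth$counts <- as.data.frame(truth$counts)
  truth$panel_counts <- as.data.frame(truth$panel_counts)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(calls = calls_path, truth = truth_path))
}

#' @rdname run_simulate
#' @export
run_filter <- function(config) {
  if (is.null(config$calls))
    config$calls <- out_path(config, "simulated_calls.tsv")
  if (!file.exists(config$calls))
    stop("calls file not found: ", config$calls)
  fc <- cfg_filter(config)
  cfg_say(config,
          "filter: depth>=%d alt>=%d vaf[%.2f,%.2f] maf<=%.3g recurrence>%.2f",
          fc$min_depth, fc$min_alt_reads, fc$vaf_min, fc$vaf_max,
          fc$max_maf, fc$cohort_recurrence_threshold)
  cohort <- read_calls(config$calls)
  panel <- cfg_panel(config)
  res <- analyze_cohort(cohort, fc, panel = panel)
  paths <- c(
    report = out_path(config, "filter_report.json"),
    exome_counts = out_path(config, "counts_exome.tsv"),
    panel_counts = out_path(config, "counts_panel.tsv"))
  rpt <- res$stage1_report
  jsonlite::write_json(
    list(input = rpt$input, retained = rpt$retained,
         rejections = as.list(rpt$rejections),
         cohort_recurrence_removed_variants = nrow(res$recurrence_removed)),
    paths[["report"]], auto_unbox = TRUE, digits = NA)
  write_count_matrix(res$exome$counts, paths[["exome_counts"]])
  write_count_matrix(res$panel$counts, paths[["panel_counts"]])
  cfg_say(config, "filter: %d calls in, %d retained after stage 1",
          rpt$input, rpt$retained)
  invisible(paths)
}

#' @rdname run_simulate
#' @export
run_burden <- function(config) {
  paths <- character(0)
  for (scope in c("exome", "panel")) {
    cm_path <- out_path(config, sprintf("counts_%s.tsv", scope))
    if (!file.exists(cm_path))
      stop("count matrix not found (run run_filter first): ", cm_path)
    br <- burden_report(read_count_matrix(cm_path))
    p <- out_path(config, sprintf("burden_%s.tsv", scope))
    write_burden(br, p)
    paths[[scope]] <- p
    cfg_say(config, "burden (%s): %d categories", scope, nrow(br))
  }
  invisible(paths)
}

#' @rdname run_simulate
#' @export
run_recurrence <- function(config) {
  if (is.null(config$calls))
    config$calls <- out_path(config, "simulated_calls.tsv")
  fc <- cfg_filter(config)
  cohort <- read_calls(config$calls)
  panel <- cfg_panel(config)
  res <- analyze_cohort(cohort, fc, panel = panel)
  rec <- do.call(select_candidates,
                 c(list(gene_pdav_carriers(res$panel$pdavs)),
                   config$recurrence))
  paths <- c(pdavs = out_path(config, "pdavs.tsv"),
             recurrence = out_path(config, "gene_recurrence.tsv"),
             summary = out_path(config, "pdav_summary.json"))
  write_pdavs(res$panel$pdavs, paths[["pdavs"]])
  write_pdavs(rec, paths[["recurrence"]])
  s <- res$panel$summary
  jsonlite::write_json(
    list(n_records = s$n_records,
         n_distinct_patients = s$n_distinct_patients,
         n_distinct_genes = s$n_distinct_genes,
         n_novel = s$n_novel, n_splice_site = s$n_splice_site,
         genes_with_control_carriers = s$genes_with_control_carriers,
         patients_by_gene_count = as.list(s$patients_by_gene_count)),
    paths[["summary"]], auto_unbox = TRUE, digits = NA)
  cfg_say(config, "recurrence: %d genes, %d candidates",
          nrow(rec), sum(rec$candidate))
  invisible(paths)
}
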