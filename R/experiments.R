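#' End-to-end pipeline on a cohort table
#'
#' Runs the three filtration stages (per-call stage-1 filter,
#' cohort-recurrence removal, categorisation), optionally restricts to
#' a gene panel, then builds the count matrix and burden report, and —
#' when a panel is given — extracts PDAV records with their gene-level
#' recurrence and cohort summary.
#'
#' @param cohort a [cohort_table]
#' @param config a [filter_config]
#' @param panel optional [gene_panel]; when supplied, panel-wide
#'   results are included
#' @return list with `stage1_report`, `recurrence_removed`,
#'   `exome$counts`/`exome$burden`, and when a panel is given
#'   `panel$counts`, `panel$burden`, `panel$pdavs`,
#'   `panel$recurrence`, `panel$summary`
#' @export
analyze_cohort <- function(cohort, config = filter_config(),
                           panel = NULL) {
  s1 <- stage1_filter(cohort, config)
  rec <- cohort_recurrence_filter(s1$retained,
                                  config$cohort_recurrence_threshold)
  categorised <- categorize(rec$retained, config)
  exome_counts <- count_by_sample_category(categorised)
  out <- list(stage1_report = s1$report,
              recurrence_removed = rec$removed,
              exome = list(counts = exome_counts,
                           burden = burden_report(exome_counts)))
  if (!is.null(panel)) {
    on_panel <- restrict_to_panel(categorised, panel)
    panel_counts <- count_by_sample_category(on_panel)
    pdavs <- extract_pdavs(on_panel)
    out$panel <- list(counts = panel_counts,
                      burden = burden_report(panel_counts),
                      pdavs = pdavs,
                      recurrence = select_candidates(
                        gene_pdav_carriers(pdavs)),
                      summary = pdav_summary(pdavs))
  }
  out
}

#' Type-I error of the burden t-test under the null
#'
#' Simulates `n_reps` null cohorts (identical case and control rates),
#' runs the full filtration-and-burden pipeline on each, and returns
#' the fraction of replicates whose Student t-test p-value for
#' `category` falls below `alpha`. For a calibrated test this fraction
#' should sit within Monte-Carlo error of `alpha`.
#'
#' @param n_reps number of null replicates (default 500)
#' @param params a [sim_params]; enrichment factors are forced to 1
#' @param alpha nominal level (default 0.05)
#' @param category count-matrix column to test (default `"all"`)
#' @param seed master seed; replicate r uses stream seeds derived from
#'   `seed + 2r`
#' @return list with `rejection_rate`, `mc_se` (binomial Monte-Carlo
#'   standard error at `alpha`), `n_reps`, `alpha`
#' @export
typeI_error_rate <- function(n_reps = 500L,
                             params = sim_params(panel_only = TRUE),
                             alpha = 0.05, category = "all",
                             seed = 1L) {
  panel <- cagp_panel()
  config <- filter_config()
  reject <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    params$case_seed <- seed + 2L * r
    params$control_seed <- seed + 2L * r + 1L
    sim <- simulate_null(params, panel)
    res <- analyze_cohort(sim$cohort, config)
    p <- res$exome$burden$p_student[res$exome$burden$category == category]
    reject[r] <- !is.na(p) && p < alpha
  }
  list(rejection_rate = mean(reject),
       mc_se = sqrt(alpha * (1 - alpha) / n_reps),
       n_reps = n_reps, alpha = alpha)
}

#' Recovery of an injected panel enrichment factor
#'
#' Simulates `n_reps` cohorts under `params` (by default carrying the
#' single injected signal, a panel-nonsense case enrichment), runs the
#' full pipeline with panel restriction on each, and summarises how
#' well the case/control fold-change for `category` recovers the
#' injected factor. Two estimates are returned: `ratio_pooled`, the
#' ratio of the Monte-Carlo means of the group means (the consistent
#' estimate of the injected factor), and `ratio_mean_of_reps`, the
#' average of the per-replicate fold-changes (upward-biased by roughly
#' the reciprocal of the expected control-group total when that total
#' is small).
#'
#' @param n_reps number of replicates (default 500)
#' @param params a [sim_params]
#' @param category count-matrix column whose ratio is tracked
#'   (default `"nonsense"`)
#' @param seed master seed, per-replicate streams as in
#'   [typeI_error_rate()]
#' @return list with `ratio_pooled`, `ratio_mean_of_reps`, `truth`
#'   (the injected factor for `category`), `n_reps`
#' @export
enrichment_recovery <- function(n_reps = 500L,
                                params = sim_params(panel_only = TRUE),
                                category = "nonsense",
                                seed = 1L) {
  panel <- cagp_panel()
  config <- filter_config()
  mean_case <- mean_ctrl <- ratio <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    params$case_seed <- seed + 2L * r
    params$control_seed <- seed + 2L * r + 1L
    sim <- simulate_cohort(params, panel)
    res <- analyze_cohort(sim$cohort, config, panel = panel)
    row <- res$panel$burden[res$panel$burden$category == category, ]
    mean_case[r] <- row$mean_case
    mean_ctrl[r] <- row$mean_control
    ratio[r] <- row$ratio
  }
  list(ratio_pooled = mean(mean_case) / mean(mean_ctrl),
       ratio_mean_of_reps = mean(ratio, na.rm = TRUE),
       truth = unname(params$case_enrichment_panel[[category]]),
       n_reps = n_reps)
}
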