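#' Simulation parameters for synthetic case/control exome cohorts
#'
#' Defaults describe a cohort of 54 cases and 120 controls whose
#' per-sample retained-variant means match the published control-group
#' summaries, exome-wide and panel-wide, with a single injected signal:
#' a 2.39-fold enrichment of panel nonsense variants in cases. Counts
#' are Poisson per sample and category (negative-binomial when
#' `nb_size` is set); sequencing noise enters through a Poisson depth
#' around `depth_mean` (matching ~100x mean target coverage) and
#' binomial alt-read support around a heterozygous 0.5.
#'
#' A fraction `artifact_fraction` of generated calls is injected
#' violating exactly one stage-1 criterion each (failed VQSLOD,
#' intronic location, shallow depth, out-of-range allele fraction, or a
#' common population MAF), and `recurrent_artifact_count` variants are
#' planted in more than `recurrent_carrier_fraction` of both groups so
#' the cohort-recurrence filter has true targets. Cases and controls
#' are generated from two independent seeded streams.
#'
#' @param n_cases,n_controls cohort sizes (defaults 54 and 120)
#' @param exome_rates named numeric: expected retained variants per
#'   sample per category, exome-wide, in the control group
#' @param panel_rates same, restricted to panel genes; must be
#'   elementwise at most `exome_rates`
#' @param case_enrichment_panel named numeric: multiplicative case-rate
#'   factor for the panel compartment (default: nonsense 2.39, rest 1)
#' @param case_enrichment_exome same for the off-panel compartment
#'   (default all 1)
#' @param artifact_fraction fraction of all generated calls that are
#'   single-violation artifacts (default 0.10)
#' @param recurrent_artifact_count variants planted in both groups
#'   above the recurrence threshold (default 5)
#' @param recurrent_carrier_fraction carrier fraction of the planted
#'   recurrent variants (default 0.15, above the 0.10 removal
#'   threshold)
#' @param depth_mean mean sequencing depth at variant positions
#'   (default 100)
#' @param maf_reported_fraction probability a clean variant carries a
#'   (rare) database frequency rather than being unreported
#'   (default 0.5)
#' @param dbsnp_fraction probability a clean variant has a dbSNP id
#'   (default 0.5)
#' @param panel_only zero the off-panel rates, simulating only the
#'   panel compartment (default FALSE)
#' @param nb_size optional negative-binomial size parameter for
#'   overdispersed counts; NULL (default) = Poisson
#' @param seed integer master seed; `case_seed`/`control_seed`
#'   override the derived per-group stream seeds
#' @param case_seed,control_seed optional explicit group stream seeds
#' @return an object of class `sim_params`
#' @export
sim_params <- function(n_cases = 54L,
                       n_controls = 120L,
                       exome_rates = default_exome_rates(),
                       panel_rates = default_panel_rates(),
                       case_enrichment_panel = c(nonsense = 2.39),
                       case_enrichment_exome = numeric(0),
                       artifact_fraction = 0.10,
                       recurrent_artifact_count = 5L,
                       recurrent_carrier_fraction = 0.15,
                       depth_mean = 100,
                       maf_reported_fraction = 0.5,
                       dbsnp_fraction = 0.5,
                       panel_only = FALSE,
                       nb_size = NULL,
                       seed = 1L,
                       case_seed = NULL,
                       control_seed = NULL) {
  full <- function(x) {
    out <- stats::setNames(rep(0, length(CATEGORIES)), CATEGORIES)
    out[names(x)] <- x
    out
  }
  ones <- function(x) {
    out <- stats::setNames(rep(1, length(CATEGORIES)), CATEGORIES)
    out[names(x)] <- x
    out
  }
  p <- list(n_cases = as.integer(n_cases),
            n_controls = as.integer(n_controls),
            exome_rates = full(exome_rates),
            panel_rates = full(panel_rates),
            case_enrichment_panel = ones(case_enrichment_panel),
            case_enrichment_exome = ones(case_enrichment_exome),
            artifact_fraction = artifact_fraction,
            recurrent_artifact_count = as.integer(recurrent_artifact_count),
            recurrent_carrier_fraction = recurrent_carrier_fraction,
            depth_mean = depth_mean,
            maf_reported_fraction = maf_reported_fraction,
            dbsnp_fraction = dbsnp_fraction,
            panel_only = isTRUE(panel_only),
            nb_size = nb_size,
            seed = as.integer(seed),
            case_seed = if (is.null(case_seed)) as.integer(seed)
                        else as.integer(case_seed),
            control_seed = if (is.null(control_seed))
                             as.integer(seed) + 1000003L
                           else as.integer(control_seed))
  if (any(p$exome_rates < 0) || any(p$panel_rates < 0))
    stop("rates must be non-negative")
  if (any(p$panel_rates > p$exome_rates + 1e-9))
    stop("panel_rates cannot exceed exome_rates")
  if (any(p$case_enrichment_panel <= 0) || any(p$case_enrichment_exome <= 0))
    stop("enrichment factors must be positive")
  if (p$artifact_fraction < 0 || p$artifact_fraction >= 1)
    stop("artifact_fraction must lie in [0, 1)")
  if (p$recurrent_carrier_fraction < 0 || p$recurrent_carrier_fraction > 1)
    stop("recurrent_carrier_fraction must lie in [0, 1]")
  if (p$n_cases < 1 || p$n_controls < 1) stop("empty group")
  structure(p, class = "sim_params")
}

# control-group per-sample retained-variant means, exome-wide
default_exome_rates <- function() {
  c(synonymous = 149.09, inframe_indel = 8.18, frameshift_indel = 8.77,
    splice_site = 3.50, nonsense = 6.40, missense_probably = 99.41,
    missense_possibly = 43.31, missense_benign = 108.18)
}

# same, within the 492-gene panel (group totals / 120 controls)
default_panel_rates <- function() {
  c(synonymous = 589, inframe_indel = 21, frameshift_indel = 23,
    splice_site = 20, nonsense = 13, missense_probably = 398,
    missense_possibly = 174, missense_benign = 417) / 120
}

#' Simulate a case/control cohort of annotated variant calls
#'
#' Draws per-sample per-category clean-call counts from the group- and
#' compartment-adjusted rates, materialises each call with coordinates
#' uniform within gene intervals (panel genes for the panel
#' compartment, a fixed synthetic off-panel gene set otherwise), depth
#' and alt-read noise, a mostly-unreported rare MAF, and passing
#' VQSLOD. Injected artifacts each violate exactly one stage-1
#' criterion; planted recurrent variants exceed the removal threshold
#' in both groups. Fully reproducible from the seeds in `params`.
#'
#' @param params a [sim_params]
#' @param panel a [gene_panel] supplying the panel compartment's genes
#'   (default: the packaged CAGP)
#' @return list of class `simulated_cohort`: `cohort` (a
#'   [cohort_table]) and `truth` (per-sample clean category counts
#'   `counts` and `panel_counts`, `artifact_keys`, `recurrent_keys`,
#'   and the effective `rates` by group and compartment)
#' @examples
#' sim <- simulate_cohort(sim_params(n_cases = 5, n_controls = 5,
#'                                   panel_only = TRUE, seed = 7))
#' sim$cohort
#' @export
simulate_cohort <- function(params = sim_params(), panel = cagp_panel()) {
  stopifnot(inherits(params, "sim_params"), inherits(panel, "gene_panel"))
  panel_tbl <- gene_interval_table(panel)
  off_tbl <- offpanel_gene_table()
  n_rec_case <- ceiling(params$recurrent_carrier_fraction * params$n_cases)
  n_rec_ctrl <- ceiling(params$recurrent_carrier_fraction * params$n_controls)
  if (params$recurrent_artifact_count > 0 &&
      (n_rec_case > params$n_cases || n_rec_ctrl > params$n_controls))
    stop("recurrent artifact carriers exceed cohort size")

  gen <- function(group) {
    is_case <- group == "case"
    n <- if (is_case) params$n_cases else params$n_controls
    ids <- sprintf(if (is_case) "BC%03d" else "CT%03d", seq_len(n))
    set.seed(if (is_case) params$case_seed else params$control_seed)
    rates_panel <- params$panel_rates *
      (if (is_case) params$case_enrichment_panel else 1)
    rates_off <- pmax(params$exome_rates - params$panel_rates, 0) *
      (if (is_case) params$case_enrichment_exome else 1)
    if (params$panel_only) rates_off[] <- 0
    panel_part <- draw_clean_calls(ids, rates_panel, panel_tbl, params)
    off_part <- draw_clean_calls(ids, rates_off, off_tbl, params)
    n_clean <- nrow(panel_part$calls) + nrow(off_part$calls)
    n_art <- round(params$artifact_fraction / (1 - params$artifact_fraction) *
                     n_clean)
    art_tbl <- if (params$panel_only) panel_tbl else off_tbl
    art <- draw_artifact_calls(ids, n_art, art_tbl, params,
                               rates_panel + rates_off)
    rec <- draw_recurrent_calls(ids,
                                if (is_case) n_rec_case else n_rec_ctrl,
                                params)
    list(calls = rbind(panel_part$calls, off_part$calls, art$calls,
                       rec$calls),
         counts = panel_part$counts + off_part$counts,
         panel_counts = panel_part$counts,
         artifact_keys = art$keys, recurrent_keys = rec$keys,
         ids = ids, group = group,
         rates = list(panel = rates_panel, offpanel = rates_off))
  }
  case <- gen("case")
  ctrl <- gen("control")
  calls <- rbind(case$calls, ctrl$calls)
  calls <- resolve_position_clashes(calls)
  samples <- data.frame(sample_id = c(case$ids, ctrl$ids),
                        group = rep(c("case", "control"),
                                    c(length(case$ids), length(ctrl$ids))),
                        stringsAsFactors = FALSE)
  ord <- order(calls$sample_id, calls$chrom, calls$pos, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  interval_cols <- c(".iv_start", ".iv_width")
  cohort <- cohort_table(calls[, setdiff(names(calls), interval_cols)],
                         samples)
  truth <- list(counts = rbind(case$counts, ctrl$counts),
                panel_counts = rbind(case$panel_counts, ctrl$panel_counts),
                artifact_keys = c(case$artifact_keys, ctrl$artifact_keys),
                recurrent_keys = unique(c(case$recurrent_keys,
                                          ctrl$recurrent_keys)),
                rates = list(case = case$rates, control = ctrl$rates))
  structure(list(cohort = cohort, truth = truth),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort\n")
  print(x$cohort)
  cat(sprintf("  clean calls: %d | artifact calls: %d | recurrent variants: %d\n",
              sum(x$truth$counts),
              length(x$truth$artifact_keys),
              length(x$truth$recurrent_keys)))
  invisible(x)
}

#' Simulate a null cohort (no case/control difference)
#'
#' [simulate_cohort()] with every enrichment factor forced to 1: case
#' and control rates identical per category. The type-I-error harness
#' for the burden tests.
#'
#' @inheritParams simulate_cohort
#' @return as [simulate_cohort()]
#' @export
simulate_null <- function(params = sim_params(), panel = cagp_panel()) {
  params$case_enrichment_panel[] <- 1
  params$case_enrichment_exome[] <- 1
  simulate_cohort(params, panel)
}

# one interval row per gene (first interval): gene, chrom, start, width
gene_interval_table <- function(panel) {
  iv <- panel$intervals[!duplicated(panel$intervals$gene), , drop = FALSE]
  data.frame(gene = iv$gene, chrom = iv$chrom, start = iv$start,
             width = iv$end - iv$start, stringsAsFactors = FALSE)
}

# fixed synthetic off-panel gene set, far from the panel's coordinates
offpanel_gene_table <- function(n_genes = 400L) {
  i <- seq_len(n_genes)
  data.frame(gene = sprintf("NPG%04d", i),
             chrom = sprintf("chr%d", (i - 1L) %% 22L + 1L),
             start = 60e6 + ((i - 1L) %/% 22L) * 1e5,
             width = 5e4,
             stringsAsFactors = FALSE)
}

BASES <- c("A", "C", "G", "T")

# clean calls for one group/compartment; counts matrix is the truth
draw_clean_calls <- function(ids, rates, gene_tbl, params) {
  n <- length(ids)
  counts <- matrix(0L, nrow = n, ncol = length(CATEGORIES),
                   dimnames = list(ids, CATEGORIES))
  for (cat in CATEGORIES) {
    lam <- rates[[cat]]
    if (lam <= 0) next
    counts[, cat] <- if (is.null(params$nb_size))
      stats::rpois(n, lam)
    else
      stats::rnbinom(n, mu = lam, size = params$nb_size)
  }
  total <- sum(counts)
  if (total == 0)
    return(list(calls = empty_sim_calls(), counts = counts))
  sample_id <- rep(rep(ids, ncol(counts)), as.vector(counts))
  category <- rep(rep(CATEGORIES, each = n), as.vector(counts))
  g <- sample.int(nrow(gene_tbl), total, replace = TRUE)
  pos <- gene_tbl$start[g] + sample.int(max(gene_tbl$width), total,
                                        replace = TRUE) %% gene_tbl$width[g] + 1L
  alleles <- draw_alleles(category)
  depth <- pmax(stats::rpois(total, params$depth_mean), 10L)
  alt_reads <- clamp_alt_reads(stats::rbinom(total, depth, 0.5), depth)
  maf <- rep(NA_character_, total)
  rep_maf <- stats::runif(total) < params$maf_reported_fraction
  maf[rep_maf] <- sprintf("popdb:%.6g", stats::runif(sum(rep_maf), 0, 0.01))
  dbsnp <- rep(NA_character_, total)
  has_rs <- stats::runif(total) < params$dbsnp_fraction
  dbsnp[has_rs] <- sprintf("rs%09d",
                           sample.int(999999999L, sum(has_rs), replace = TRUE))
  ann <- category_annotation(category)
  calls <- data.frame(sample_id = sample_id,
                      chrom = gene_tbl$chrom[g], pos = as.integer(pos),
                      ref = alleles$ref, alt = alleles$alt,
                      gene = gene_tbl$gene[g],
                      region = ann$region, func = ann$func,
                      depth = depth, alt_reads = alt_reads,
                      vqslod_pass = TRUE, maf = maf,
                      pph2_hdiv = ann$pph2, dbsnp_id = dbsnp,
                      .iv_start = gene_tbl$start[g],
                      .iv_width = gene_tbl$width[g],
                      stringsAsFactors = FALSE)
  list(calls = calls, counts = counts)
}

empty_sim_calls <- function() {
  data.frame(sample_id = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             gene = character(), region = character(), func = character(),
             depth = integer(), alt_reads = integer(),
             vqslod_pass = logical(), maf = character(),
             pph2_hdiv = numeric(), dbsnp_id = character(),
             .iv_start = numeric(), .iv_width = numeric(),
             stringsAsFactors = FALSE)
}

clamp_alt_reads <- function(alt, depth) {
  lo <- pmax(2L, as.integer(ceiling(0.2 * depth)))
  hi <- as.integer(floor(0.8 * depth))
  pmin(pmax(alt, lo), hi)
}

draw_alleles <- function(category) {
  total <- length(category)
  ref1 <- BASES[sample.int(4L, total, replace = TRUE)]
  shift <- sample.int(3L, total, replace = TRUE)
  alt1 <- BASES[(match(ref1, BASES) - 1L + shift) %% 4L + 1L]
  ref <- ref1
  alt <- alt1
  fs <- category == "frameshift_indel"
  ref[fs] <- paste0(ref1[fs], alt1[fs])       # 1 bp deletion
  alt[fs] <- ref1[fs]
  inf <- category == "inframe_indel"
  ref[inf] <- paste0(ref1[inf], alt1[inf], ref1[inf], alt1[inf])  # 3 bp
  alt[inf] <- ref1[inf]
  list(ref = ref, alt = alt)
}

# region / func / pph2 consistent with the target category
category_annotation <- function(category) {
  n <- length(category)
  region <- rep("exonic", n)
  region[category == "splice_site"] <- "splice_site"
  func <- rep("other", n)
  func[category == "synonymous"] <- "synonymous"
  func[category == "inframe_indel"] <- "inframe_indel"
  func[category == "frameshift_indel"] <- "frameshift_indel"
  func[category == "splice_site"] <- "splice_site_snv"
  func[category == "nonsense"] <- "nonsense"
  func[category == "stop_loss"] <- "stop_loss"
  func[startsWith(category, "missense")] <- "missense"
  pph2 <- rep(NA_real_, n)
  i <- category == "missense_probably"
  pph2[i] <- stats::runif(sum(i), 0.957, 1)
  i <- category == "missense_possibly"
  pph2[i] <- stats::runif(sum(i), 0.453, 0.956)
  i <- category == "missense_benign"
  pph2[i] <- stats::runif(sum(i), 0, 0.452)
  list(region = region, func = func, pph2 = pph2)
}

# artifact calls: each violates exactly one stage-1 criterion
ARTIFACT_MODES <- c("vqslod", "region", "depth", "vaf", "maf")

draw_artifact_calls <- function(ids, n_art, gene_tbl, params, rates) {
  if (n_art == 0)
    return(list(calls = empty_sim_calls(), keys = character(0)))
  categories <- if (sum(rates) > 0)
    sample(CATEGORIES, n_art, replace = TRUE, prob = rates)
  else rep("synonymous", n_art)
  sample_id <- ids[sample.int(length(ids), n_art, replace = TRUE)]
  g <- sample.int(nrow(gene_tbl), n_art, replace = TRUE)
  pos <- gene_tbl$start[g] + sample.int(max(gene_tbl$width), n_art,
                                        replace = TRUE) %% gene_tbl$width[g] + 1L
  alleles <- draw_alleles(categories)
  ann <- category_annotation(categories)
  depth <- pmax(stats::rpois(n_art, params$depth_mean), 10L)
  alt_reads <- clamp_alt_reads(stats::rbinom(n_art, depth, 0.5), depth)
  maf <- rep(NA_character_, n_art)
  vqslod <- rep(TRUE, n_art)
  mode <- ARTIFACT_MODES[sample.int(length(ARTIFACT_MODES), n_art,
                                    replace = TRUE)]
  vqslod[mode == "vqslod"] <- FALSE
  ann$region[mode == "region"] <- "intronic"
  i <- mode == "depth"     # shallow but otherwise supported: 5..9 reads
  depth[i] <- 5L + (sample.int(5L, sum(i), replace = TRUE) - 1L)
  alt_reads[i] <- clamp_alt_reads(stats::rbinom(sum(i), depth[i], 0.5),
                                  depth[i])
  i <- mode == "vaf"       # deep site, 10% allele fraction
  depth[i] <- pmax(stats::rpois(sum(i), params$depth_mean), 50L)
  alt_reads[i] <- pmax(2L, as.integer(round(0.10 * depth[i])))
  i <- mode == "maf"       # common variant missed upstream
  maf[i] <- sprintf("popdb:%.6g", stats::runif(sum(i), 0.02, 0.5))
  calls <- data.frame(sample_id = sample_id,
                      chrom = gene_tbl$chrom[g], pos = as.integer(pos),
                      ref = alleles$ref, alt = alleles$alt,
                      gene = gene_tbl$gene[g],
                      region = ann$region, func = ann$func,
                      depth = depth, alt_reads = alt_reads,
                      vqslod_pass = vqslod, maf = maf,
                      pph2_hdiv = ann$pph2,
                      dbsnp_id = NA_character_,
                      .iv_start = gene_tbl$start[g],
                      .iv_width = gene_tbl$width[g],
                      stringsAsFactors = FALSE)
  list(calls = calls,
       keys = paste(calls$sample_id,
                    variant_key(calls), sep = "@"))
}

# planted cohort-recurrent variants (clean per-call attributes, fixed
# coordinates shared across carriers in both groups)
draw_recurrent_calls <- function(ids, n_carriers, params) {
  k <- params$recurrent_artifact_count
  if (k == 0 || n_carriers == 0)
    return(list(calls = empty_sim_calls(), keys = character(0)))
  carriers <- lapply(seq_len(k), function(j)
    ids[sample.int(length(ids), n_carriers)])
  per_var <- lengths(carriers)
  sample_id <- unlist(carriers)
  pos <- rep(90e6 + seq_len(k), per_var)
  total <- length(sample_id)
  depth <- pmax(stats::rpois(total, params$depth_mean), 10L)
  alt_reads <- clamp_alt_reads(stats::rbinom(total, depth, 0.5), depth)
  calls <- data.frame(sample_id = sample_id,
                      chrom = "chr1", pos = as.integer(pos),
                      ref = "A", alt = "T",
                      gene = rep(sprintf("RECART%02d", seq_len(k)), per_var),
                      region = "exonic", func = "synonymous",
                      depth = depth, alt_reads = alt_reads,
                      vqslod_pass = TRUE, maf = NA_character_,
                      pph2_hdiv = NA_real_, dbsnp_id = NA_character_,
                      .iv_start = 90e6, .iv_width = 1,
                      stringsAsFactors = FALSE)
  list(calls = calls,
       keys = unique(variant_key(calls)))
}

# deterministically nudge positions until no (sample, variant) tuple
# repeats; recurrent variants (width-1 intervals) are never nudged
resolve_position_clashes <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  for (round in 1:100) {
    dup <- duplicated(variant_key(calls, with_sample = TRUE)) &
      calls$.iv_width > 1
    if (!any(dup)) return(calls)
    calls$pos[dup] <- as.integer(
      calls$.iv_start[dup] +
        (calls$pos[dup] - calls$.iv_start[dup]) %% calls$.iv_width[dup] + 1L)
  }
  stop("could not resolve duplicate variant positions")
}
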