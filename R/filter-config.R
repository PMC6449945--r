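#' Filtration thresholds
#'
#' Bundles every threshold of the three-stage filtration with the
#' published analysis values as defaults: calls must pass VQSLOD
#' recalibration, lie in an exon or within `splice_window` bp of an
#' exon-intron border, reach `min_depth` total reads and
#' `min_alt_reads` variant-supporting reads, show a variant allele
#' fraction inside \[`vaf_min`, `vaf_max`\], and have every reported
#' population MAF at or below `max_maf`. Variants carried by more than
#' `cohort_recurrence_threshold` of samples in both groups are removed
#' as artifacts. Missense calls are triaged on the PolyPhen-2 HDIV
#' probability: probably damaging at or above `pph2_probably_min`,
#' benign at or below `pph2_benign_max`, possibly damaging in between.
#'
#' All retention comparisons at the stated bounds are inclusive;
#' cohort-recurrence removal is strict (`>`).
#'
#' @param min_depth minimum total read depth (default 10)
#' @param min_alt_reads minimum variant-supporting reads (default 2)
#' @param vaf_min,vaf_max retained variant-allele-fraction range
#'   (defaults 0.20, 0.80)
#' @param max_maf maximum population minor allele frequency (default
#'   0.01); a variant absent from every database counts as MAF 0
#' @param splice_window bp around the exon-intron border called
#'   splice-site (default 2)
#' @param cohort_recurrence_threshold carrier fraction above which a
#'   variant seen in both groups is treated as an artifact (default 0.10)
#' @param pph2_probably_min,pph2_benign_max PolyPhen-2 HDIV class
#'   boundaries (defaults 0.957 and 0.452)
#' @return an object of class `filter_config`
#' @export
filter_config <- function(min_depth = 10L,
                          min_alt_reads = 2L,
                          vaf_min = 0.20,
                          vaf_max = 0.80,
                          max_maf = 0.01,
                          splice_window = 2L,
                          cohort_recurrence_threshold = 0.10,
                          pph2_probably_min = 0.957,
                          pph2_benign_max = 0.452) {
  cfg <- list(min_depth = as.integer(min_depth),
              min_alt_reads = as.integer(min_alt_reads),
              vaf_min = vaf_min, vaf_max = vaf_max,
              max_maf = max_maf,
              splice_window = as.integer(splice_window),
              cohort_recurrence_threshold = cohort_recurrence_threshold,
              pph2_probably_min = pph2_probably_min,
              pph2_benign_max = pph2_benign_max)
  stopifnot(cfg$min_depth >= 0, cfg$min_alt_reads >= 0,
            cfg$splice_window >= 0)
  if (!(0 <= cfg$vaf_min && cfg$vaf_min < cfg$vaf_max && cfg$vaf_max <= 1))
    stop("need 0 <= vaf_min < vaf_max <= 1")
  if (!(0 < cfg$max_maf && cfg$max_maf < 1))
    stop("need 0 < max_maf < 1")
  if (!(cfg$cohort_recurrence_threshold > 0))
    stop("cohort_recurrence_threshold must be positive")
  if (!(cfg$pph2_benign_max < cfg$pph2_probably_min))
    stop("need pph2_benign_max < pph2_probably_min")
  structure(cfg, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("filter_config:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
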