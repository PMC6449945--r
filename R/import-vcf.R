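#' Import a multi-sample VCF plus an annotation table
#'
#' Converts a VCF 4.x file into the canonical cohort representation:
#' one annotated call per non-reference genotype allele per sample.
#' Multiallelic records are split into biallelic calls before
#' annotation lookup; a genotype carrying two different alt alleles
#' yields two calls. Per-sample depth comes from the `DP` FORMAT field
#' and alt support from the allele's `AD` entry (0 when absent).
#' `vqslod_pass` is derived from the FILTER column: `PASS` (or `.`)
#' passes, anything else — e.g. a VQSR tranche label — fails.
#'
#' The annotation table is keyed by (chrom, pos, ref, alt) and supplies
#' `gene`, `region`, `func`, `maf`, `pph2_hdiv`, `dbsnp_id` (same
#' encodings as the canonical TSV). A VCF variant with no annotation
#' row is imported with `func = "other"`, `region = "other"` and a
#' warning.
#'
#' @param vcf_path path to a VCF file (plain or bgzipped)
#' @param annotation_path path to the annotation TSV
#' @param group_map named character vector or two-column data.frame
#'   (`sample_id`, `group`) assigning every VCF sample to
#'   case/control/excluded
#' @return a [cohort_table]
#' @export
import_vcf <- function(vcf_path, annotation_path, group_map) {
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path)
  if (is.data.frame(group_map))
    group_map <- stats::setNames(as.character(group_map$group),
                                 group_map$sample_id)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  vcf_samples <- colnames(gt)
  missing <- setdiff(vcf_samples, names(group_map))
  if (length(missing))
    stop("sample(s) absent from group map: ", toString(missing))
  ann <- read_annotation_table(annotation_path)
  rows <- list()
  unannotated <- character(0)
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    pass <- is.na(fix[i, "FILTER"]) ||
      fix[i, "FILTER"] %in% c("PASS", ".")
    for (s in vcf_samples) {
      g <- gt[i, s]
      if (is.na(g)) next
      alleles <- strsplit(g, "[/|]")[[1]]
      carried <- sort(unique(suppressWarnings(as.integer(alleles))))
      carried <- carried[!is.na(carried) & carried > 0]
      if (!length(carried)) next
      ads <- suppressWarnings(
        as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
      for (a in carried) {
        key <- paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"],
                     alts[a], sep = ":")
        arow <- ann[match(key, ann$key), , drop = FALSE]
        if (is.na(arow$key[1])) {
          unannotated <- c(unannotated, key)
          arow <- data.frame(gene = NA_character_, region = "other",
                             func = "other", maf = NA_character_,
                             pph2_hdiv = NA_real_,
                             dbsnp_id = NA_character_)
        }
        depth <- if (!is.null(dim(dp)) && !is.na(dp[i, s]))
          as.integer(dp[i, s]) else sum(ads, na.rm = TRUE)
        alt_reads <- if (length(ads) > a && !is.na(ads[a + 1]))
          ads[a + 1] else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, chrom = fix[i, "CHROM"],
          pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[a],
          gene = arow$gene, region = arow$region, func = arow$func,
          depth = depth, alt_reads = alt_reads,
          vqslod_pass = pass, maf = arow$maf,
          pph2_hdiv = arow$pph2_hdiv, dbsnp_id = arow$dbsnp_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(unannotated))
    warning("no annotation for ", length(unique(unannotated)),
            " variant(s): ", toString(utils::head(unique(unannotated), 3)),
            if (length(unique(unannotated)) > 3) ", ..." else "")
  calls <- if (length(rows)) do.call(rbind, rows) else
    empty_sim_calls()[, CALL_COLUMNS]
  cohort_table(calls,
               data.frame(sample_id = vcf_samples,
                          group = unname(group_map[vcf_samples]),
                          stringsAsFactors = FALSE))
}

read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           na.strings = NULL, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "region", "func",
            "maf", "pph2_hdiv", "dbsnp_id")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop(path, ": lacks column(s): ", toString(missing))
  tab$key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  tab$gene <- dot_to_na(tab$gene)
  tab$maf <- dot_to_na(tab$maf)
  tab$dbsnp_id <- dot_to_na(tab$dbsnp_id)
  tab$pph2_hdiv <- suppressWarnings(as.numeric(dot_to_na(tab$pph2_hdiv)))
  tab
}
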