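#' Classify positions relative to an exon model
#'
#' A position is `exonic` if it falls inside an exon, `splice_site` if
#' it lies within `window` bases outside an exon boundary (the
#' exon-intron border), `intronic` if it falls between two exons of the
#' model on the same chromosome, and `intergenic` otherwise.
#'
#' @param chrom,pos chromosome and 1-based position vectors (recycled)
#' @param exon_model data.frame with columns `chrom`, `start`, `end` —
#'   exon intervals, 0-based half-open (BED convention)
#' @param window splice-window size in bases (default 2)
#' @return character vector of region labels
#' @examples
#' exons <- data.frame(chrom = "chr1", start = 99L, end = 200L)
#' locate_region("chr1", c(100L, 202L, 203L), exons)
#' @export
locate_region <- function(chrom, pos, exon_model, window = 2L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(exon_model)))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  out <- rep("intergenic", n)
  q <- IRanges::IRanges(start = pos, width = 1L)
  for (ch in unique(exon_model$chrom)) {
    on <- which(chrom == ch)
    if (!length(on)) next
    ex <- exon_model[exon_model$chrom == ch, , drop = FALSE]
    # exon e covers 1-based positions start+1 .. end
    exon_r <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
    span_r <- range(exon_r)
    hit <- function(rr)
      IRanges::countOverlaps(q[on], rr) > 0
    in_exon <- hit(exon_r)
    if (window > 0L) {
      splice_r <- c(
        IRanges::IRanges(start = ex$start + 1L - window, end = ex$start),
        IRanges::IRanges(start = ex$end + 1L, end = ex$end + window))
      in_splice <- !in_exon & hit(splice_r)
    } else {
      in_splice <- rep(FALSE, length(on))
    }
    in_span <- !in_exon & !in_splice & hit(span_r)
    out[on][in_exon] <- "exonic"
    out[on][in_splice] <- "splice_site"
    out[on][in_span] <- "intronic"
  }
  out
}

#' Read an exon model from a BED file
#'
#' Three or more tab-separated columns, no header: chrom, start, end
#' (0-based half-open).
#'
#' @param path BED path
#' @return data.frame with columns `chrom`, `start`, `end`
#' @export
read_exon_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bed <- utils::read.delim(path, header = FALSE,
                           colClasses = "character")[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  if (any(bed$start >= bed$end)) stop(path, ": degenerate exon interval")
  bed
}

#' Stage-1 per-call quality, location and rarity filter
#'
#' A call is retained iff it passes VQSLOD recalibration, its region is
#' exonic or splice-site, `depth >= min_depth`,
#' `alt_reads >= min_alt_reads`, its variant allele fraction
#' `alt_reads / depth` lies in \[`vaf_min`, `vaf_max`\], and its largest
#' reported population MAF is at most `max_maf` (a variant reported in
#' no database counts as MAF 0). Each rejected call is attributed to
#' the first failing filter, in the order vqslod, region, depth,
#' alt_reads, vaf, maf.
#'
#' @param cohort a [cohort_table]
#' @param config a [filter_config]
#' @return list with `retained` (a `cohort_table`) and `report` (a
#'   `filter_report`: input size, retained size, named rejection
#'   tallies summing with `retained` to `input`).
#' @export
stage1_filter <- function(cohort, config = filter_config()) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(config, "filter_config"))
  calls <- cohort$calls
  n <- nrow(calls)
  vaf <- ifelse(calls$depth > 0, calls$alt_reads / calls$depth, NaN)
  checks <- cbind(
    vqslod      = !calls$vqslod_pass,
    region      = !calls$region %in% c("exonic", "splice_site"),
    depth       = calls$depth < config$min_depth,
    alt_reads   = calls$alt_reads < config$min_alt_reads,
    vaf         = !(vaf >= config$vaf_min & vaf <= config$vaf_max) | is.nan(vaf),
    maf         = maf_max(calls$maf) > config$max_maf)
  first_fail <- integer(n)
  for (i in rev(seq_len(ncol(checks))))   # lower index wins: first-fail
    first_fail[checks[, i]] <- i
  retained <- subset_calls(cohort, first_fail == 0L)
  tallies <- vapply(seq_len(ncol(checks)), function(i)
    sum(first_fail == i), integer(1))
  names(tallies) <- colnames(checks)
  report <- structure(list(input = n,
                           retained = n_calls(retained),
                           rejections = tallies),
                      class = "filter_report")
  list(retained = retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in, %d retained\n", x$input, x$retained))
  for (nm in names(x$rejections))
    cat(sprintf("  rejected by %-10s %d\n", nm, x$rejections[[nm]]))
  invisible(x)
}

#' Cohort-recurrence artifact removal
#'
#' Variants carried by more than `threshold` of the case samples AND
#' more than `threshold` of the control samples most likely reflect
#' systematic sequencing/alignment errors or common variation private
#' to the study population; all calls of such variants are removed.
#' Carrier fractions are distinct-sample counts over the group sizes in
#' the registry (excluded samples count in neither numerator nor
#' denominator). Variants exceeding the threshold in only one group are
#' kept — the rule is deliberately symmetric and conjunctive.
#'
#' @param cohort a [cohort_table], normally stage-1 output
#' @param threshold carrier fraction above which (strictly) a
#'   both-group variant is removed (default 0.10)
#' @return list with `retained` (a `cohort_table`), `removed`
#'   (data.frame of removed variant keys with per-group carrier
#'   fractions) and `n_removed_calls`.
#' @export
cohort_recurrence_filter <- function(cohort, threshold = 0.10) {
  stopifnot(inherits(cohort, "cohort_table"))
  sizes <- group_sizes(cohort)
  if (any(sizes == 0))
    stop("both case and control groups must be non-empty")
  calls <- cohort$calls
  grp <- stats::setNames(cohort$samples$group, cohort$samples$sample_id)
  call_grp <- unname(grp[calls$sample_id])
  key <- variant_key(calls)
  carriers <- function(g) {
    idx <- which(call_grp == g)
    u <- idx[!duplicated(paste(key[idx], calls$sample_id[idx]))]
    tab <- table(key[u])
    stats::setNames(as.integer(tab), names(tab))
  }
  cc <- carriers("case")
  kc <- carriers("control")
  keys <- union(names(cc), names(kc))
  frac_case <- ifelse(keys %in% names(cc), cc[keys], 0L) / sizes[["case"]]
  frac_control <- ifelse(keys %in% names(kc), kc[keys], 0L) / sizes[["control"]]
  removed_keys <- keys[frac_case > threshold & frac_control > threshold]
  drop <- key %in% removed_keys
  removed <- data.frame(variant = removed_keys,
                        frac_case = frac_case[match(removed_keys, keys)],
                        frac_control = frac_control[match(removed_keys, keys)],
                        stringsAsFactors = FALSE)
  list(retained = subset_calls(cohort, !drop),
       removed = removed,
       n_removed_calls = sum(drop))
}

#' PolyPhen-2 HDIV missense triage
#'
#' Scores at or above `pph2_probably_min` are probably damaging, at or
#' below `pph2_benign_max` benign, anything strictly between (including
#' the narrow gaps left open by the published three-decimal class
#' boundaries) possibly damaging; an absent score yields
#' `missense_unscored`.
#'
#' @param score numeric vector of HDIV probabilities in \[0, 1\]
#'   (`NA` = unscored)
#' @param config a [filter_config]
#' @return character vector over
#'   `missense_probably|missense_possibly|missense_benign|missense_unscored`
#' @export
classify_missense <- function(score, config = filter_config()) {
  if (any(!is.na(score) & (score < 0 | score > 1)))
    stop("pph2 score outside [0,1]")
  out <- rep("missense_unscored", length(score))
  out[!is.na(score)] <- "missense_possibly"
  out[!is.na(score) & score >= config$pph2_probably_min] <- "missense_probably"
  out[!is.na(score) & score <= config$pph2_benign_max] <- "missense_benign"
  out
}

#' Assign each retained call to a single variant category
#'
#' Deterministic severity precedence resolves conflicting annotations:
#' frameshift_indel > nonsense > stop_loss > splice_site >
#' inframe_indel > missense (sub-triaged by [classify_missense()]) >
#' synonymous > other. A call whose region is splice-site is
#' categorised `splice_site` unless its functional annotation already
#' places it in a more severe class.
#'
#' @param cohort a [cohort_table] (normally after [stage1_filter()])
#' @param config a [filter_config]
#' @return the cohort with a `category` column added to its calls
#' @export
categorize <- function(cohort, config = filter_config()) {
  stopifnot(inherits(cohort, "cohort_table"))
  calls <- cohort$calls
  cat <- rep("other", nrow(calls))
  cat[calls$func == "synonymous"] <- "synonymous"
  is_mis <- calls$func == "missense"
  cat[is_mis] <- classify_missense(calls$pph2_hdiv[is_mis], config)
  cat[calls$func == "inframe_indel"] <- "inframe_indel"
  cat[calls$func == "splice_site_snv"] <- "splice_site"
  cat[calls$region == "splice_site" &
        !calls$func %in% c("frameshift_indel", "nonsense", "stop_loss")] <-
    "splice_site"
  cat[calls$func == "stop_loss"] <- "stop_loss"
  cat[calls$func == "nonsense"] <- "nonsense"
  cat[calls$func == "frameshift_indel"] <- "frameshift_indel"
  cohort$calls$category <- cat
  cohort
}

#' Restrict calls to a virtual gene panel
#'
#' A call is kept iff its gene symbol is a panel member, or — when the
#' gene annotation is absent — its coordinate intersects one of the
#' panel's intervals. Pure set inclusion; calls are not modified.
#'
#' @param cohort a [cohort_table]
#' @param panel a [gene_panel]
#' @return a `cohort_table` with the panel calls only
#' @export
restrict_to_panel <- function(cohort, panel) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(panel, "gene_panel"))
  calls <- cohort$calls
  keep <- !is.na(calls$gene) & calls$gene %in% panel$genes$gene
  anon <- which(is.na(calls$gene))
  if (length(anon) && nrow(panel$intervals)) {
    hit <- locate_region(calls$chrom[anon], calls$pos[anon],
                         panel$intervals, window = 0L) == "exonic"
    keep[anon] <- hit
  }
  subset_calls(cohort, keep)
}

#' Extract protein-damaging allelic variants (PDAVs)
#'
#' PDAVs are the highest-impact retained variants: frameshift indels,
#' nonsense and splice-site variants, plus stop-loss substitutions
#' (included by default; set `include_stop_loss = FALSE` for the strict
#' three-class definition). One record is produced per distinct variant,
#' with carriers grouped by case/control; a variant is novel when it has
#' no dbSNP identifier.
#'
#' @param cohort a categorised [cohort_table] (see [categorize()])
#' @param include_stop_loss include the stop-loss class (default TRUE)
#' @return data.frame of class `pdav_records`: `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `category`, `carriers_case`, `carriers_control`
#'   (`;`-joined sample ids, "" when none), `n_case_carriers`,
#'   `n_control_carriers`, `is_novel`.
#' @export
extract_pdavs <- function(cohort, include_stop_loss = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(cohort$calls$category))
    stop("calls are not categorised; run categorize() first")
  classes <- PDAV_CATEGORIES
  if (!include_stop_loss) classes <- setdiff(classes, "stop_loss")
  calls <- cohort$calls[cohort$calls$category %in% classes, , drop = FALSE]
  if (nrow(calls) == 0) return(empty_pdav_records())
  grp <- stats::setNames(cohort$samples$group, cohort$samples$sample_id)
  calls$group <- unname(grp[calls$sample_id])
  key <- variant_key(calls)
  idx <- split(seq_len(nrow(calls)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  join <- function(i, g) {
    ids <- sort(unique(calls$sample_id[i][calls$group[i] == g]))
    c(paste(ids, collapse = ";"), length(ids))
  }
  cases <- vapply(idx, join, character(2), g = "case")
  ctrls <- vapply(idx, join, character(2), g = "control")
  out <- data.frame(gene = calls$gene[first],
                    chrom = calls$chrom[first], pos = calls$pos[first],
                    ref = calls$ref[first], alt = calls$alt[first],
                    category = calls$category[first],
                    carriers_case = cases[1, ],
                    carriers_control = ctrls[1, ],
                    n_case_carriers = as.integer(cases[2, ]),
                    n_control_carriers = as.integer(ctrls[2, ]),
                    is_novel = is.na(calls$dbsnp_id[first]),
                    stringsAsFactors = FALSE)
  out <- out[out$n_case_carriers + out$n_control_carriers > 0, , drop = FALSE]
  out <- out[order(out$gene, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pdav_records", "data.frame")
  out
}

empty_pdav_records <- function() {
  out <- data.frame(gene = character(), chrom = character(),
                    pos = integer(), ref = character(), alt = character(),
                    category = character(), carriers_case = character(),
                    carriers_control = character(),
                    n_case_carriers = integer(),
                    n_control_carriers = integer(), is_novel = logical(),
                    stringsAsFactors = FALSE)
  class(out) <- c("pdav_records", "data.frame")
  out
}
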