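#' Construct a cohort table of annotated variant calls
#'
#' A cohort table couples a set of per-sample annotated variant calls
#' with a sample registry assigning each sample to the `case` or
#' `control` group (samples may also be flagged `excluded`, e.g.
#' internal positive controls: their calls are kept but they never enter
#' group statistics).
#'
#' Coordinates follow VCF convention: `pos` is the 1-based position of
#' the first reference base and indels carry a shared anchor base.
#' Population frequencies are held per call as a `"db:freq"` string with
#' `";"` separating databases (e.g. `"exac:0.002;gonl:0.0081"`), `NA`
#' when the variant is reported in no database.
#'
#' @param calls data.frame with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `region`, `func`, `depth`, `alt_reads`,
#'   `vqslod_pass`, `maf`, `pph2_hdiv`, `dbsnp_id`. Extra columns (such
#'   as `category`) are preserved.
#' @param samples data.frame with columns `sample_id` and `group`
#'   (one of `r toString(GROUPS)`).
#' @return An object of class `cohort_table`: a list with elements
#'   `calls` and `samples`.
#' @examples
#' ct <- cohort_table(
#'   data.frame(sample_id = "S1", chrom = "chr1", pos = 100L, ref = "A",
#'              alt = "T", gene = "CHEK2", region = "exonic",
#'              func = "nonsense", depth = 50L, alt_reads = 25L,
#'              vqslod_pass = TRUE, maf = NA, pph2_hdiv = NA,
#'              dbsnp_id = NA),
#'   data.frame(sample_id = c("S1", "S2"), group = c("case", "control")))
#' n_calls(ct)
#' @export
cohort_table <- function(calls, samples) {
  calls <- normalize_calls(calls)
  samples <- normalize_samples(samples)
  ct <- structure(list(calls = calls, samples = samples),
                  class = "cohort_table")
  validate_cohort(ct)
  ct
}

CALL_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                  "region", "func", "depth", "alt_reads", "vqslod_pass",
                  "maf", "pph2_hdiv", "dbsnp_id")

normalize_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  missing <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing))
    stop("calls table lacks column(s): ", toString(missing))
  calls$sample_id <- as.character(calls$sample_id)
  calls$chrom <- as.character(calls$chrom)
  calls$pos <- as.integer(calls$pos)
  calls$ref <- as.character(calls$ref)
  calls$alt <- as.character(calls$alt)
  calls$gene <- as.character(calls$gene)
  calls$region <- as.character(calls$region)
  calls$func <- as.character(calls$func)
  calls$depth <- as.integer(calls$depth)
  calls$alt_reads <- as.integer(calls$alt_reads)
  calls$vqslod_pass <- as.logical(calls$vqslod_pass)
  calls$maf <- as.character(calls$maf)
  calls$pph2_hdiv <- as.numeric(calls$pph2_hdiv)
  calls$dbsnp_id <- as.character(calls$dbsnp_id)
  extra <- setdiff(names(calls), CALL_COLUMNS)
  calls <- calls[, c(CALL_COLUMNS, extra), drop = FALSE]
  rownames(calls) <- NULL
  calls
}

normalize_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("sample registry needs columns sample_id and group")
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  rownames(samples) <- NULL
  samples[, c("sample_id", "group")]
}

#' Validate cohort-table invariants
#'
#' Checks field domains (region/func vocabularies, allele alphabets),
#' read-support consistency (`alt_reads <= depth`), MAF values in
#' \[0, 1\], registry coverage of every call's sample, and absence of
#' duplicate (sample, chrom, pos, ref, alt) tuples. Called by
#' [cohort_table()]; exported so readers can re-check after manual edits.
#'
#' @param ct a `cohort_table`
#' @return `ct`, invisibly; errors describe the first violated invariant
#'   and the offending row.
#' @export
validate_cohort <- function(ct) {
  calls <- ct$calls
  samples <- ct$samples
  fail <- function(rows, what) {
    stop(sprintf("invalid call (row %s): %s", toString(utils::head(rows, 5)),
                 what), call. = FALSE)
  }
  bad <- which(duplicated(samples$sample_id))
  if (length(bad)) stop("duplicate sample_id in registry: ",
                        toString(samples$sample_id[bad]))
  bad <- which(!samples$group %in% GROUPS)
  if (length(bad)) stop("unknown group label: ",
                        toString(unique(samples$group[bad])),
                        " (legal: ", toString(GROUPS), ")")
  if (nrow(calls) == 0) return(invisible(ct))
  bad <- which(!calls$sample_id %in% samples$sample_id)
  if (length(bad)) fail(bad, "sample_id not in registry")
  bad <- which(is.na(calls$pos) | calls$pos < 1L)
  if (length(bad)) fail(bad, "pos must be a positive integer")
  bad <- which(!grepl("^[ACGT]+$", calls$ref) | !grepl("^[ACGT]+$", calls$alt))
  if (length(bad)) fail(bad, "ref/alt must be non-empty strings over ACGT")
  bad <- which(calls$ref == calls$alt)
  if (length(bad)) fail(bad, "ref and alt are identical")
  bad <- which(!calls$region %in% REGIONS)
  if (length(bad)) fail(bad, "unknown region value")
  bad <- which(!calls$func %in% FUNCS)
  if (length(bad)) fail(bad, "unknown func value")
  bad <- which(is.na(calls$depth) | calls$depth < 0L |
                 is.na(calls$alt_reads) | calls$alt_reads < 0L)
  if (length(bad)) fail(bad, "depth/alt_reads must be non-negative integers")
  bad <- which(calls$alt_reads > calls$depth)
  if (length(bad)) fail(bad, "alt_reads exceeds depth")
  bad <- which(is.na(calls$vqslod_pass))
  if (length(bad)) fail(bad, "vqslod_pass must be TRUE/FALSE")
  bad <- which(!is.na(calls$pph2_hdiv) &
                 (calls$pph2_hdiv < 0 | calls$pph2_hdiv > 1))
  if (length(bad)) fail(bad, "pph2_hdiv outside [0,1]")
  mafs <- parse_maf(calls$maf)
  bad <- which(vapply(mafs, function(v)
    length(v) > 0 && (anyNA(v) || any(v < 0 | v > 1)), logical(1)))
  if (length(bad)) fail(bad, "malformed maf entry (need db:freq in [0,1])")
  key <- variant_key(calls, with_sample = TRUE)
  bad <- which(duplicated(key))
  if (length(bad)) fail(bad, paste0("duplicate call tuple ", key[bad[1]]))
  invisible(ct)
}

#' @export
print.cohort_table <- function(x, ...) {
  grp <- table(factor(x$samples$group, levels = GROUPS))
  cat(sprintf("cohort_table: %d calls, %d samples (%d case / %d control / %d excluded)\n",
              nrow(x$calls), nrow(x$samples),
              grp[["case"]], grp[["control"]], grp[["excluded"]]))
  invisible(x)
}

#' @rdname cohort_table
#' @export
n_calls <- function(ct) nrow(ct$calls)

# variant identity key; with_sample = TRUE adds the carrying sample
variant_key <- function(calls, with_sample = FALSE) {
  k <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  if (with_sample) paste(calls$sample_id, k, sep = "@") else k
}

#' Parse and summarise per-call population frequencies
#'
#' `parse_maf()` splits the `"db:freq;db:freq"` encoding into named
#' numeric vectors (empty vector when no database reports the variant).
#' `maf_max()` returns the maximum reported frequency per call, 0 when
#' unreported — the quantity the rarity filter thresholds.
#'
#' @param maf character vector of encoded frequencies (`NA` = unreported)
#' @return `parse_maf`: list of named numeric vectors; `maf_max`:
#'   numeric vector.
#' @export
parse_maf <- function(maf) {
  maf[!is.na(maf) & (maf == NA_SENTINEL | maf == "")] <- NA_character_
  parts <- strsplit(maf, ";", fixed = TRUE)
  parts[is.na(maf)] <- list(character(0))
  idx <- rep(seq_along(parts), lengths(parts))
  flat <- unlist(parts, use.names = FALSE)
  vals <- suppressWarnings(as.numeric(sub("^[^:]*:", "", flat)))
  names(vals) <- sub(":.*$", "", flat)
  out <- rep(list(numeric(0)), length(maf))
  if (length(vals))
    out[unique(idx)] <- split(vals, idx)
  out
}

#' @rdname parse_maf
#' @export
maf_max <- function(maf) {
  out <- numeric(length(maf))
  has <- which(!is.na(maf) & maf != NA_SENTINEL & maf != "")
  if (length(has)) {
    parts <- strsplit(maf[has], ";", fixed = TRUE)
    idx <- rep(seq_along(parts), lengths(parts))
    vals <- suppressWarnings(as.numeric(sub("^[^:]*:", "",
                                            unlist(parts, use.names = FALSE))))
    vals[is.na(vals)] <- Inf   # malformed entries never slip through
    out[has] <- as.numeric(tapply(vals, idx, max))
  }
  out
}

#' Subset the calls of a cohort table
#'
#' Keeps the sample registry untouched (group sizes are a property of
#' the cohort, not of the surviving calls).
#'
#' @param ct a `cohort_table`
#' @param keep logical or integer index into `ct$calls`
#' @return a `cohort_table` with the selected calls
#' @export
subset_calls <- function(ct, keep) {
  structure(list(calls = ct$calls[keep, , drop = FALSE],
                 samples = ct$samples),
            class = "cohort_table")
}

# registry restricted to samples entering group statistics
active_samples <- function(ct) {
  ct$samples[ct$samples$group %in% c("case", "control"), , drop = FALSE]
}

group_sizes <- function(ct) {
  s <- active_samples(ct)
  c(case = sum(s$group == "case"), control = sum(s$group == "control"))
}
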