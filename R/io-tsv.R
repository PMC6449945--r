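#' Read and write the canonical calls TSV
#'
#' The canonical exchange format is a tab-delimited table with one row
#' per (sample, variant) observation and a header naming every call
#' field plus the sample's `group`. Absent optional values (`gene`,
#' `maf`, `pph2_hdiv`, `dbsnp_id`) are encoded `"."`. `vqslod_pass` is
#' written `TRUE`/`FALSE`. The sample registry is reconstructed from the
#' (sample_id, group) pairs; a sample listed with two different groups
#' is an error. A registered sample with no retained calls is written as
#' a registry-only row whose variant fields are all `"."` (so group
#' sizes survive the round trip); such rows contribute no call.
#'
#' @param path file path
#' @return `read_calls`: a [cohort_table]. `write_calls`: `path`,
#'   invisibly.
#' @seealso [import_vcf()] for VCF import
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = NULL, check.names = FALSE)
  required <- c("sample_id", "group", CALL_COLUMNS_IO[-1])
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop(path, ": header lacks column(s): ", toString(missing))
  reg <- unique(raw[, c("sample_id", "group")])
  dup <- reg$sample_id[duplicated(reg$sample_id)]
  if (length(dup))
    stop(path, ": sample(s) assigned to more than one group: ",
         toString(unique(dup)))
  registry_only <- raw$chrom == NA_SENTINEL & raw$pos == NA_SENTINEL
  calls <- raw[!registry_only, , drop = FALSE]
  lineno <- which(!registry_only) + 1L   # header is line 1
  calls$group <- NULL
  for (col in c("gene", "maf", "dbsnp_id"))
    calls[[col]] <- dot_to_na(calls[[col]])
  calls$pph2_hdiv <- suppressWarnings(as.numeric(dot_to_na(calls$pph2_hdiv)))
  for (col in c("pos", "depth", "alt_reads")) {
    v <- suppressWarnings(as.integer(calls[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("%s: line %d: field '%s' is not an integer (%s)",
                   path, lineno[bad[1]], col, calls[[col]][bad[1]]))
    calls[[col]] <- v
  }
  v <- toupper(calls$vqslod_pass) %in% c("TRUE", "T", "1")
  ok <- toupper(calls$vqslod_pass) %in%
    c("TRUE", "T", "1", "FALSE", "F", "0")
  if (!all(ok))
    stop(sprintf("%s: line %d: field 'vqslod_pass' is not a logical (%s)",
                 path, lineno[which(!ok)[1]], calls$vqslod_pass[which(!ok)[1]]))
  calls$vqslod_pass <- v
  tryCatch(
    cohort_table(calls, data.frame(sample_id = reg$sample_id,
                                   group = reg$group)),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
}

# column order in the file (group inserted after sample_id on write)
CALL_COLUMNS_IO <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                     "region", "func", "depth", "alt_reads",
                     "vqslod_pass", "maf", "pph2_hdiv", "dbsnp_id")

#' @rdname read_calls
#' @param ct a [cohort_table]
#' @export
write_calls <- function(ct, path) {
  stopifnot(inherits(ct, "cohort_table"))
  out <- ct$calls[, CALL_COLUMNS_IO, drop = FALSE]
  out <- lapply(out, as.character)
  orphan <- setdiff(ct$samples$sample_id, ct$calls$sample_id)
  if (length(orphan)) {
    for (col in CALL_COLUMNS_IO)
      out[[col]] <- c(out[[col]], rep(NA_character_, length(orphan)))
    out$sample_id[seq.int(to = length(out$sample_id),
                          length.out = length(orphan))] <- orphan
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  for (col in CALL_COLUMNS_IO[-1]) out[[col]] <- na_to_dot(out[[col]])
  grp <- stats::setNames(ct$samples$group, ct$samples$sample_id)
  out <- data.frame(sample_id = out$sample_id,
                    group = unname(grp[out$sample_id]),
                    out[, -1, drop = FALSE],
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
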