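#' Gene-level PDAV carrier counts
#'
#' Collapses PDAV records to one row per gene with the number of
#' distinct case and control samples carrying at least one PDAV in the
#' gene. Carriers are counted as samples, never as variant occurrences:
#' two PDAVs in the same gene of the same sample contribute one
#' carrier.
#'
#' @param pdavs a `pdav_records` data.frame (see [extract_pdavs()] or
#'   [pdav_validated_records()])
#' @return data.frame of class `gene_recurrence`: `gene`,
#'   `n_case_carriers`, `n_control_carriers`, ordered by decreasing
#'   case carriers
#' @export
gene_pdav_carriers <- function(pdavs) {
  stopifnot(is.data.frame(pdavs))
  if (nrow(pdavs) == 0) {
    out <- data.frame(gene = character(), n_case_carriers = integer(),
                      n_control_carriers = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("gene_recurrence", "data.frame")
    return(out)
  }
  split_ids <- function(s) unique(unlist(strsplit(s[s != ""], ";")))
  per_gene <- lapply(split(pdavs, pdavs$gene), function(g) {
    cases <- split_ids(g$carriers_case)
    n_ctrl <- if ("carriers_control" %in% names(g) &&
                  any(g$carriers_control != ""))
      length(split_ids(g$carriers_control))
    else
      # only per-record control counts known (e.g. transcribed tables):
      # a lower bound that is exact when records share no control carrier
      max(g$n_control_carriers)
    data.frame(gene = g$gene[1], n_case_carriers = length(cases),
               n_control_carriers = as.integer(n_ctrl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  out <- out[order(-out$n_case_carriers, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_recurrence", "data.frame")
  out
}

#' Flag candidate predisposition genes by PDAV recurrence
#'
#' A gene is a candidate when PDAVs recur in several cases while
#' (nearly) absent from controls: either at least `min_case_carriers`
#' case carriers with at most `max_control_carriers` control carriers,
#' or — the relaxed arm for strongly recurrent genes — at least
#' `relaxed_min_cases` case carriers with at most
#' `relaxed_max_controls` control carriers.
#'
#' @param recurrence a `gene_recurrence` data.frame
#' @param min_case_carriers,max_control_carriers strict arm thresholds
#'   (defaults 3 and 0)
#' @param relaxed_min_cases,relaxed_max_controls relaxed arm thresholds
#'   (defaults 4 and 1)
#' @return the input with a logical `candidate` column added
#' @examples
#' rec <- data.frame(gene = c("A", "B", "C"),
#'                   n_case_carriers = c(3L, 4L, 2L),
#'                   n_control_carriers = c(0L, 1L, 0L))
#' select_candidates(rec)$candidate   # TRUE TRUE FALSE
#' @export
select_candidates <- function(recurrence,
                              min_case_carriers = 3L,
                              max_control_carriers = 0L,
                              relaxed_min_cases = 4L,
                              relaxed_max_controls = 1L) {
  stopifnot(is.data.frame(recurrence),
            all(c("n_case_carriers", "n_control_carriers") %in%
                  names(recurrence)))
  recurrence$candidate <-
    (recurrence$n_case_carriers >= min_case_carriers &
       recurrence$n_control_carriers <= max_control_carriers) |
    (recurrence$n_case_carriers >= relaxed_min_cases &
       recurrence$n_control_carriers <= relaxed_max_controls)
  recurrence
}

#' Cohort-level PDAV summary
#'
#' Summarises a set of PDAV records the way a validated-variant table
#' is reported: number of records, distinct carrier patients, distinct
#' genes, novel variants (no dbSNP id), splice-site variants, genes
#' with any control carrier, and the distribution of patients by the
#' number of distinct genes in which they carry a PDAV.
#'
#' @param pdavs a `pdav_records` data.frame
#' @return list of class `pdav_summary` with fields `n_records`,
#'   `n_distinct_patients`, `n_distinct_genes`, `n_novel`,
#'   `n_splice_site`, `genes_with_control_carriers`,
#'   `patients_by_gene_count` (named integer vector, name = number of
#'   genes). The identity
#'   `sum(k * patients_by_gene_count[k]) == n (patient, gene) pairs`
#'   always holds.
#' @examples
#' pdav_summary(pdav_validated_records())
#' @export
pdav_summary <- function(pdavs) {
  stopifnot(is.data.frame(pdavs))
  split_ids <- function(s) unlist(strsplit(s[!is.na(s) & s != ""], ";"))
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(pdavs)), function(i) {
    ids <- split_ids(pdavs$carriers_case[i])
    if (!length(ids)) return(NULL)
    data.frame(patient = ids, gene = pdavs$gene[i],
               stringsAsFactors = FALSE)
  })))
  if (is.null(pairs))
    pairs <- data.frame(patient = character(), gene = character())
  genes_per_patient <- table(table(pairs$patient))
  dist <- stats::setNames(as.integer(genes_per_patient),
                          names(genes_per_patient))
  structure(list(
    n_records = nrow(pdavs),
    n_distinct_patients = length(unique(pairs$patient)),
    n_distinct_genes = length(unique(pdavs$gene)),
    n_novel = sum(pdavs$is_novel),
    n_splice_site = sum(pdavs$category == "splice_site"),
    genes_with_control_carriers =
      length(unique(pdavs$gene[pdavs$n_control_carriers > 0])),
    patients_by_gene_count = dist),
    class = "pdav_summary")
}

#' @export
print.pdav_summary <- function(x, ...) {
  cat(sprintf(paste0("pdav_summary: %d records | %d patients | %d genes | ",
                     "%d novel | %d splice-site | ",
                     "%d genes with control carriers\n"),
              x$n_records, x$n_distinct_patients, x$n_distinct_genes,
              x$n_novel, x$n_splice_site, x$genes_with_control_carriers))
  cat("patients by number of mutated genes:",
      paste(sprintf("%s gene(s): %d", names(x$patients_by_gene_count),
                    x$patients_by_gene_count), collapse = ", "), "\n")
  invisible(x)
}

#' The packaged validated-PDAV table
#'
#' Loads the transcription of the study's validated protein-damaging
#' variant table shipped with the package (31 records across 26 genes
#' in 24 patients): per record the gene, PDAV category, an opaque
#' HGVS-like label, the carrier patient, the dbSNP identifier (`"."`
#' when the variant is novel) and the number of control carriers.
#'
#' @param path optional alternative TSV with the same columns
#' @return a `pdav_records` data.frame (case carriers only; control
#'   carriers are counts, their sample ids being unreported)
#' @export
pdav_validated_records <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pdav_validated.tsv",
                        package = "varburden", mustWork = TRUE)
  tab <- utils::read.delim(path, colClasses = "character",
                           na.strings = NULL, check.names = FALSE)
  need <- c("gene", "category", "variant_label", "patient_id", "rsid",
            "control_carriers")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop(path, ": lacks column(s): ", toString(missing))
  bad <- setdiff(unique(tab$category), PDAV_CATEGORIES)
  if (length(bad))
    stop(path, ": non-PDAV category: ", toString(bad))
  out <- data.frame(gene = tab$gene,
                    chrom = NA_character_, pos = NA_integer_,
                    ref = NA_character_, alt = NA_character_,
                    category = tab$category,
                    variant_label = tab$variant_label,
                    carriers_case = tab$patient_id,
                    carriers_control = "",
                    n_case_carriers = 1L,
                    n_control_carriers = as.integer(tab$control_carriers),
                    is_novel = is.na(dot_to_na(tab$rsid)),
                    validated = if ("validated" %in% names(tab))
                      toupper(tab$validated) == "TRUE" else TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("pdav_records", "data.frame")
  out
}

#' Write PDAV records or gene recurrence as TSV
#' @param x a `pdav_records` or `gene_recurrence` data.frame
#' @param path file path
#' @export
write_pdavs <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
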