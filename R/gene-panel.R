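#' Gene panels: construction, import, and overlap accounting
#'
#' A gene panel is a set of gene symbols, each with one or more genomic
#' intervals (0-based half-open, BED convention) and a non-empty set of
#' source-list memberships drawn from the seven published lists
#' aggregated into the cancer-associated gene panel (CAGP):
#' `r toString(PANEL_SOURCES)`.
#'
#' @param entries data.frame with columns `gene`, `chrom`, `start`,
#'   `end`, `sources` (comma- or semicolon-separated source names); one
#'   row per interval, rows of the same gene are merged (intervals
#'   concatenated, sources unioned).
#' @return An object of class `gene_panel`: list with `genes`
#'   (data.frame `gene`, `n_sources`, `sources`) and `intervals`
#'   (data.frame `gene`, `chrom`, `start`, `end`).
#' @export
gene_panel <- function(entries) {
  stopifnot(is.data.frame(entries))
  need <- c("gene", "chrom", "start", "end", "sources")
  missing <- setdiff(need, names(entries))
  if (length(missing)) stop("panel table lacks column(s): ", toString(missing))
  entries$gene <- as.character(entries$gene)
  entries$chrom <- as.character(entries$chrom)
  entries$start <- as.integer(entries$start)
  entries$end <- as.integer(entries$end)
  bad <- which(entries$start >= entries$end)
  if (length(bad))
    stop(sprintf("degenerate interval for gene %s: [%d, %d)",
                 entries$gene[bad[1]], entries$start[bad[1]],
                 entries$end[bad[1]]))
  src <- lapply(strsplit(as.character(entries$sources), "[,;] *"), trimws)
  unknown <- setdiff(unique(unlist(src)), PANEL_SOURCES)
  unknown <- setdiff(unknown, "")
  if (length(unknown))
    stop("unknown source list(s): ", toString(unknown),
         " (legal: ", toString(PANEL_SOURCES), ")")
  merged <- lapply(split(src, entries$gene),
                   function(s) sort(unique(unlist(s))))
  empty <- names(merged)[lengths(merged) == 0]
  if (length(empty))
    stop("gene(s) with no source list: ", toString(empty))
  genes <- data.frame(gene = names(merged),
                      n_sources = lengths(merged),
                      sources = vapply(merged, paste, character(1),
                                       collapse = ","),
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 intervals = entries[, c("gene", "chrom", "start", "end")]),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel: %d genes, %d intervals, %d in >=2 source lists\n",
              nrow(x$genes), nrow(x$intervals),
              sum(x$genes$n_sources >= 2)))
  invisible(x)
}

#' Read a gene panel from a BED-style TSV
#'
#' Expected columns: `gene`, `chrom`, `start`, `end` (0-based
#' half-open), `sources` (comma-separated names of contributing source
#' lists). Multiple rows per gene are merged.
#'
#' @param path panel TSV path
#' @return a [gene_panel]
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           na.strings = NULL, check.names = FALSE)
  if (nrow(tab) == 0)
    return(structure(list(genes = data.frame(gene = character(),
                                             n_sources = integer(),
                                             sources = character()),
                          intervals = data.frame(gene = character(),
                                                 chrom = character(),
                                                 start = integer(),
                                                 end = integer())),
                     class = "gene_panel"))
  gene_panel(tab)
}

#' The packaged cancer-associated gene panel (CAGP)
#'
#' Loads the 492-gene virtual panel aggregated from seven published
#' cancer-gene lists, shipped with the package. Gene symbols and
#' per-gene source-list membership counts follow the published panel;
#' the genomic intervals (and the identity of the member lists for
#' genes on fewer than seven lists) are synthetic placeholders — the
#' panel is intended for symbol-based restriction and membership
#' accounting, not for coordinate-accurate interval work.
#'
#' @return a [gene_panel] with 492 genes
#' @examples
#' panel_summary(cagp_panel())
#' @export
cagp_panel <- function() {
  read_gene_panel(system.file("extdata",
                              "cagp_panel_synthetic_intervals.tsv",
                              package = "varburden", mustWork = TRUE))
}

#' Panel source-list overlap accounting
#'
#' Tabulates, for each membership count k (number of source lists a
#' gene belongs to), the number of panel genes with that count — the
#' accounting used to report how much of a virtual panel is supported
#' by multiple independent gene lists.
#'
#' @param panel a [gene_panel] (non-empty)
#' @return list with `by_membership` (named integer vector, names =
#'   membership count, decreasing), `total` and `multi_list` (number of
#'   genes on at least two lists). The counts partition the panel.
#' @examples
#' panel_summary(cagp_panel())   # 492 genes, 177 on >= 2 lists
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "gene_panel"))
  if (nrow(panel$genes) == 0) stop("panel is empty")
  tab <- table(panel$genes$n_sources)
  by_membership <- stats::setNames(as.integer(tab), names(tab))
  by_membership <- by_membership[order(as.integer(names(by_membership)),
                                       decreasing = TRUE)]
  structure(list(by_membership = by_membership,
                 total = nrow(panel$genes),
                 multi_list = sum(panel$genes$n_sources >= 2)),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("panel: %d genes, %d (%.0f%%) on >=2 source lists\n",
              x$total, x$multi_list, 100 * x$multi_list / x$total))
  df <- data.frame(n_lists = names(x$by_membership),
                   n_genes = as.integer(x$by_membership))
  print(df, row.names = FALSE)
  invisible(x)
}
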