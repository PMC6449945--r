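#' Controlled vocabularies for variant observations
#'
#' Legal values for the `region` and `func` fields of an annotated call,
#' the variant categories assigned after filtration, and the names of the
#' seven source gene lists aggregated into the cancer-associated gene
#' panel (CAGP).
#'
#' Category precedence (most severe first) resolves conflicting
#' transcript annotations: frameshift_indel > nonsense > stop_loss >
#' splice_site > inframe_indel > missense > synonymous > other.
#'
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
REGIONS <- c("exonic", "splice_site", "intronic", "intergenic", "other")

#' @rdname vocabularies
#' @export
FUNCS <- c("synonymous", "missense", "nonsense", "stop_loss",
           "frameshift_indel", "inframe_indel", "splice_site_snv", "other")

#' @rdname vocabularies
#' @export
CATEGORIES <- c("synonymous", "inframe_indel", "frameshift_indel",
                "splice_site", "nonsense", "stop_loss",
                "missense_probably", "missense_possibly", "missense_benign",
                "missense_unscored", "other")

#' @rdname vocabularies
#' @export
PDAV_CATEGORIES <- c("frameshift_indel", "nonsense", "splice_site",
                     "stop_loss")

#' @rdname vocabularies
#' @export
PANEL_SOURCES <- c("Easton", "Rahman", "BROCA", "GeneRead", "Kanchi",
                   "Wood", "FaCD")

#' @rdname vocabularies
#' @export
GROUPS <- c("case", "control", "excluded")

# "." sentinel used for absent optional values in all TSV interfaces
NA_SENTINEL <- "."

dot_to_na <- function(x) {
  x[x == NA_SENTINEL | x == ""] <- NA_character_
  x
}

na_to_dot <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- NA_SENTINEL
  x
}
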