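#' Packaged reference MaxRel lists
#'
#' Returns the published reference lists of informative terms shipped with
#' the package: 23 GO terms (MI threshold 0.03) and 18 KEGG pathways (MI
#' threshold 0.013) associated with drug half-life categories, in the
#' ranked-list layout (`rank`, `term_id`, `name`, `mi`). These are the
#' selected heads of MaxRel rankings computed on STITCH v4.0 interactions
#' and 2016-era GO/KEGG annotations; they serve as fixtures for count and
#' threshold checks, not as numeric reproduction targets.
#'
#' @param namespace `"GO"` or `"KEGG"`.
#' @return A tibble in ranked-list layout.
#' @export
maxrel_reference <- function(namespace = c("GO", "KEGG")) {
  namespace <- match.arg(namespace)
  file <- system.file("extdata",
                      paste0(tolower(namespace), "_maxrel_reference.tsv"),
                      package = "hlenrich", mustWork = TRUE)
  read_ranked_list(file)
}
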