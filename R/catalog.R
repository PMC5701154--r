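#' Build an annotation catalog
#'
#' Constructs an [AnnotationCatalog-class] from term ids, category labels,
#' member gene sets, and a background universe. Gene symbols are normalized
#' (uppercase, trimmed); member sets are intersected with the universe, and
#' terms emptied by that intersection are dropped with a warning.
#'
#' @param termIds character vector of unique term identifiers.
#' @param categories character vector of category labels (e.g.
#'   "GO", "KEGG_PATHWAY"), recycled if length 1.
#' @param geneSets list of character vectors of member gene symbols,
#'   parallel to `termIds`.
#' @param universe character vector of background gene symbols. Defaults to
#'   the union of all member sets.
#' @return an [AnnotationCatalog-class].
#' @export
#' @examples
#' AnnotationCatalog(c("T1", "T2"), "GO",
#'                   list(c("G1", "G2"), c("G2", "G3")),
#'                   universe = paste0("G", 1:10))
AnnotationCatalog <- function(termIds, categories, geneSets,
                              universe = unique(unlist(geneSets))) {
    stopifnot(length(termIds) == length(geneSets))
    categories <- rep_len(as.character(categories), length(termIds))
    universe <- .normalizeUnique(universe, "universe")
    geneSets <- lapply(geneSets, function(g)
        intersect(unique(normalizeGenes(g)), universe))
    empty <- lengths(geneSets) == 0L
    if (any(empty)) {
        warning(sum(empty), " term(s) empty after intersection with the ",
                "universe were dropped", call. = FALSE)
        termIds <- termIds[!empty]
        categories <- categories[!empty]
        geneSets <- geneSets[!empty]
    }
    if (length(termIds) == 0L)
        stop("catalog has no non-empty terms", call. = FALSE)
    new("AnnotationCatalog",
        termInfo = data.frame(term_id = as.character(termIds),
                              category = categories,
                              stringsAsFactors = FALSE),
        geneSets = unname(geneSets),
        universe = universe)
}

#' Subset a catalog to a set of terms
#'
#' @param catalog an [AnnotationCatalog-class].
#' @param terms character vector of term ids to keep.
#' @return an [AnnotationCatalog-class] restricted to `terms`.
#' @export
subsetCatalog <- function(catalog, terms) {
    keep <- catalog@termInfo$term_id %in% terms
    if (!any(keep)) stop("none of the requested terms are in the catalog")
    new("AnnotationCatalog",
        termInfo = catalog@termInfo[keep, , drop = FALSE],
        geneSets = catalog@geneSets[keep],
        universe = catalog@universe)
}
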