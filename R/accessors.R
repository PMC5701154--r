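#' @rdname AnnotationCatalog-class
#' @aliases geneUniverse,AnnotationCatalog-method
setMethod("geneUniverse", "AnnotationCatalog", function(object) object@universe)

#' @rdname AnnotationCatalog-class
setMethod("geneSets", "AnnotationCatalog", function(object) {
    stats::setNames(object@geneSets, object@termInfo$term_id)
})

#' @rdname AnnotationCatalog-class
setMethod("termIds", "AnnotationCatalog", function(object) object@termInfo$term_id)

#' @rdname AnnotationCatalog-class
setMethod("termCategories", "AnnotationCatalog", function(object) {
    stats::setNames(object@termInfo$category, object@termInfo$term_id)
})

#' @rdname EnrichmentTable-class
setMethod("enrichResults", "EnrichmentTable", function(object) object@results)

#' @rdname EnrichmentTable-class
setMethod("alphaLevel", "EnrichmentTable", function(object) object@alpha)

#' @rdname EnrichmentTable-class
setMethod("significantTerms", "EnrichmentTable", function(object) {
    object@results$term_id[object@results$significant]
})

#' @rdname AnnotationMatrix-class
setMethod("incidence", "AnnotationMatrix", function(object) object@incidence)

#' @rdname AnnotationMatrix-class
#' @export
setMethod("dim", "AnnotationMatrix", function(x) dim(x@incidence))

#' @rdname ClusterPartition-class
setMethod("assignments", "ClusterPartition", function(object) object@assignments)

#' @rdname ClusterPartition-class
setMethod("cutHeight", "ClusterPartition", function(object) object@h)

#' @rdname ClusterPartition-class
setMethod("nClusters", "ClusterPartition", function(object) object@k)

#' @rdname BipartiteNetwork-class
setMethod("asIgraph", "BipartiteNetwork", function(object) object@graph)

#' @rdname GeneGraph-class
#' @param object a GeneGraph
setMethod("asIgraph", "GeneGraph", function(object) object@graph)

#' @rdname BipartiteNetwork-class
setMethod("membershipEdges", "BipartiteNetwork", function(object) object@edges)

#' @rdname BipartiteNetwork-class
setMethod("networkGenes", "BipartiteNetwork", function(object) {
    sort(unique(object@edges$gene))
})

#' @rdname BipartiteNetwork-class
setMethod("networkPathways", "BipartiteNetwork", function(object) {
    sort(unique(object@edges$pathway))
})

#' @rdname CommunityResult-class
setMethod("communityMembership", "CommunityResult", function(object) object@assignments)

#' @rdname CommunityResult-class
setMethod("modularityScore", "CommunityResult", function(object) object@Q)

#' @rdname ClusterTermCounts-class
setMethod("termCounts", "ClusterTermCounts", function(object) object@counts)

#' @rdname TermWeightTable-class
setMethod("termWeightMatrix", "TermWeightTable", function(object) object@weights)

#' @rdname SyntheticTruth-class
setMethod("plantedModules", "SyntheticTruth", function(object) object@modules)

#' @rdname SyntheticTruth-class
setMethod("plantedHubs", "SyntheticTruth", function(object) object@hubs)

#' @rdname SyntheticTruth-class
setMethod("plantedBridges", "SyntheticTruth", function(object) object@bridges)

setMethod("show", "AnnotationCatalog", function(object) {
    cat("AnnotationCatalog with", nrow(object@termInfo), "terms over a",
        "universe of", length(object@universe), "genes\n")
    cat("  categories:",
        paste(utils::head(sort(unique(object@termInfo$category)), 5),
              collapse = ", "), "\n")
})

setMethod("show", "EnrichmentTable", function(object) {
    cat("EnrichmentTable:", nrow(object@results), "terms with overlap,",
        sum(object@results$significant), "significant at alpha =",
        object@alpha, paste0("(", object@method, ")"), "\n")
})

setMethod("show", "AnnotationMatrix", function(object) {
    cat("AnnotationMatrix:", nrow(object@incidence), "genes x",
        ncol(object@incidence), "annotation terms;",
        sum(object@incidence), "incidences\n")
})

setMethod("show", "ClusterPartition", function(object) {
    cat("ClusterPartition:", length(object@assignments), "genes in",
        object@k, "clusters",
        if (!is.na(object@h)) paste0("(cut at h = ", object@h, ")") else
            "(cut by cluster count)", "\n")
})

setMethod("show", "BipartiteNetwork", function(object) {
    cat("BipartiteNetwork:", length(unique(object@edges$gene)), "genes,",
        length(unique(object@edges$pathway)), "pathways,",
        nrow(object@edges), "membership edges\n")
})

setMethod("show", "GeneGraph", function(object) {
    cat("GeneGraph:", igraph::vcount(object@graph), "genes,",
        igraph::ecount(object@graph), "weighted edges\n")
})

setMethod("show", "CommunityResult", function(object) {
    cat("CommunityResult:", length(unique(object@assignments)),
        "communities over", length(object@assignments),
        "genes; Q =", format(object@Q, digits = 4), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:",
        if (length(object@modules))
            paste(length(object@modules), "genes in",
                  length(unique(object@modules)), "planted modules;")
        else "",
        length(object@hubs), "hubs,", length(object@bridges),
        "bridges; seed", object@seed, "\n")
})
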