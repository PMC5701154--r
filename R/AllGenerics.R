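#' @rdname AnnotationCatalog-class
#' @param object,x an object of the documented class
#' @export
setGeneric("geneUniverse", function(object) standardGeneric("geneUniverse"))

#' @rdname AnnotationCatalog-class
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname AnnotationCatalog-class
#' @export
setGeneric("termIds", function(object) standardGeneric("termIds"))

#' @rdname AnnotationCatalog-class
#' @export
setGeneric("termCategories", function(object) standardGeneric("termCategories"))

#' @rdname EnrichmentTable-class
#' @export
setGeneric("enrichResults", function(object) standardGeneric("enrichResults"))

#' @rdname EnrichmentTable-class
#' @export
setGeneric("alphaLevel", function(object) standardGeneric("alphaLevel"))

#' @rdname EnrichmentTable-class
#' @export
setGeneric("significantTerms", function(object) standardGeneric("significantTerms"))

#' @rdname AnnotationMatrix-class
#' @export
setGeneric("incidence", function(object) standardGeneric("incidence"))

#' @rdname ClusterPartition-class
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname ClusterPartition-class
#' @export
setGeneric("cutHeight", function(object) standardGeneric("cutHeight"))

#' @rdname ClusterPartition-class
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname BipartiteNetwork-class
#' @export
setGeneric("asIgraph", function(object) standardGeneric("asIgraph"))

#' @rdname BipartiteNetwork-class
#' @export
setGeneric("membershipEdges", function(object) standardGeneric("membershipEdges"))

#' @rdname BipartiteNetwork-class
#' @export
setGeneric("networkGenes", function(object) standardGeneric("networkGenes"))

#' @rdname BipartiteNetwork-class
#' @export
setGeneric("networkPathways", function(object) standardGeneric("networkPathways"))

#' @rdname CommunityResult-class
#' @export
setGeneric("communityMembership", function(object) standardGeneric("communityMembership"))

#' @rdname CommunityResult-class
#' @export
setGeneric("modularityScore", function(object) standardGeneric("modularityScore"))

#' @rdname ClusterTermCounts-class
#' @export
setGeneric("termCounts", function(object) standardGeneric("termCounts"))

#' @rdname TermWeightTable-class
#' @export
setGeneric("termWeightMatrix", function(object) standardGeneric("termWeightMatrix"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedModules", function(object) standardGeneric("plantedModules"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedHubs", function(object) standardGeneric("plantedHubs"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedBridges", function(object) standardGeneric("plantedBridges"))
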