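#' @import methods
NULL

#' AnnotationCatalog: annotation terms with member gene sets and a universe
#'
#' Container for a catalog of annotation terms (GO-, KEGG-, INTERPRO-style),
#' each carrying a category label and a set of member genes, together with
#' the background gene universe against which enrichment is assessed.
#' Member sets are intersected with the universe at construction; terms left
#' empty by that intersection are invalid.
#'
#' @slot termInfo data.frame with columns `term_id` and `category`, one row
#'   per term; `term_id` values are unique.
#' @slot geneSets list of character vectors, parallel to `termInfo`, each a
#'   set of (normalized, uppercase) gene symbols, all members of `universe`.
#' @slot universe character vector of unique gene symbols forming the
#'   background universe.
#'
#' @seealso [AnnotationCatalog()] for the user-facing constructor,
#'   [enrichCatalog()] for enrichment against the catalog.
#' @exportClass AnnotationCatalog
setClass("AnnotationCatalog",
    slots = c(termInfo = "data.frame", geneSets = "list",
              universe = "character"))

setValidity("AnnotationCatalog", function(object) {
    msg <- character()
    if (length(object@universe) == 0L)
        msg <- c(msg, "universe is empty")
    if (anyDuplicated(object@universe))
        msg <- c(msg, "universe contains duplicate symbols")
    if (!all(c("term_id", "category") %in% colnames(object@termInfo)))
        msg <- c(msg, "termInfo must have columns 'term_id' and 'category'")
    else {
        if (anyDuplicated(object@termInfo$term_id))
            msg <- c(msg, "term_ids are not unique")
        if (length(object@geneSets) != nrow(object@termInfo))
            msg <- c(msg, "geneSets and termInfo lengths differ")
        else {
            if (any(lengths(object@geneSets) == 0L))
                msg <- c(msg, "a term has an empty gene set")
            if (!all(unlist(object@geneSets) %in% object@universe))
                msg <- c(msg, "a member gene is outside the universe")
        }
    }
    if (length(msg)) msg else TRUE
})

#' EnrichmentTable: per-term enrichment results
#'
#' One row per tested annotation term with nonzero overlap: the overlap
#' count `k`, term size `K`, query size `n`, universe size `N`, the raw
#' enrichment p-value, a Benjamini-Hochberg FDR column (informational), and
#' a significance flag defined by `p_value < alpha`.
#'
#' @slot results data.frame with columns term_id, category, k, K, n, N,
#'   p_value, bh_fdr, significant; sorted ascending by p_value.
#' @slot alpha numeric significance threshold recorded with the table.
#' @slot method character, "ease" or "hypergeometric".
#'
#' @exportClass EnrichmentTable
setClass("EnrichmentTable",
    slots = c(results = "data.frame", alpha = "numeric", method = "character"))

setValidity("EnrichmentTable", function(object) {
    req <- c("term_id", "category", "k", "K", "n", "N",
             "p_value", "bh_fdr", "significant")
    r <- object@results
    msg <- character()
    if (!all(req %in% colnames(r)))
        return(paste("results must have columns:", paste(req, collapse = ", ")))
    if (nrow(r)) {
        if (any(r$k > pmin(r$K, r$n)) || any(r$K > r$N) || any(r$n > r$N) ||
            any(r$k < 0))
            msg <- c(msg, "inconsistent counts (need 0 <= k <= min(K, n), K <= N, n <= N)")
        if (any(r$p_value < 0 | r$p_value > 1))
            msg <- c(msg, "p_value outside [0, 1]")
        if (!identical(r$significant, r$p_value < object@alpha))
            msg <- c(msg, "significant flag inconsistent with p_value < alpha")
    }
    if (length(object@alpha) != 1L || object@alpha < 0 || object@alpha > 1)
        msg <- c(msg, "alpha must be a single value in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' AnnotationMatrix: binary gene-by-annotation incidence
#'
#' Binary matrix with genes as rows and (significantly enriched) annotation
#' terms as columns; entry 1 means the gene is a member of the term's gene
#' set. All-zero gene rows are retained (a gene may carry no significant
#' term), but every column must be carried by at least one gene.
#'
#' @slot incidence integer matrix of 0/1 with gene rownames and term
#'   colnames.
#'
#' @exportClass AnnotationMatrix
setClass("AnnotationMatrix", slots = c(incidence = "matrix"))

setValidity("AnnotationMatrix", function(object) {
    m <- object@incidence
    msg <- character()
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("incidence must have gene rownames and term colnames")
    if (anyDuplicated(rownames(m)))
        msg <- c(msg, "duplicate gene labels")
    if (anyDuplicated(colnames(m)))
        msg <- c(msg, "duplicate term labels")
    if (!all(m %in% c(0L, 1L)))
        msg <- c(msg, "incidence values must be 0 or 1")
    else if (ncol(m) && any(colSums(m) == 0L))
        msg <- c(msg, "a term column has no member genes")
    if (length(msg)) msg else TRUE
})

#' ClusterPartition: gene clusters from a dendrogram cut
#'
#' A hard partition of the genes into clusters, usually obtained by cutting
#' a Ward dendrogram at a height threshold. Cluster ids are contiguous
#' integers 1..k, assigned by dendrogram leaf order.
#'
#' @slot assignments named integer vector, gene -> cluster id.
#' @slot h numeric cut height (NA when the partition was defined by a
#'   requested number of clusters rather than a height).
#' @slot k integer number of clusters.
#'
#' @exportClass ClusterPartition
setClass("ClusterPartition",
    slots = c(assignments = "integer", h = "numeric", k = "integer"))

setValidity("ClusterPartition", function(object) {
    a <- object@assignments
    msg <- character()
    if (is.null(names(a)) || anyDuplicated(names(a)))
        msg <- c(msg, "assignments must be uniquely named by gene")
    ids <- sort(unique(unname(a)))
    if (length(a) && !identical(ids, seq_len(object@k)))
        msg <- c(msg, "cluster ids must be contiguous 1..k")
    if (length(msg)) msg else TRUE
})

#' BipartiteNetwork: gene-pathway membership graph
#'
#' Bipartite graph whose two node classes are genes and pathways and whose
#' edges are pathway memberships. Genes belonging to none of the selected
#' pathways are excluded; pathways are never isolated.
#'
#' @slot graph igraph object with a logical vertex attribute `type`
#'   (FALSE = gene, TRUE = pathway).
#' @slot edges data.frame with columns `gene` and `pathway`, one row per
#'   membership edge.
#'
#' @exportClass BipartiteNetwork
setClass("BipartiteNetwork", slots = c(graph = "ANY", edges = "data.frame"))

setValidity("BipartiteNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("gene", "pathway") %in% colnames(e)))
        return("edges must have columns 'gene' and 'pathway'")
    if (anyDuplicated(e))
        msg <- c(msg, "duplicate membership edges")
    if (nrow(e) && length(intersect(unique(e$gene), unique(e$pathway))))
        msg <- c(msg, "a node appears both as gene and as pathway")
    if (length(msg)) msg else TRUE
})

#' GeneGraph: weighted one-mode gene projection
#'
#' Undirected weighted gene graph obtained by projecting a
#' [BipartiteNetwork-class] onto its gene nodes; the weight of an edge is
#' the number of pathways the two genes share (an integer >= 1). No
#' self-loops.
#'
#' @slot graph igraph object with an edge attribute `weight`.
#'
#' @exportClass GeneGraph
setClass("GeneGraph", slots = c(graph = "ANY"))

#' CommunityResult: gene communities with modularity
#'
#' A partition of the genes of a [GeneGraph-class] into communities,
#' together with the weighted Newman-Girvan modularity Q of that partition
#' (recomputed from the partition, not taken from the optimizer) and the
#' seed used by the (order-sensitive) Louvain optimizer.
#'
#' @slot assignments named integer vector, gene -> community id (1..k).
#' @slot Q numeric modularity of the partition.
#' @slot seed integer seed used for the Louvain run.
#'
#' @exportClass CommunityResult
setClass("CommunityResult",
    slots = c(assignments = "integer", Q = "numeric", seed = "integer"))

setValidity("CommunityResult", function(object) {
    msg <- character()
    if (is.null(names(object@assignments)))
        msg <- c(msg, "assignments must be named by gene")
    if (length(object@Q) != 1L || object@Q < -0.5 - 1e-12 ||
        object@Q > 1 + 1e-12)
        msg <- c(msg, "Q must be a single value in [-0.5, 1]")
    if (length(msg)) msg else TRUE
})

#' ClusterTermCounts: annotation counts per cluster
#'
#' The term-by-cluster count matrix n(a, c): the number of genes of cluster
#' c annotated by term a. Row sums give the total count of each annotation
#' across clusters, the grand total is the total count of all annotations,
#' and the number of clusters with a nonzero count gives each annotation's
#' cluster presence.
#'
#' @slot counts integer matrix, terms (rows, named) by clusters (columns
#'   named "1".."k").
#'
#' @exportClass ClusterTermCounts
setClass("ClusterTermCounts", slots = c(counts = "matrix"))

setValidity("ClusterTermCounts", function(object) {
    m <- object@counts
    if (is.null(rownames(m))) return("counts must have term rownames")
    if (any(m < 0)) return("counts must be non-negative")
    TRUE
})

#' TermWeightTable: per-(annotation, cluster) extraction weights
#'
#' Weights w(a, c) = n(a, c) * ln(N_total / n(a, .)) used to rank
#' annotations within clusters, where n(a, c) is the count of annotation a
#' in cluster c, n(a, .) its total count across clusters, and N_total the
#' total count of all annotations across all clusters.
#'
#' @slot weights numeric matrix, terms by clusters, parallel to `counts`.
#' @slot counts integer matrix of the underlying counts.
#'
#' @exportClass TermWeightTable
setClass("TermWeightTable", slots = c(weights = "matrix", counts = "matrix"))

setValidity("TermWeightTable", function(object) {
    w <- object@weights
    msg <- character()
    if (!identical(dim(w), dim(object@counts)))
        msg <- c(msg, "weights and counts dimensions differ")
    if (any(!is.finite(w)))
        msg <- c(msg, "weights must be finite")
    else if (any(w[object@counts == 0] != 0))
        msg <- c(msg, "w(a,c) must be 0 wherever n(a,c) = 0")
    if (length(msg)) msg else TRUE
})

#' SyntheticTruth: planted structure of a simulated dataset
#'
#' Ground truth attached to the output of the synthetic generators: planted
#' module labels, term-to-module assignment, designated hub and bridge
#' genes, designated uncovered pathways, and the full generator parameter
#' set (including the seed) for reproducibility.
#'
#' @slot modules named integer vector, gene -> planted module (empty for
#'   pathway-only simulations).
#' @slot termModules named integer vector, annotation term -> module whose
#'   private pool it belongs to.
#' @slot hubs character vector of designated hub genes.
#' @slot bridges character vector of designated bridge genes.
#' @slot uncovered character vector of designated uncovered pathways.
#' @slot params list of generator parameters.
#' @slot seed integer seed that produced the dataset.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    slots = c(modules = "integer", termModules = "integer",
              hubs = "character", bridges = "character",
              uncovered = "character", params = "list", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (length(object@modules) && is.null(names(object@modules)))
        msg <- c(msg, "modules must be named by gene")
    p <- object@params
    if (!is.null(p$pIn) && !is.null(p$pOut) &&
        !(p$pOut >= 0 && p$pOut < p$pIn && p$pIn <= 1))
        msg <- c(msg, "need 0 <= pOut < pIn <= 1")
    if (length(msg)) msg else TRUE
})
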