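#' Select significantly enriched signaling pathways
#'
#' From an enrichment table, keeps the significant rows of pathway-type
#' categories whose term name contains the substring "signaling"
#' (case-insensitive).
#'
#' @param table an [EnrichmentTable-class].
#' @param pathwayCategories categories to treat as pathway annotations;
#'   `NULL` (default) selects categories whose label contains "pathway"
#'   (case-insensitive), e.g. "KEGG_PATHWAY".
#' @return character vector of selected pathway term ids.
#' @export
#' @examples
#' # "hsa04390:Hippo signaling pathway" matches; "hsa04110:cell cycle"
#' # does not.
selectSignalingPathways <- function(table, pathwayCategories = NULL) {
    stopifnot(is(table, "EnrichmentTable"))
    res <- table@results
    res <- res[res$significant, , drop = FALSE]
    if (is.null(pathwayCategories))
        inPathway <- grepl("pathway", res$category, ignore.case = TRUE)
    else
        inPathway <- res$category %in% pathwayCategories
    hit <- inPathway & grepl("signaling", res$term_id, ignore.case = TRUE)
    out <- res$term_id[hit]
    if (length(out) == 0L)
        stop("no significant signaling pathway found; check that the ",
             "catalog's pathway categories are selected ",
             "(pathwayCategories) and that term names contain 'signaling'")
    out
}

#' Build the bipartite gene-pathway membership network
#'
#' One edge per (gene, pathway) membership, restricted to the supplied
#' gene list; genes belonging to none of the selected pathways are
#' excluded from the network.
#'
#' @param pathways character vector of pathway term ids (must exist in the
#'   catalog).
#' @param catalog the [AnnotationCatalog-class].
#' @param genes character vector of gene symbols eligible as gene nodes.
#' @return a [BipartiteNetwork-class].
#' @export
buildBipartite <- function(pathways, catalog, genes) {
    stopifnot(is(catalog, "AnnotationCatalog"))
    sets <- geneSets(catalog)
    missing <- setdiff(pathways, names(sets))
    if (length(missing))
        stop("pathways absent from catalog: ",
             paste(utils::head(missing, 3), collapse = ", "))
    genes <- .normalizeUnique(genes, "gene list")
    edges <- do.call(rbind, lapply(pathways, function(p) {
        memb <- intersect(sets[[p]], genes)
        if (length(memb) == 0L) return(NULL)
        data.frame(gene = memb, pathway = p, stringsAsFactors = FALSE)
    }))
    if (is.null(edges) || nrow(edges) == 0L)
        stop("no gene in the list belongs to any selected pathway")
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::V(g)$type <- igraph::V(g)$name %in% edges$pathway
    new("BipartiteNetwork", graph = g, edges = edges)
}

#' Per-gene pathway-membership degrees
#'
#' @param net a [BipartiteNetwork-class].
#' @return named integer vector: number of pathways each gene belongs to
#'   (always >= 1).
#' @export
pathwayDegrees <- function(net) {
    stopifnot(is(net, "BipartiteNetwork"))
    tab <- table(net@edges$gene)
    stats::setNames(as.integer(tab), names(tab))
}

#' Percentile hub threshold of the degree distribution
#'
#' The requested percentile of the gene degree distribution under linear
#' interpolation between order statistics. Hub genes are those with degree
#' strictly greater than the threshold.
#'
#' @param degrees named numeric vector of gene degrees (from
#'   [pathwayDegrees()]).
#' @param percentile percentile in (0, 100), default 95.
#' @return the threshold t (a single number).
#' @export
#' @examples
#' hubThreshold(stats::setNames(1:10, letters[1:10]), 90)  # 9.1
hubThreshold <- function(degrees, percentile = 95) {
    stopifnot(length(degrees) > 0, percentile > 0, percentile < 100)
    unname(stats::quantile(degrees, percentile / 100, type = 7))
}

#' Hub genes above a degree threshold
#'
#' @param degrees named numeric vector of gene degrees.
#' @param threshold degree threshold; genes with degree strictly greater
#'   are hubs.
#' @return character vector of hub gene names.
#' @export
hubGenes <- function(degrees, threshold) {
    names(degrees)[degrees > threshold]
}

#' Pathways not covered by any hub gene
#'
#' @param net a [BipartiteNetwork-class].
#' @param hubs character vector of hub genes (must be network genes).
#' @return character vector of uncovered pathway ids.
#' @export
uncoveredPathways <- function(net, hubs) {
    stopifnot(is(net, "BipartiteNetwork"))
    bad <- setdiff(hubs, net@edges$gene)
    if (length(bad))
        stop("hubs outside the network: ",
             paste(utils::head(bad, 3), collapse = ", "))
    covered <- unique(net@edges$pathway[net@edges$gene %in% hubs])
    setdiff(sort(unique(net@edges$pathway)), covered)
}

#' Bridge genes linking uncovered pathways into the network
#'
#' Genes that belong to at least one uncovered pathway and to at least two
#' pathways in total, and therefore connect an uncovered pathway to the
#' rest of the network. Uncovered pathways with no such member remain
#' isolated and are reported separately.
#'
#' @param net a [BipartiteNetwork-class].
#' @param uncovered character vector of uncovered pathway ids.
#' @return list with `genes` (bridge genes), `connected` and `isolated`
#'   (partition of `uncovered`).
#' @export
bridgeGenes <- function(net, uncovered) {
    stopifnot(is(net, "BipartiteNetwork"))
    bad <- setdiff(uncovered, net@edges$pathway)
    if (length(bad))
        stop("uncovered pathways outside the network: ",
             paste(utils::head(bad, 3), collapse = ", "))
    deg <- pathwayDegrees(net)
    inUncov <- unique(net@edges$gene[net@edges$pathway %in% uncovered])
    bridges <- sort(intersect(inUncov, names(deg)[deg >= 2L]))
    connected <- sort(unique(
        net@edges$pathway[net@edges$pathway %in% uncovered &
                          net@edges$gene %in% bridges]))
    list(genes = bridges,
         connected = connected,
         isolated = setdiff(sort(uncovered), connected))
}

#' One-mode gene projection of the bipartite network
#'
#' Weighted undirected gene graph in which two genes are linked iff they
#' share at least one pathway; the edge weight is the number of shared
#' pathways.
#'
#' @param net a [BipartiteNetwork-class].
#' @return a [GeneGraph-class].
#' @export
projectGenes <- function(net) {
    stopifnot(is(net, "BipartiteNetwork"))
    genes <- sort(unique(net@edges$gene))
    paths <- sort(unique(net@edges$pathway))
    m <- matrix(0L, length(genes), length(paths),
                dimnames = list(genes, paths))
    m[cbind(net@edges$gene, net@edges$pathway)] <- 1L
    adj <- tcrossprod(m)
    diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    new("GeneGraph", graph = g)
}

#' Louvain community detection on the gene graph
#'
#' Greedy modularity optimization (the Louvain method) on the weighted
#' gene projection. The method is order-sensitive, so the node shuffling
#' is controlled by a seed; with `restarts > 1` the best-Q partition over
#' the restarts is returned. The reported Q is always recomputed from the
#' final partition with [modularityQ()], never taken from the optimizer.
#'
#' @param graph a [GeneGraph-class] (or igraph object with weights).
#' @param seed integer seed controlling node order (default 1).
#' @param restarts number of seeded restarts; the partition with highest
#'   recomputed Q wins (default 1).
#' @return a [CommunityResult-class].
#' @export
louvainCommunities <- function(graph, seed = 1, restarts = 1) {
    g <- if (is(graph, "GeneGraph")) graph@graph else graph
    if (igraph::vcount(g) == 0L) stop("graph has no nodes")
    nodes <- igraph::V(g)$name
    if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
    if (igraph::ecount(g) == 0L) {
        memb <- stats::setNames(seq_along(nodes), nodes)
        return(new("CommunityResult", assignments = memb, Q = 0,
                   seed = as.integer(seed)))
    }
    best <- NULL
    for (r in seq_len(restarts)) {
        memb <- withr::with_seed(as.integer(seed) + r - 1L, {
            cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
            stats::setNames(as.integer(igraph::membership(cl)), nodes)
        })
        q <- modularityQ(g, memb)
        if (is.null(best) || q > best$q) best <- list(memb = memb, q = q)
    }
    new("CommunityResult", assignments = best$memb, Q = best$q,
        seed = as.integer(seed))
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' Q = sum_c ( w_c / W - (s_c / 2W)^2 ), where W is the total edge weight,
#' w_c the weight inside community c, and s_c the summed strength of its
#' nodes.
#'
#' @param graph a [GeneGraph-class] or weighted undirected igraph object.
#' @param partition named integer/character vector mapping every node to a
#'   community.
#' @return the modularity Q (a single number in \[-0.5, 1\]).
#' @export
modularityQ <- function(graph, partition) {
    g <- if (is(graph, "GeneGraph")) graph@graph else graph
    nodes <- igraph::V(g)$name
    if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
    if (is(partition, "CommunityResult")) partition <- partition@assignments
    miss <- setdiff(nodes, names(partition))
    if (length(miss))
        stop("nodes missing from partition: ",
             paste(utils::head(miss, 3), collapse = ", "))
    comm <- partition[nodes]
    el <- igraph::as_data_frame(g, what = "edges")
    wt <- if (is.null(el$weight)) rep(1, nrow(el)) else el$weight
    W <- sum(wt)
    if (W == 0) return(0)
    intra <- tapply(wt[comm[el$from] == comm[el$to]],
                    comm[el$from][comm[el$from] == comm[el$to]], sum)
    strength <- igraph::strength(g, weights = wt)
    s_c <- tapply(strength, comm, sum)
    q <- sum(intra / W) - sum((s_c / (2 * W))^2)
    unname(q)
}

#' Summarize a signaling-network analysis
#'
#' @param net a [BipartiteNetwork-class].
#' @param percentile hub percentile (default 95).
#' @param seed,restarts passed to [louvainCommunities()].
#' @return list with the network statistics: node counts, degree extremes,
#'   hub threshold and hubs, covered/uncovered pathways, bridge genes, and
#'   the community result.
#' @export
summarizeNetwork <- function(net, percentile = 95, seed = 1, restarts = 1) {
    deg <- pathwayDegrees(net)
    t <- hubThreshold(deg, percentile)
    hubs <- hubGenes(deg, t)
    uncov <- uncoveredPathways(net, hubs)
    br <- bridgeGenes(net, uncov)
    comm <- louvainCommunities(projectGenes(net), seed = seed,
                               restarts = restarts)
    list(n_genes = length(unique(net@edges$gene)),
         n_pathways = length(unique(net@edges$pathway)),
         min_degree = min(deg), max_degree = max(deg),
         hub_threshold = t, hubs = hubs,
         n_covered = length(unique(net@edges$pathway)) - length(uncov),
         uncovered = uncov,
         bridges = br$genes,
         bridge_connected = br$connected,
         bridge_isolated = br$isolated,
         communities = comm)
}
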