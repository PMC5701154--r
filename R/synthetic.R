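#' Simulate an annotation catalog with planted gene modules
#'
#' Generates a query gene list partitioned into `nModules` planted modules,
#' an annotation catalog in which each module owns a private pool of
#' `annotationsPerModule` terms, and a background universe. A gene of
#' module m carries each of module m's terms with probability `pIn` and
#' every other module's terms with probability `pOut`; background
#' (non-query) universe genes carry every term at rate `pOut`, so the
#' query list is enriched for the planted terms by construction and the
#' whole pipeline can run on the output. Terms left without members are
#' given one member from their own module so the catalog stays valid. All
#' draws flow from the single seed.
#'
#' @param nGenes query genes (default 240); must be divisible by
#'   `nModules`.
#' @param nModules planted modules (default 6).
#' @param annotationsPerModule private terms per module (default 30).
#' @param pIn within-module term-carriage probability (default 0.6).
#' @param pOut background carriage probability (default 0.02); must be
#'   < `pIn`.
#' @param universeSize background universe size (default `2 * nGenes`;
#'   must be at least that).
#' @param category category label given to all terms (default "GO").
#' @param seed integer seed.
#' @return list with `genes` (query list), `catalog`
#'   ([AnnotationCatalog-class]), and `truth` ([SyntheticTruth-class]).
#' @export
simulateAnnotationCatalog <- function(nGenes = 240, nModules = 6,
                                      annotationsPerModule = 30,
                                      pIn = 0.6, pOut = 0.02,
                                      universeSize = 2 * nGenes,
                                      category = "GO", seed = 1) {
    if (!(pOut >= 0 && pOut < pIn && pIn <= 1))
        stop("need 0 <= pOut < pIn <= 1")
    if (nGenes %% nModules != 0)
        stop("nGenes must be divisible by nModules")
    if (universeSize < 2 * nGenes)
        stop("universeSize must be at least 2 * nGenes")
    universe <- sprintf("GENE%05d", seq_len(universeSize))
    genes <- universe[seq_len(nGenes)]
    modules <- stats::setNames(rep(seq_len(nModules),
                                   each = nGenes / nModules), genes)
    termIds <- as.vector(outer(sprintf("M%02d", seq_len(nModules)),
                               sprintf("ANN%03d", seq_len(annotationsPerModule)),
                               function(m, a) paste0(m, "_", a)))
    termModules <- rep(seq_len(nModules), times = annotationsPerModule)
    ord <- order(termModules, termIds)
    termIds <- termIds[ord]; termModules <- termModules[ord]
    sets <- withr::with_seed(as.integer(seed), {
        lapply(seq_along(termIds), function(i) {
            m <- termModules[i]
            pQuery <- ifelse(modules == m, pIn, pOut)
            carrier <- genes[stats::runif(nGenes) < pQuery]
            bg <- universe[-seq_len(nGenes)]
            carrier <- c(carrier, bg[stats::runif(length(bg)) < pOut])
            if (length(carrier) == 0L)
                carrier <- genes[modules == m][1L]
            carrier
        })
    })
    catalog <- suppressWarnings(
        AnnotationCatalog(termIds, category, sets, universe = universe))
    truth <- new("SyntheticTruth",
                 modules = modules,
                 termModules = stats::setNames(termModules, termIds),
                 hubs = character(), bridges = character(),
                 uncovered = character(),
                 params = list(nGenes = nGenes, nModules = nModules,
                               annotationsPerModule = annotationsPerModule,
                               pIn = pIn, pOut = pOut,
                               universeSize = universeSize),
                 seed = as.integer(seed))
    list(genes = genes, catalog = catalog, truth = truth)
}

#' Simulate a gene-pathway bipartite network with planted hubs and bridges
#'
#' Pathways are split into covered and designated-uncovered blocks.
#' Planted hub genes join each covered pathway with probability `hubRate`;
#' ordinary genes join with probability `backgroundRate`. Uncovered
#' pathways exclude hubs by construction; their members are ordinary genes
#' (at `backgroundRate`) plus designated bridge genes, each of which is
#' also guaranteed at least one covered-pathway membership. Every pathway
#' is guaranteed at least one member, and genes with no membership are
#' absent from the network.
#'
#' @param nGenes candidate genes (default 200).
#' @param nPathways total pathways (default 40; at least 4).
#' @param nHubs planted hub genes (default 10).
#' @param hubRate hub membership probability for covered pathways
#'   (default 0.6).
#' @param backgroundRate ordinary membership probability (default 0.05).
#' @param nUncovered designated uncovered pathways (default 2).
#' @param nBridges designated bridge genes (default 8).
#' @param seed integer seed.
#' @return list with `network` ([BipartiteNetwork-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @export
simulatePathwayMembership <- function(nGenes = 200, nPathways = 40,
                                      nHubs = 10, hubRate = 0.6,
                                      backgroundRate = 0.05,
                                      nUncovered = 2, nBridges = 8,
                                      seed = 1) {
    if (nPathways < 4) stop("need at least 4 pathways")
    if (nHubs < 1) stop("need at least 1 designated hub")
    if (nUncovered < 1) stop("need at least 1 designated uncovered pathway")
    if (nUncovered >= nPathways)
        stop("uncovered pathways must leave at least one covered pathway")
    if (nHubs + nBridges > nGenes)
        stop("more designated hubs and bridges than genes")
    genes <- sprintf("GENE%05d", seq_len(nGenes))
    paths <- sprintf("PATH%03d", seq_len(nPathways))
    hubs <- genes[seq_len(nHubs)]
    bridges <- genes[nHubs + seq_len(nBridges)]
    uncovered <- paths[nPathways - seq_len(nUncovered) + 1L]
    covered <- setdiff(paths, uncovered)
    memb <- withr::with_seed(as.integer(seed), {
        m <- matrix(FALSE, nGenes, nPathways, dimnames = list(genes, paths))
        rate <- matrix(backgroundRate, nGenes, nPathways)
        rate[match(hubs, genes), match(covered, paths)] <- hubRate
        rate[match(hubs, genes), match(uncovered, paths)] <- 0  # by construction
        m[] <- stats::runif(length(m)) < rate
        # bridges: one uncovered pathway each (round-robin) plus >= 1
        # covered membership
        for (i in seq_along(bridges)) {
            u <- uncovered[(i - 1L) %% nUncovered + 1L]
            m[bridges[i], u] <- TRUE
            if (!any(m[bridges[i], covered]))
                m[bridges[i], sample(covered, 1L)] <- TRUE
        }
        # no empty pathway: give it one non-hub member
        for (p in paths[colSums(m) == 0L]) {
            pool <- if (p %in% uncovered) setdiff(genes, hubs) else genes
            m[sample(pool, 1L), p] <- TRUE
        }
        m
    })
    idx <- which(memb, arr.ind = TRUE)
    edges <- data.frame(gene = genes[idx[, 1]], pathway = paths[idx[, 2]],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$pathway, edges$gene), ]
    rownames(edges) <- NULL
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::V(g)$type <- igraph::V(g)$name %in% edges$pathway
    net <- new("BipartiteNetwork", graph = g, edges = edges)
    truth <- new("SyntheticTruth",
                 modules = integer(),
                 termModules = integer(),
                 hubs = hubs, bridges = bridges, uncovered = uncovered,
                 params = list(nGenes = nGenes, nPathways = nPathways,
                               nHubs = nHubs, hubRate = hubRate,
                               backgroundRate = backgroundRate,
                               nUncovered = nUncovered,
                               nBridges = nBridges),
                 seed = as.integer(seed))
    list(network = net, truth = truth)
}

#' Recovery metrics against planted truth
#'
#' Compares pipeline outputs with the planted structure of a synthetic
#' dataset: adjusted Rand index of a cluster partition against planted
#' modules, hub precision/recall, bridge-gene recall, and community/module
#' agreement. Only the comparisons whose inputs are supplied are computed.
#'
#' @param truth a [SyntheticTruth-class].
#' @param partition optional [ClusterPartition-class] over the planted
#'   genes.
#' @param communities optional [CommunityResult-class].
#' @param hubs optional character vector of detected hub genes.
#' @param bridges optional character vector of detected bridge genes.
#' @return list of metrics (JSON-serializable).
#' @export
recoveryReport <- function(truth, partition = NULL, communities = NULL,
                           hubs = NULL, bridges = NULL) {
    stopifnot(is(truth, "SyntheticTruth"))
    out <- list(seed = truth@seed)
    if (!is.null(partition)) {
        out$module_ari <- partitionAgreement(truth@modules,
                                             .labelsOf(partition))
    }
    if (!is.null(hubs)) {
        tp <- length(intersect(hubs, truth@hubs))
        out$hub_recall <- if (length(truth@hubs)) tp / length(truth@hubs) else NA
        out$hub_precision <- if (length(hubs)) tp / length(hubs) else NA
    }
    if (!is.null(bridges)) {
        tp <- length(intersect(bridges, truth@bridges))
        out$bridge_recall <-
            if (length(truth@bridges)) tp / length(truth@bridges) else NA
    }
    if (!is.null(communities)) {
        memb <- communityMembership(communities)
        shared <- intersect(names(memb), names(truth@modules))
        if (length(shared))
            out$community_module_ari <-
                partitionAgreement(truth@modules[shared], memb[shared])
        out$modularity <- modularityScore(communities)
    }
    out
}
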