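# catalog with signaling and non-signaling pathway terms over 30 genes
networkFixture <- function() {
    universe <- paste0("G", 1:30)
    AnnotationCatalog(
        c("hsa04390:Hippo signaling pathway",
          "WNT SIGNALING",
          "hsa04110:cell cycle",
          "p53 signaling pathway"),
        "KEGG_PATHWAY",
        list(paste0("G", 1:6), paste0("G", 4:9), paste0("G", 1:8),
             paste0("G", c(9, 10))),
        universe = universe)
}

test_that("signaling pathways are selected by substring, case-insensitive", {
    catalog <- networkFixture()
    tab <- enrichCatalog(paste0("G", 1:10), catalog, alpha = 1)
    sel <- selectSignalingPathways(tab)
    expect_setequal(sel, c("hsa04390:Hippo signaling pathway",
                           "WNT SIGNALING", "p53 signaling pathway"))
    expect_false("hsa04110:cell cycle" %in% sel)
    # non-pathway categories never qualify
    goCat <- AnnotationCatalog("tor signaling", "GOTERM_BP_DIRECT",
                               list(paste0("G", 1:5)),
                               universe = paste0("G", 1:30))
    goTab <- enrichCatalog(paste0("G", 1:5), goCat, alpha = 1)
    expect_error(selectSignalingPathways(goTab), "signaling")
})

test_that("bipartite network holds memberships and drops unconnected genes", {
    catalog <- networkFixture()
    net <- buildBipartite(c("hsa04390:Hippo signaling pathway",
                            "WNT SIGNALING"),
                          catalog, paste0("G", c(1:9, 25)))
    expect_setequal(networkPathways(net),
                    c("hsa04390:Hippo signaling pathway", "WNT SIGNALING"))
    expect_setequal(networkGenes(net), paste0("G", 1:9))   # G25 excluded
    # two pathways sharing one gene, one annotated gene -> 3 nodes, 2 edges
    small <- AnnotationCatalog(c("P1", "P2"), "KEGG_PATHWAY",
                               list("G1", "G1"), universe = paste0("G", 1:5))
    net2 <- buildBipartite(c("P1", "P2"), small, "G1")
    expect_equal(nrow(membershipEdges(net2)), 2L)
    expect_equal(igraph::vcount(asIgraph(net2)), 3L)
    # bipartiteness: the graph 2-colors by construction
    expect_true(igraph::bipartite_mapping(asIgraph(net))$res)
})

test_that("hub threshold interpolates order statistics; hubs are strict", {
    degrees <- stats::setNames(1:10, letters[1:10])
    expect_equal(hubThreshold(degrees, 90), 9.1)
    expect_identical(hubGenes(degrees, 9.1), "j")
    # all degrees equal: threshold equals the degree, no hub
    flat <- stats::setNames(rep(4, 8), letters[1:8])
    expect_equal(hubThreshold(flat, 95), 4)
    expect_length(hubGenes(flat, 4), 0)
})

test_that("uncovered pathways and bridge genes follow membership topology", {
    # P1{g1,g2}, P2{g3}; hub g1 -> P2 uncovered
    catalog <- AnnotationCatalog(c("P1", "P2"), "KEGG_PATHWAY",
                                 list(c("g1", "g2"), "g3"),
                                 universe = paste0("g", 1:5))
    net <- buildBipartite(c("P1", "P2"), catalog, paste0("g", 1:5))
    expect_identical(uncoveredPathways(net, "G1"), "P2")
    expect_identical(uncoveredPathways(net, character()), c("P1", "P2"))
    expect_length(uncoveredPathways(net, c("G1", "G3")), 0)
    # g3 has degree 1: P2 stays isolated, no bridge
    br <- bridgeGenes(net, "P2")
    expect_length(br$genes, 0)
    expect_identical(br$isolated, "P2")
    # give g3 a second membership: it becomes the bridge
    catalog2 <- AnnotationCatalog(c("P1", "P2"), "KEGG_PATHWAY",
                                  list(c("g1", "g2", "g3"), c("g3", "g4")),
                                  universe = paste0("g", 1:5))
    net2 <- buildBipartite(c("P1", "P2"), catalog2, paste0("g", 1:5))
    br2 <- bridgeGenes(net2, "P2")
    expect_identical(br2$genes, "G3")
    expect_identical(br2$connected, "P2")
    # conservation: covered + uncovered = all pathways
    unc <- uncoveredPathways(net2, "G1")
    expect_setequal(c(unc, setdiff(networkPathways(net2), unc)),
                    networkPathways(net2))
    expect_error(uncoveredPathways(net2, "NOT_A_GENE"), "outside")
})

test_that("gene projection counts shared pathways", {
    catalog <- AnnotationCatalog(paste0("P", 1:3), "KEGG_PATHWAY",
                                 list(c("g1", "g2"), c("g1", "g2"),
                                      c("g1", "g2", "g3")),
                                 universe = paste0("g", 1:6))
    net <- buildBipartite(paste0("P", 1:3), catalog, paste0("g", 1:6))
    gg <- projectGenes(net)
    g <- asIgraph(gg)
    w12 <- igraph::E(g)[igraph::V(g)["G1"] %--% igraph::V(g)["G2"]]$weight
    expect_equal(w12, 3)
    w13 <- igraph::E(g)[igraph::V(g)["G1"] %--% igraph::V(g)["G3"]]$weight
    expect_equal(w13, 1)
    # star pathway of m genes projects to a unit-weight clique
    star <- AnnotationCatalog("P1", "KEGG_PATHWAY",
                              list(paste0("g", 1:5)),
                              universe = paste0("g", 1:6))
    sg <- asIgraph(projectGenes(
        buildBipartite("P1", star, paste0("g", 1:5))))
    expect_equal(igraph::ecount(sg), choose(5, 2))
    expect_true(all(igraph::E(sg)$weight == 1))
    # genes sharing no pathway are unlinked
    disj <- AnnotationCatalog(c("P1", "P2"), "KEGG_PATHWAY",
                              list("g1", "g2"), universe = paste0("g", 1:6))
    dg <- asIgraph(projectGenes(
        buildBipartite(c("P1", "P2"), disj, paste0("g", 1:6))))
    expect_equal(igraph::ecount(dg), 0)
})

test_that("modularity matches closed forms and the naive double sum", {
    cl2 <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
    igraph::V(cl2)$name <- paste0("g", 1:8)
    igraph::E(cl2)$weight <- 1
    byComp <- stats::setNames(rep(1:2, each = 4), paste0("g", 1:8))
    expect_equal(modularityQ(cl2, byComp), 0.5)
    expect_equal(modularityQ(cl2, stats::setNames(rep(1, 8),
                                                  paste0("g", 1:8))), 0)
    # random weighted graphs vs the naive formula and igraph
    for (seed in 1:5) {
        adj <- withr::with_seed(seed, {
            a <- matrix(0, 12, 12)
            idx <- which(upper.tri(a))
            a[sample(idx, 25)] <- sample(1:4, 25, TRUE)
            a + t(a)
        })
        dimnames(adj) <- list(paste0("g", 1:12), paste0("g", 1:12))
        g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                                 weighted = TRUE)
        comm <- withr::with_seed(seed + 100,
            stats::setNames(sample(1:3, 12, TRUE), paste0("g", 1:12)))
        q <- modularityQ(g, comm)
        expect_equal(q, oracleModularity(adj, comm), tolerance = 1e-12)
        expect_equal(q, igraph::modularity(g, comm,
                                           weights = igraph::E(g)$weight),
                     tolerance = 1e-12)
    }
    expect_error(modularityQ(cl2, byComp[1:5]), "missing")
})

test_that("Louvain recovers bridged cliques at the exhaustive optimum", {
    g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
    g <- igraph::add_edges(g, c(1, 5))
    igraph::V(g)$name <- paste0("g", 1:8)
    igraph::E(g)$weight <- 1
    res <- louvainCommunities(new("GeneGraph", graph = g), seed = 1)
    memb <- communityMembership(res)
    expect_equal(length(unique(memb)), 2L)
    expect_equal(length(unique(memb[paste0("g", 1:4)])), 1L)
    expect_equal(length(unique(memb[paste0("g", 5:8)])), 1L)
    expect_equal(modularityScore(res), 11 / 26, tolerance = 1e-4) # 0.4231
    # exhaustive search over all 4140 partitions of the 8 nodes
    adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
    best <- max(vapply(allPartitions(8),
                       function(p) oracleModularity(adj, p), numeric(1)))
    expect_equal(modularityScore(res), best, tolerance = 1e-12)
    # single complete graph collapses to one community
    kg <- igraph::make_full_graph(5)
    igraph::V(kg)$name <- paste0("g", 1:5); igraph::E(kg)$weight <- 1
    one <- louvainCommunities(new("GeneGraph", graph = kg), seed = 1)
    expect_equal(length(unique(communityMembership(one))), 1L)
    # edgeless graph: all singletons, Q = 0
    eg <- igraph::make_empty_graph(3, directed = FALSE)
    igraph::V(eg)$name <- paste0("g", 1:3)
    iso <- louvainCommunities(new("GeneGraph", graph = eg), seed = 1)
    expect_equal(length(unique(communityMembership(iso))), 3L)
    expect_equal(modularityScore(iso), 0)
})

test_that("planted two-block gene graphs are recovered across seeds", {
    blockGraph <- function() {
        adj <- matrix(0, 20, 20,
                      dimnames = list(paste0("g", 1:20), paste0("g", 1:20)))
        adj[1:10, 1:10] <- 5; adj[11:20, 11:20] <- 5
        adj[1, 11] <- adj[11, 1] <- 1
        diag(adj) <- 0
        igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            weighted = TRUE)
    }
    truthLabels <- stats::setNames(rep(1:2, each = 10), paste0("g", 1:20))
    for (seed in 1:20) {
        res <- louvainCommunities(new("GeneGraph", graph = blockGraph()),
                                  seed = seed)
        expect_equal(partitionAgreement(truthLabels,
                                        communityMembership(res)), 1)
    }
})

test_that("network summary is internally consistent on synthetic data", {
    sim <- simulatePathwayMembership(seed = 12)
    s <- summarizeNetwork(sim$network, seed = 1)
    expect_equal(s$n_pathways, s$n_covered + length(s$uncovered))
    expect_true(all(s$bridges %in% networkGenes(sim$network)))
    expect_gte(s$min_degree, 1)
    expect_lte(s$max_degree, s$n_pathways)
    q <- modularityQ(projectGenes(sim$network),
                     communityMembership(s$communities))
    expect_equal(modularityScore(s$communities), q, tolerance = 1e-12)
})
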