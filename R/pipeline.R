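#' Pipeline configuration
#'
#' Validated configuration object gathering the free parameters of the
#' whole analysis: the significance threshold alpha, the enrichment
#' method, the dendrogram cut height h, the hub percentile, the
#' term-extraction ubiquity fraction and label count, the Louvain seed and
#' restarts, and the uninformative-term blocklist. Round-trips through
#' JSON unchanged.
#'
#' @param geneListPath,catalogPath,universePath input file paths (universe
#'   optional, `NA` to derive it from the catalog).
#' @param outDir output directory (created if needed).
#' @param alpha raw-p significance threshold, in (0, 1\] (default 0.05).
#' @param method enrichment method, "ease" or "hypergeometric".
#' @param h dendrogram cut height (default 1.15).
#' @param percentile hub percentile (default 95).
#' @param maxFraction term-extraction ubiquity fraction (default 0.6).
#' @param topK labels per cluster (default 20).
#' @param seed seed for the Louvain optimizer (default 1).
#' @param restarts Louvain restarts (default 1).
#' @param blocklist uninformative term names to drop after enrichment.
#' @return a validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(geneListPath, catalogPath,
                           universePath = NA_character_,
                           outDir = "geneModules_out",
                           alpha = 0.05,
                           method = c("ease", "hypergeometric"),
                           h = 1.15, percentile = 95,
                           maxFraction = 0.6, topK = 20,
                           seed = 1, restarts = 1,
                           blocklist = c("disease mutation", "polymorphism",
                                         "sequence variant")) {
    method <- match.arg(method)
    cfg <- list(geneListPath = geneListPath, catalogPath = catalogPath,
                universePath = universePath, outDir = outDir,
                alpha = alpha, method = method, h = h,
                percentile = percentile, maxFraction = maxFraction,
                topK = topK, seed = seed, restarts = restarts,
                blocklist = blocklist)
    .validateConfig(cfg)
    structure(cfg, class = "pipelineConfig")
}

.validateConfig <- function(cfg) {
    if (!(cfg$alpha > 0 && cfg$alpha <= 1))
        stop("config: alpha must be in (0, 1]")
    if (!(cfg$maxFraction > 0 && cfg$maxFraction <= 1))
        stop("config: maxFraction must be in (0, 1]")
    if (cfg$h < 0) stop("config: h must be >= 0")
    if (cfg$topK < 1) stop("config: topK must be >= 1")
    if (!(cfg$percentile > 0 && cfg$percentile < 100))
        stop("config: percentile must be in (0, 100)")
    invisible(TRUE)
}

#' Run the full module-derivation pipeline
#'
#' Executes enrichment -> uninformative-term filter -> binary annotation
#' matrix -> Jaccard distances -> Ward linkage -> height cut -> weighted
#' term extraction, and (when the catalog contains significant signaling
#' pathways) the bipartite network analysis with hubs, bridges, and
#' Louvain communities. Every stage logs its parameters; all artifacts are
#' written under the configured output directory, and the returned
#' manifest lists each file with its md5 checksum. Deterministic given the
#' configured seed.
#'
#' @param config a [pipelineConfig()] object.
#' @param quiet suppress stage logging (default FALSE).
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest` (data.frame of file, md5).
#' @export
runPipeline <- function(config, quiet = FALSE) {
    stopifnot(inherits(config, "pipelineConfig"))
    .validateConfig(config)
    log <- function(...) if (!quiet) message("[geneModules] ", ...)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

    log("config: ", jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
    genes <- stage("read", readGeneList(config$geneListPath))
    universe <- if (is.na(config$universePath)) NULL else
        stage("read", readUniverse(config$universePath))
    catalog <- stage("read", readGMT(config$catalogPath, universe = universe))

    log("enrichment: ", length(genes), " genes, ",
        length(termIds(catalog)), " terms, method=", config$method,
        ", alpha=", config$alpha)
    enr <- stage("enrichment",
                 enrichCatalog(genes, catalog, method = config$method,
                               alpha = config$alpha))
    enr <- stage("enrichment", filterUninformative(enr, config$blocklist))
    log("enrichment: ", sum(enr@results$significant), " significant terms")

    log("clustering: building matrix, Jaccard distances, Ward linkage")
    amat <- stage("clustering", buildAnnotationMatrix(genes, enr, catalog))
    hc <- stage("clustering", wardLinkage(jaccardDistances(amat)))
    partition <- stage("clustering", cutAtHeight(hc, config$h))
    log("clustering: h=", config$h, " -> k=", partition@k, " clusters")

    log("term extraction: maxFraction=", config$maxFraction,
        ", topK=", config$topK)
    counts <- stage("term extraction", countTermsByCluster(amat, partition))
    kept <- stage("term extraction",
                  filterUbiquitous(counts, config$maxFraction))
    labels <- stage("term extraction",
                    extractClusterLabels(amat, partition, termWeights(kept),
                                         k = config$topK))

    network <- NULL; summary <- NULL; projection <- NULL
    sigPaths <- tryCatch(selectSignalingPathways(enr), error = function(e) {
        log("network: skipped (", conditionMessage(e), ")")
        NULL
    })
    if (!is.null(sigPaths)) {
        log("network: ", length(sigPaths), " signaling pathways")
        network <- stage("network", buildBipartite(sigPaths, catalog, genes))
        projection <- stage("network", projectGenes(network))
        summary <- stage("network",
                         summarizeNetwork(network,
                                          percentile = config$percentile,
                                          seed = config$seed,
                                          restarts = config$restarts))
        log("network: ", summary$n_genes, " genes, ", summary$n_pathways,
            " pathways, ", length(summary$hubs), " hubs, Q=",
            format(modularityScore(summary$communities), digits = 4))
    }

    out <- file.path(config$outDir, c(
        enrichment = "enrichment.tsv", matrix = "annotation_matrix.tsv",
        partition = "clusters.tsv", dendrogram = "dendrogram.nwk",
        terms = "cluster_terms.tsv", summary = "cluster_summary.tsv"))
    names(out) <- c("enrichment", "matrix", "partition", "dendrogram",
                    "terms", "summary")
    writeEnrichmentTable(enr, out["enrichment"])
    writeAnnotationMatrix(amat, out["matrix"])
    writePartition(partition, out["partition"])
    writeNewick(hc, out["dendrogram"])
    utils::write.table(labels$terms, out["terms"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(labels$summary, out["summary"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(network)) {
        out <- c(out, network = file.path(config$outDir, "network.sif"),
                 projection = file.path(config$outDir, "gene_projection.tsv"),
                 communities = file.path(config$outDir, "communities.tsv"),
                 network_summary = file.path(config$outDir,
                                             "network_summary.json"))
        writeSIF(network, out["network"])
        writeEdgeList(projection, out["projection"])
        writeCommunities(summary$communities, out["communities"])
        netJson <- summary
        netJson$communities <- list(
            n = length(unique(summary$communities@assignments)),
            Q = modularityScore(summary$communities),
            seed = summary$communities@seed)
        jsonlite::write_json(netJson, out["network_summary"],
                             auto_unbox = TRUE, digits = NA)
    }
    manifest <- data.frame(file = unname(out),
                           md5 = unname(tools::md5sum(unname(out))),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(config$outDir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log("done: ", nrow(manifest), " artifacts in ", config$outDir)
    invisible(list(enrichment = enr, matrix = amat, dendrogram = hc,
                   partition = partition, labels = labels,
                   network = network, networkSummary = summary,
                   manifest = manifest))
}
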