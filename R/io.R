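#' Read a gene list
#'
#' One symbol per line (or the first tab-separated field per line).
#' Symbols are normalized; duplicates collapse with a warning.
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
readGeneList <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty gene list file: ", path)
    .normalizeUnique(vapply(strsplit(lines, "\t"), `[[`, character(1), 1L),
                     paste0("gene list '", basename(path), "'"))
}

#' Read a background universe file
#'
#' @param path file with one gene symbol per line.
#' @return character vector of unique symbols.
#' @export
readUniverse <- function(path) readGeneList(path)

#' Read an annotation catalog in GMT format
#'
#' Lines are `term_id <tab> category/description <tab> gene1 <tab> gene2
#' ...` with at least three fields. The second field is used as the
#' category label.
#'
#' @param path GMT file path.
#' @param universe optional background universe; defaults to the union of
#'   all member genes.
#' @return an [AnnotationCatalog-class].
#' @export
readGMT <- function(path, universe = NULL) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty GMT file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("malformed GMT line ", short[1], " in '", basename(path),
             "': fewer than 3 tab-separated fields")
    AnnotationCatalog(
        termIds = vapply(fields, `[[`, character(1), 1L),
        categories = vapply(fields, `[[`, character(1), 2L),
        geneSets = lapply(fields, function(f) f[-(1:2)]),
        universe = if (is.null(universe))
            unique(normalizeGenes(unlist(lapply(fields, `[`, -(1:2)))))
        else universe)
}

#' Write an annotation catalog in GMT format
#'
#' @param catalog an [AnnotationCatalog-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(catalog, path) {
    stopifnot(is(catalog, "AnnotationCatalog"))
    sets <- geneSets(catalog)
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], catalog@termInfo$category[i],
                sort(sets[[i]])), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write an enrichment table as TSV
#'
#' Columns: term_id, category, k, K, n, N, p_value, bh_fdr, significant.
#'
#' @param table an [EnrichmentTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTable <- function(table, path) {
    stopifnot(is(table, "EnrichmentTable"))
    utils::write.table(table@results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a cluster partition as TSV (gene, cluster_id)
#'
#' @param partition a [ClusterPartition-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePartition <- function(partition, path) {
    stopifnot(is(partition, "ClusterPartition"))
    a <- partition@assignments
    utils::write.table(
        data.frame(gene = names(a), cluster_id = unname(a)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write an annotation matrix as TSV
#'
#' Header row of term ids; first column `gene`.
#'
#' @param x an [AnnotationMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAnnotationMatrix <- function(x, path) {
    stopifnot(is(x, "AnnotationMatrix"))
    df <- data.frame(gene = rownames(x@incidence), x@incidence,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths carry the merge heights (ultrametric tree).
#'
#' @param dendrogram an `hclust` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(dendrogram, path) {
    stopifnot(inherits(dendrogram, "hclust"))
    ape::write.tree(ape::as.phylo(dendrogram), file = path)
    invisible(path)
}

#' Export a bipartite network in SIF format
#'
#' Lines are `gene <tab> member_of <tab> pathway`.
#'
#' @param net a [BipartiteNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSIF <- function(net, path) {
    stopifnot(is(net, "BipartiteNetwork"))
    writeLines(paste(net@edges$gene, "member_of", net@edges$pathway,
                     sep = "\t"), path)
    invisible(path)
}

#' Export the gene projection as an edge-list TSV
#'
#' Columns: gene_a, gene_b, weight.
#'
#' @param graph a [GeneGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
    stopifnot(is(graph, "GeneGraph"))
    el <- igraph::as_data_frame(graph@graph, what = "edges")
    names(el) <- c("gene_a", "gene_b", "weight")
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write community assignments as TSV (gene, community_id)
#'
#' @param communities a [CommunityResult-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCommunities <- function(communities, path) {
    stopifnot(is(communities, "CommunityResult"))
    a <- communities@assignments
    utils::write.table(
        data.frame(gene = names(a), community_id = unname(a)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
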