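#' Build the binary gene-by-annotation matrix
#'
#' Incidence matrix over exactly the supplied gene list (rows) and the
#' significant terms of an enrichment table (columns, in table order);
#' an entry is 1 iff the gene is a member of the term's catalog gene set.
#' Genes carrying no significant term keep an all-zero row.
#'
#' @param genes character vector of gene symbols (row order of the matrix).
#' @param table an [EnrichmentTable-class]; only rows flagged significant
#'   contribute columns.
#' @param catalog the [AnnotationCatalog-class] holding term memberships.
#' @return an [AnnotationMatrix-class].
#' @export
buildAnnotationMatrix <- function(genes, table, catalog) {
    stopifnot(is(table, "EnrichmentTable"), is(catalog, "AnnotationCatalog"))
    genes <- .normalizeUnique(genes, "gene list")
    if (length(genes) == 0L) stop("gene list is empty")
    terms <- significantTerms(table)
    if (length(terms) == 0L) stop("no significant terms to build matrix from")
    sets <- geneSets(catalog)
    missing <- setdiff(terms, names(sets))
    if (length(missing))
        stop("enrichment terms absent from catalog: ",
             paste(utils::head(missing, 3), collapse = ", "))
    m <- vapply(terms, function(t) as.integer(genes %in% sets[[t]]),
                integer(length(genes)))
    m <- matrix(m, nrow = length(genes), ncol = length(terms),
                dimnames = list(genes, terms))
    # columns can only be empty if the query used for enrichment differs
    # from `genes`; drop them so the incidence invariant holds
    empty <- colSums(m) == 0L
    if (any(empty)) {
        warning(sum(empty), " significant term(s) with no member in the ",
                "gene list dropped from the matrix", call. = FALSE)
        m <- m[, !empty, drop = FALSE]
        if (ncol(m) == 0L) stop("no term has members in the gene list")
    }
    new("AnnotationMatrix", incidence = m)
}

#' Pairwise Jaccard distances between gene annotation profiles
#'
#' d(i, j) = 1 - |A_i intersect A_j| / |A_i union A_j| on the genes' term
#' sets (matrix rows). Two all-zero profiles are at distance 0 (0/0 is
#' defined as 0, keeping unannotated genes co-clusterable); an empty
#' profile is at distance 1 from any non-empty one.
#'
#' @param x an [AnnotationMatrix-class] or a binary matrix with gene rows.
#' @return a `stats::dist` object over the genes.
#' @export
jaccardDistances <- function(x) {
    m <- if (is(x, "AnnotationMatrix")) x@incidence else as.matrix(x)
    storage.mode(m) <- "double"
    inter <- tcrossprod(m)
    sizes <- rowSums(m)
    union <- outer(sizes, sizes, "+") - inter
    d <- 1 - inter / union
    d[union == 0] <- 0          # both profiles empty
    diag(d) <- 0
    stats::as.dist(d)
}

#' Ward agglomerative clustering of a distance structure
#'
#' Agglomerative hierarchical clustering under the Ward variance-
#' minimization criterion, applied to the supplied dissimilarities through
#' Lance-Williams updates on their squares with square-root merge heights
#' (the semantics of `scipy`'s `linkage(method = "ward")` and of
#' `stats::hclust(method = "ward.D2")`). Deterministic given the input
#' order.
#'
#' @param d a `stats::dist` object (e.g. from [jaccardDistances()]).
#' @return an object of class `hclust` (the dendrogram model: merge table,
#'   heights, leaf order).
#' @export
wardLinkage <- function(d) {
    if (!inherits(d, "dist")) d <- stats::as.dist(d)
    if (attr(d, "Size") < 2L) stop("need at least 2 genes to cluster")
    if (anyNA(d)) stop("distances contain NA/NaN")
    hc <- stats::hclust(d, method = "ward.D2")
    if (is.unsorted(hc$height))
        warning("non-monotone merge heights (ultrametric violation)",
                call. = FALSE)
    hc
}

#' Cut a dendrogram at a height threshold
#'
#' Clusters are the connected leaf groups joined by merges at height <= h.
#' Cluster ids are relabelled to be contiguous in dendrogram leaf order
#' (the leftmost leaf's cluster is 1).
#'
#' @param dendrogram an `hclust` object.
#' @param h non-negative cut height.
#' @return a [ClusterPartition-class].
#' @export
cutAtHeight <- function(dendrogram, h) {
    stopifnot(inherits(dendrogram, "hclust"), is.numeric(h), h >= 0)
    raw <- stats::cutree(dendrogram, h = h)
    .asPartition(raw, dendrogram, h = h)
}

#' Cut a dendrogram into a requested number of clusters
#'
#' @param dendrogram an `hclust` object.
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @return a [ClusterPartition-class] with `cutHeight()` NA.
#' @export
cutIntoK <- function(dendrogram, k) {
    stopifnot(inherits(dendrogram, "hclust"))
    raw <- stats::cutree(dendrogram, k = k)
    .asPartition(raw, dendrogram, h = NA_real_)
}

.asPartition <- function(raw, dendrogram, h) {
    leaves <- dendrogram$labels[dendrogram$order]
    if (is.null(leaves)) leaves <- as.character(dendrogram$order)
    leafOrderIds <- unique(raw[leaves])
    map <- stats::setNames(seq_along(leafOrderIds), leafOrderIds)
    out <- as.integer(map[as.character(raw)])
    names(out) <- names(raw)
    new("ClusterPartition", assignments = out, h = h,
        k = length(unique(out)))
}

#' Principal component reduction of an annotation matrix
#'
#' Centered (uncentered columns removed of their means, no scaling) linear
#' projection onto the leading principal components, with the explained-
#' variance curve used to choose the number of components. Requests beyond
#' the matrix rank are truncated with a warning.
#'
#' @param x an [AnnotationMatrix-class] or numeric matrix (genes in rows).
#' @param nComponents number of components to retain (default 100).
#' @return list with `scores` (genes x components), `explainedVariance`
#'   (per-component variance ratios, non-increasing), and `nComponents`.
#' @export
pcaReduce <- function(x, nComponents = 100) {
    m <- if (is(x, "AnnotationMatrix")) x@incidence else as.matrix(x)
    storage.mode(m) <- "double"
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
    if (nComponents > rank) {
        warning("nComponents = ", nComponents, " exceeds matrix rank (",
                rank, "); truncated", call. = FALSE)
        nComponents <- rank
    }
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    list(scores = pc$x[, seq_len(nComponents), drop = FALSE],
         explainedVariance = ev,
         nComponents = nComponents)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two hard partitions of the same gene
#' set: 1 iff identical up to relabelling, ~0 for independent partitions.
#'
#' @param a,b [ClusterPartition-class] objects or named label vectors over
#'   the same genes.
#' @return the adjusted Rand index (a single number <= 1).
#' @export
partitionAgreement <- function(a, b) {
    a <- .labelsOf(a); b <- .labelsOf(b)
    if (length(a) != length(b) || !setequal(names(a), names(b)))
        stop("partitions are over different gene sets")
    b <- b[names(a)]
    tab <- table(a, b)
    nij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    npairs <- choose(sum(tab), 2)
    expected <- ai * bj / npairs
    denom <- (ai + bj) / 2 - expected
    if (denom == 0) return(1)           # both partitions trivial and equal
    (nij - expected) / denom
}

.labelsOf <- function(p) {
    if (is(p, "ClusterPartition")) return(p@assignments)
    if (is.null(names(p))) stop("partition labels must be named by gene")
    p
}
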