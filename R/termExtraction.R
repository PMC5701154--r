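#' Count annotations per cluster
#'
#' n(a, c) = number of genes of cluster c carrying annotation a (the
#' binary-matrix column sum restricted to the cluster's rows). These counts
#' are the input to the weighted term-extraction statistic.
#'
#' @param x an [AnnotationMatrix-class].
#' @param partition a [ClusterPartition-class] covering exactly the matrix
#'   genes.
#' @return a [ClusterTermCounts-class] (terms x clusters).
#' @export
countTermsByCluster <- function(x, partition) {
    stopifnot(is(x, "AnnotationMatrix"), is(partition, "ClusterPartition"))
    m <- x@incidence
    part <- partition@assignments
    if (!setequal(rownames(m), names(part)))
        stop("matrix genes and partition genes differ")
    part <- part[rownames(m)]
    k <- partition@k
    counts <- vapply(seq_len(k), function(cl)
        colSums(m[part == cl, , drop = FALSE]), numeric(ncol(m)))
    counts <- matrix(as.integer(counts), nrow = ncol(m), ncol = k,
                     dimnames = list(colnames(m), as.character(seq_len(k))))
    new("ClusterTermCounts", counts = counts)
}

#' Cluster presence of each annotation
#'
#' @param counts a [ClusterTermCounts-class].
#' @return named integer vector: number of clusters in which each
#'   annotation appears (count >= 1).
#' @export
clusterPresence <- function(counts) {
    stopifnot(is(counts, "ClusterTermCounts"))
    rowSums(counts@counts >= 1L)
}

#' Drop ubiquitous annotations before term extraction
#'
#' Removes annotations present in too many clusters, increasing the
#' specificity of extracted labels. The default rule retains annotations
#' appearing in strictly fewer than `maxFraction` of the clusters (with 35
#' clusters and the default 0.6: presence <= 20). The alternative rule
#' `"at-most-floor"` retains presence <= floor(maxFraction * k) (with 35
#' clusters: presence <= 21); the two differ by a single presence value.
#'
#' @param counts a [ClusterTermCounts-class].
#' @param maxFraction fraction of clusters above which an annotation is
#'   considered ubiquitous, in (0, 1\].
#' @param rule "fewer-than" (default) or "at-most-floor".
#' @return the filtered [ClusterTermCounts-class].
#' @export
filterUbiquitous <- function(counts, maxFraction = 0.6,
                             rule = c("fewer-than", "at-most-floor")) {
    stopifnot(is(counts, "ClusterTermCounts"),
              maxFraction > 0, maxFraction <= 1)
    rule <- match.arg(rule)
    k <- ncol(counts@counts)
    presence <- clusterPresence(counts)
    keep <- switch(rule,
        "fewer-than" = presence < maxFraction * k,
        "at-most-floor" = presence <= floor(maxFraction * k))
    new("ClusterTermCounts",
        counts = counts@counts[keep, , drop = FALSE])
}

#' Weighted term-extraction statistic
#'
#' w(a, c) = n(a, c) * ln(N_total / n(a, .)): the count of annotation a in
#' cluster c, multiplied by the natural log of the inverse of its relative
#' frequency across all clusters. Annotations spread over many genes are
#' down-weighted (an annotation accounting for every incidence scores 0
#' everywhere); annotations absent from a cluster score 0 there.
#'
#' @param counts a [ClusterTermCounts-class] (normally already passed
#'   through [filterUbiquitous()]; N_total is computed from the counts as
#'   given).
#' @return a [TermWeightTable-class].
#' @export
termWeights <- function(counts) {
    stopifnot(is(counts, "ClusterTermCounts"))
    m <- counts@counts
    na <- rowSums(m)
    total <- sum(na)
    if (total <= 0) stop("no annotation incidences to weight (N_total = 0)")
    w <- m * log(total / na)
    w[m == 0L] <- 0
    new("TermWeightTable", weights = w, counts = m)
}

#' Top-ranked annotations of a cluster
#'
#' The k highest-weight annotations carried by the cluster, descending by
#' weight, ties broken lexicographically by term id.
#'
#' @param weights a [TermWeightTable-class].
#' @param cluster cluster id.
#' @param k maximum number of annotations to return (default 20).
#' @return data.frame (rank, term_id, weight, n_in_cluster).
#' @export
topTerms <- function(weights, cluster, k = 20) {
    stopifnot(is(weights, "TermWeightTable"), k >= 1)
    cl <- as.character(cluster)
    if (!cl %in% colnames(weights@weights))
        stop("unknown cluster id: ", cluster)
    w <- weights@weights[, cl]
    n <- weights@counts[, cl]
    present <- n >= 1L
    w <- w[present]; n <- n[present]
    ord <- order(-w, names(w))
    ord <- ord[seq_len(min(k, length(ord)))]
    data.frame(rank = seq_along(ord),
               term_id = names(w)[ord],
               weight = unname(w[ord]),
               n_in_cluster = unname(n[ord]),
               stringsAsFactors = FALSE)
}

#' Per-cluster extraction tables and summary
#'
#' Runs [topTerms()] for every cluster and assembles the long table and
#' the one-line-per-cluster summary (size, mapped genes, joined labels).
#'
#' @param x the [AnnotationMatrix-class].
#' @param partition the [ClusterPartition-class].
#' @param weights a [TermWeightTable-class] over the same clusters.
#' @param k labels per cluster (default 20).
#' @return list with `terms` (cluster_id, rank, term_id, weight,
#'   n_in_cluster) and `summary` (cluster_id, size, mapped_genes,
#'   top_terms).
#' @export
extractClusterLabels <- function(x, partition, weights, k = 20) {
    ids <- seq_len(partition@k)
    tops <- lapply(ids, function(cl) {
        tt <- topTerms(weights, cl, k = k)
        cbind(cluster_id = cl, tt)
    })
    terms <- do.call(rbind, tops)
    selected <- lapply(ids, function(cl)
        terms$term_id[terms$cluster_id == cl])
    names(selected) <- ids
    mapped <- mappedGeneCount(x, partition, selected)
    sizes <- table(factor(partition@assignments, levels = ids))
    summary <- data.frame(
        cluster_id = ids,
        size = as.integer(sizes),
        mapped_genes = as.integer(mapped[as.character(ids)]),
        top_terms = vapply(selected, paste, character(1), collapse = ";"),
        stringsAsFactors = FALSE)
    list(terms = terms, summary = summary)
}

#' Genes mapped by the selected annotations of their cluster
#'
#' For each cluster, counts member genes carrying at least one of the
#' cluster's selected (extracted) annotations; always bounded by the
#' cluster size.
#'
#' @param x the [AnnotationMatrix-class].
#' @param partition the [ClusterPartition-class].
#' @param selected named list (by cluster id) of selected term ids.
#' @return named integer vector of mapped-gene counts per cluster.
#' @export
mappedGeneCount <- function(x, partition, selected) {
    stopifnot(is(x, "AnnotationMatrix"), is(partition, "ClusterPartition"))
    m <- x@incidence
    part <- partition@assignments[rownames(m)]
    bad <- setdiff(unique(unlist(selected)), colnames(m))
    if (length(bad))
        stop("selected terms absent from matrix: ",
             paste(utils::head(bad, 3), collapse = ", "))
    out <- vapply(seq_len(partition@k), function(cl) {
        sel <- selected[[as.character(cl)]]
        rows <- m[part == cl, sel, drop = FALSE]
        sum(rowSums(rows) >= 1L)
    }, integer(1))
    stats::setNames(out, as.character(seq_len(partition@k)))
}
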