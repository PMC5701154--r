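#' Upper-tail hypergeometric probability
#'
#' Computes P(X >= k) where X ~ Hypergeometric(N, K, n): the probability of
#' drawing at least `k` members of a term of size `K` when sampling a query
#' of size `n` without replacement from a universe of size `N`. This is the
#' one-sided Fisher exact p-value of the 2x2 overlap table. Arguments are
#' recycled to a common length.
#'
#' @param k overlap count(s), 0 <= k <= min(K, n).
#' @param K term size(s) in the universe.
#' @param n query size(s) in the universe.
#' @param N universe size(s).
#' @return numeric vector of upper-tail probabilities in \[0, 1\].
#' @seealso [easeScore()] for the conservative jackknifed variant.
#' @export
#' @examples
#' hypergeometricTail(3, 4, 5, 20)   # 496/15504
hypergeometricTail <- function(k, K, n, N) {
    args <- .recycleCounts(k = k, K = K, n = n, N = N)
    with(args, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' EASE score (jackknifed Fisher exact test)
#'
#' The conservative enrichment statistic popularized by the DAVID/EASE
#' tools: the overlap cell of the 2x2 table is reduced by one (the three
#' other cells are unchanged, margins recomputed from the cells) before
#' taking the one-sided Fisher upper tail. Penalizes terms supported by a
#' single gene: an overlap of 1 always scores 1.
#'
#' @inheritParams hypergeometricTail
#' @return numeric vector of EASE p-values; always >=
#'   `hypergeometricTail(k, K, n, N)`.
#' @export
#' @examples
#' easeScore(3, 4, 5, 20)   # 376/3876
easeScore <- function(k, K, n, N) {
    args <- .recycleCounts(k = k, K = K, n = n, N = N)
    if (any(args$k < 1))
        stop("EASE requires k >= 1 (the overlap cell is reduced by one); ",
             "use hypergeometricTail() for k = 0", call. = FALSE)
    # reduced table: a = k-1, b = K-k, c = n-k, d = N-K-n+k
    # margins: term size K-1, query size n-1, universe N-1
    with(args, stats::phyper(k - 2, K - 1, N - K, n - 1, lower.tail = FALSE))
}

.recycleCounts <- function(k, K, n, N) {
    .checkCount(k, "k"); .checkCount(K, "K")
    .checkCount(n, "n"); .checkCount(N, "N")
    len <- max(length(k), length(K), length(n), length(N))
    k <- rep_len(k, len); K <- rep_len(K, len)
    n <- rep_len(n, len); N <- rep_len(N, len)
    if (any(K > N)) stop("invalid counts: K > N (term larger than universe)",
                         call. = FALSE)
    if (any(n > N)) stop("invalid counts: n > N (query larger than universe)",
                         call. = FALSE)
    if (any(k > K)) stop("invalid counts: k > K (overlap exceeds term size)",
                         call. = FALSE)
    if (any(k > n)) stop("invalid counts: k > n (overlap exceeds query size)",
                         call. = FALSE)
    list(k = k, K = K, n = n, N = N)
}

#' Annotation enrichment of a query gene list
#'
#' Tests every catalog term for over-representation in the query list
#' relative to the catalog's background universe, using either the EASE
#' score (default, matching the behaviour of the DAVID functional
#' annotation tool) or the plain one-sided hypergeometric test. Terms with
#' zero overlap are suppressed. No multiple-testing correction is applied
#' to the significance call (the flag is `p_value < alpha` on raw
#' p-values); a Benjamini-Hochberg FDR column is included for information.
#'
#' @param query character vector of query gene symbols. Genes outside the
#'   universe are dropped with a warning.
#' @param catalog an [AnnotationCatalog-class].
#' @param method "ease" (default) or "hypergeometric".
#' @param alpha raw-p significance threshold (default 0.05).
#' @return an [EnrichmentTable-class], sorted ascending by p-value.
#' @export
#' @examples
#' cat <- AnnotationCatalog("T1", "GO", list(paste0("G", 1:4)),
#'                          universe = paste0("G", 1:20))
#' enrichCatalog(paste0("G", 1:5), cat, method = "hypergeometric")
enrichCatalog <- function(query, catalog,
                          method = c("ease", "hypergeometric"),
                          alpha = 0.05) {
    method <- match.arg(method)
    stopifnot(is(catalog, "AnnotationCatalog"))
    if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha > 1)
        stop("alpha must be a single value in [0, 1]")
    universe <- geneUniverse(catalog)
    query <- .normalizeUnique(query, "query")
    outside <- setdiff(query, universe)
    if (length(outside)) {
        warning(length(outside), " query gene(s) outside the universe ",
                "dropped: ", paste(utils::head(outside, 5), collapse = ", "),
                if (length(outside) > 5) ", ...", call. = FALSE)
        query <- intersect(query, universe)
    }
    if (length(query) == 0L)
        stop("query is empty after intersection with the universe")
    n <- length(query)
    N <- length(universe)
    K <- lengths(catalog@geneSets)
    k <- vapply(catalog@geneSets,
                function(g) sum(g %in% query), integer(1))
    keep <- k >= 1L
    if (!any(keep))
        stop("no catalog term overlaps the query")
    k <- k[keep]; K <- K[keep]
    p <- switch(method,
        hypergeometric = hypergeometricTail(k, K, n, N),
        ease = easeScore(k, K, n, N))
    res <- data.frame(
        term_id = catalog@termInfo$term_id[keep],
        category = catalog@termInfo$category[keep],
        k = k, K = as.integer(K), n = n, N = N,
        p_value = p,
        bh_fdr = stats::p.adjust(p, method = "BH"),
        significant = p < alpha,
        stringsAsFactors = FALSE)
    ord <- order(res$p_value, res$term_id)
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL
    new("EnrichmentTable", results = res, alpha = alpha, method = method)
}

#' Remove molecularly uninformative annotations
#'
#' Drops enrichment rows whose term id exactly matches a blocklist entry.
#' The default blocklist holds the sequence-feature annotations that
#' describe variation rather than molecular function.
#'
#' @param table an [EnrichmentTable-class].
#' @param blocklist character vector of term names to remove; empty is a
#'   no-op.
#' @return the filtered [EnrichmentTable-class], row order preserved.
#' @export
filterUninformative <- function(table,
                                blocklist = c("disease mutation",
                                              "polymorphism",
                                              "sequence variant")) {
    stopifnot(is(table, "EnrichmentTable"))
    res <- table@results
    res <- res[!(res$term_id %in% blocklist), , drop = FALSE]
    rownames(res) <- NULL
    new("EnrichmentTable", results = res, alpha = table@alpha,
        method = table@method)
}
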