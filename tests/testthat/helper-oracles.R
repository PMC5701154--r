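# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (enumeration, naive recursion, closed form)
# and stays independent of the package code paths it validates.

# upper-tail hypergeometric by exhaustive point-mass summation with
# binomial coefficients
oracleHyperTail <- function(k, K, n, N) {
    j <- k:min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# EASE: build the reduced 2x2 table explicitly, then sum the Fisher tail
oracleEase <- function(k, K, n, N) {
    a <- k - 1; b <- K - k; c <- n - k; d <- N - K - n + k
    Ks <- a + b; ns <- a + c; Ns <- a + b + c + d
    oracleHyperTail(a, Ks, ns, Ns)
}

# naive O(n^3) Ward agglomeration: Lance-Williams on squared
# dissimilarities, sqrt merge heights
oracleWardHeights <- function(d) {
    n <- attr(d, "Size")
    D2 <- as.matrix(d)^2
    sizes <- rep(1, n)
    active <- seq_len(n)
    heights <- numeric(n - 1)
    for (s in seq_len(n - 1)) {
        best <- NULL; bv <- Inf
        for (i in seq_along(active)) for (j in seq_len(i - 1)) {
            v <- D2[active[j], active[i]]
            if (v < bv) { bv <- v; best <- c(active[j], active[i]) }
        }
        heights[s] <- sqrt(bv)
        i <- best[1]; j <- best[2]
        ni <- sizes[i]; nj <- sizes[j]
        for (k in setdiff(active, best)) {
            nk <- sizes[k]
            D2[i, k] <- D2[k, i] <-
                ((ni + nk) * D2[i, k] + (nj + nk) * D2[j, k] - nk * bv) /
                (ni + nj + nk)
        }
        sizes[i] <- ni + nj
        active <- setdiff(active, j)
    }
    heights
}

# all set partitions of 1..n (restricted growth strings)
allPartitions <- function(n) {
    out <- list()
    rec <- function(labels, mx) {
        pos <- length(labels) + 1L
        if (pos > n) { out[[length(out) + 1L]] <<- labels; return() }
        for (v in seq_len(mx + 1L)) rec(c(labels, v), max(mx, v))
    }
    rec(integer(), 0L)
    out
}

# modularity by the naive double sum over node pairs:
# Q = (1/2W) * sum_ij (A_ij - s_i s_j / 2W) delta(c_i, c_j)
oracleModularity <- function(adj, comm) {
    W <- sum(adj) / 2
    s <- rowSums(adj)
    delta <- outer(comm, comm, "==")
    sum((adj - outer(s, s) / (2 * W)) * delta) / (2 * W)
}

# ARI by explicit enumeration of all unordered pairs
oracleARI <- function(a, b) {
    n <- length(a)
    ss <- sd <- ds <- dd <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        sa <- a[i] == a[j]; sb <- b[i] == b[j]
        if (sa && sb) ss <- ss + 1
        else if (sa && !sb) sd <- sd + 1
        else if (!sa && sb) ds <- ds + 1
        else dd <- dd + 1
    }
    npairs <- ss + sd + ds + dd
    expected <- (ss + sd) * (ss + ds) / npairs
    denom <- ((ss + sd) + (ss + ds)) / 2 - expected
    if (denom == 0) return(1)
    (ss - expected) / denom
}

# tiny two-term catalog over a 20-gene universe used in several tests
toyCatalog <- function() {
    AnnotationCatalog(c("T1", "T2"), c("GO", "GO"),
                      list(paste0("G", 1:4), paste0("G", 10:15)),
                      universe = paste0("G", 1:20))
}
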