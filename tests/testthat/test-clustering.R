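makeMatrix <- function(m, genes = paste0("g", seq_len(nrow(m))),
                       terms = paste0("t", seq_len(ncol(m)))) {
    m[1, colSums(m) == 0] <- 1   # enrichment-derived terms are never empty
    dimnames(m) <- list(genes, terms)
    storage.mode(m) <- "integer"
    new("AnnotationMatrix", incidence = m)
}

test_that("annotation matrix is the incidence of significant terms", {
    universe <- paste0("G", 1:20)
    catalog <- AnnotationCatalog(c("A", "B", "C"), "GO",
                                 list(c("G1", "G2"), c("G2", "G3"),
                                      c("G4", "G5")),
                                 universe = universe)
    tab <- enrichCatalog(c("G1", "G2", "G3"), catalog,
                         method = "hypergeometric", alpha = 1)
    m <- buildAnnotationMatrix(c("G1", "G2", "G3"), tab, catalog)
    inc <- incidence(m)
    expect_identical(sort(colnames(inc)), c("A", "B"))  # C has k = 0
    expect_identical(unname(inc[, "A"]), c(1L, 1L, 0L))
    expect_identical(unname(inc[, "B"]), c(0L, 1L, 1L))
    # a gene carrying no significant term keeps an all-zero row
    m4 <- buildAnnotationMatrix(c("G1", "G2", "G3", "G19"), tab, catalog)
    expect_identical(sum(incidence(m4)["G19", ]), 0L)
    expect_error(buildAnnotationMatrix(character(), tab, catalog), "empty")
})

test_that("Jaccard distances follow the binary-profile definition", {
    m <- makeMatrix(rbind(c(1, 1, 1, 0),
                          c(0, 1, 1, 1),
                          c(1, 1, 1, 0),
                          c(0, 0, 0, 0),
                          c(0, 0, 0, 0)))
    d <- as.matrix(jaccardDistances(m))
    expect_equal(d["g1", "g2"], 0.5)        # 1 - 2/4
    expect_equal(d["g1", "g3"], 0)          # identical profiles
    expect_equal(d["g4", "g5"], 0)          # both empty: 0/0 -> 0
    expect_equal(d["g1", "g4"], 1)          # empty vs non-empty
    expect_true(all(diag(d) == 0))
    expect_equal(d, t(d))
    # disjoint non-empty profiles
    m2 <- makeMatrix(rbind(c(1, 0), c(0, 1)))
    expect_equal(as.vector(jaccardDistances(m2)), 1)
})

test_that("Jaccard distance satisfies the triangle inequality", {
    ok <- withr::with_seed(5, {
        vapply(seq_len(10000), function(rep) {
            m <- matrix(rbinom(3 * 12, 1, runif(1, 0.1, 0.9)), nrow = 3)
            d <- as.matrix(jaccardDistances(makeMatrix(m)))
            d[1, 2] <= d[1, 3] + d[3, 2] + 1e-12 &&
                d[1, 3] <= d[1, 2] + d[2, 3] + 1e-12 &&
                d[2, 3] <= d[2, 1] + d[1, 3] + 1e-12
        }, logical(1))
    })
    expect_true(all(ok))
})

test_that("Ward linkage reproduces a naive Lance-Williams agglomeration", {
    # two genes merge at their distance
    d2 <- stats::as.dist(matrix(c(0, 0.4, 0.4, 0), 2,
                                dimnames = list(c("a", "b"), c("a", "b"))))
    expect_equal(wardLinkage(d2)$height, 0.4)
    # separated pairs merge first
    d4 <- matrix(0.9, 4, 4); diag(d4) <- 0
    d4[1, 2] <- d4[2, 1] <- 0.1; d4[3, 4] <- d4[4, 3] <- 0.2
    hc4 <- wardLinkage(stats::as.dist(d4))
    expect_equal(sort(hc4$height[1:2]), c(0.1, 0.2))
    expect_equal(sort(abs(hc4$merge[1, ])), c(1, 2))
    expect_equal(sort(abs(hc4$merge[2, ])), c(3, 4))
    # random binary profiles vs the naive O(n^3) oracle
    for (seed in 1:10) {
        n <- 5 + seed %% 4
        withr::with_seed(seed, {
            m <- matrix(rbinom(n * 12, 1, 0.4), nrow = n)
            d <- jaccardDistances(makeMatrix(m))
            d[] <- d + runif(length(d)) * 1e-7   # break exact ties
        })
        expect_equal(wardLinkage(d)$height, oracleWardHeights(d),
                     tolerance = 1e-9)
    }
    dna <- stats::as.dist(matrix(c(0, NA, NA, 0), 2))
    expect_error(wardLinkage(dna), "NA")
})

test_that("height cuts partition genes and k is monotone in h", {
    d <- withr::with_seed(3, {
        m <- matrix(rbinom(30 * 15, 1, 0.3), nrow = 30)
        d <- jaccardDistances(makeMatrix(m))
        d + runif(length(d)) * 1e-7   # no zero-height merges
    })
    hc <- wardLinkage(d)
    p0 <- cutAtHeight(hc, min(hc$height) * 0.5)
    expect_equal(nClusters(p0), 30L)
    p1 <- cutAtHeight(hc, max(hc$height) + 1)
    expect_equal(nClusters(p1), 1L)
    hs <- seq(0, max(hc$height) + 0.1, length.out = 12)
    ks <- vapply(hs, function(h) nClusters(cutAtHeight(hc, h)), integer(1))
    expect_true(all(diff(ks) <= 0L))
    # every cut is a partition: sizes sum to the gene count,
    # ids contiguous 1..k in leaf order
    for (h in hs[c(3, 6, 9)]) {
        p <- cutAtHeight(hc, h)
        a <- assignments(p)
        expect_equal(length(a), 30L)
        expect_identical(sort(unique(unname(a))), seq_len(nClusters(p)))
        leaves <- hc$labels[hc$order]
        expect_identical(unique(unname(a[leaves])), seq_len(nClusters(p)))
    }
})

test_that("PCA reduction conserves variance and truncates at rank", {
    withr::with_seed(8, {
        m <- matrix(rbinom(25 * 10, 1, 0.4), nrow = 25)
    })
    pc <- pcaReduce(makeMatrix(m), nComponents = 5)
    expect_equal(sum(pc$explainedVariance), 1, tolerance = 1e-9)
    expect_true(all(diff(pc$explainedVariance) <= 1e-12))
    expect_true(all(pc$explainedVariance >= 0 &
                    pc$explainedVariance <= 1))
    # rank-1 matrix: first component carries all the variance
    r1 <- outer(c(rep(1, 6), rep(0, 6)), rep(1, 5))
    pr <- suppressWarnings(pcaReduce(makeMatrix(r1), nComponents = 3))
    expect_equal(pr$explainedVariance[1], 1, tolerance = 1e-9)
    expect_warning(pcaReduce(makeMatrix(m), nComponents = 50), "rank")
})

test_that("adjusted Rand index matches the pair-counting oracle", {
    genes <- paste0("g", 1:20)
    a <- stats::setNames(rep(1:4, each = 5), genes)
    expect_equal(partitionAgreement(a, a), 1)
    singletons <- stats::setNames(1:20, genes)
    one <- stats::setNames(rep(1L, 20), genes)
    expect_equal(partitionAgreement(singletons, one), 0)
    for (seed in 1:10) {
        withr::with_seed(seed, {
            b <- stats::setNames(sample(1:4, 20, replace = TRUE), genes)
            b <- as.integer(factor(b))  # contiguous ids
            names(b) <- genes
        })
        expect_equal(partitionAgreement(a, b), oracleARI(unname(a), unname(b)),
                     tolerance = 1e-12)
    }
    expect_error(partitionAgreement(a, stats::setNames(1:3, paste0("x", 1:3))),
                 "different gene sets")
})

test_that("cross-checked against an independent ARI implementation", {
    genes <- paste0("g", 1:30)
    withr::with_seed(2, {
        a <- stats::setNames(sample(1:5, 30, TRUE), genes)
        b <- stats::setNames(sample(1:3, 30, TRUE), genes)
        a <- stats::setNames(as.integer(factor(a)), genes)
        b <- stats::setNames(as.integer(factor(b)), genes)
    })
    expect_equal(partitionAgreement(a, b),
                 mclust::adjustedRandIndex(unname(a), unname(b)),
                 tolerance = 1e-12)
})

test_that("the partition never depends on the diagnostic embeddings", {
    sim <- simulateAnnotationCatalog(nGenes = 60, nModules = 3,
                                     annotationsPerModule = 10, seed = 4)
    enr <- enrichCatalog(sim$genes, sim$catalog)
    amat <- buildAnnotationMatrix(sim$genes, enr, sim$catalog)
    hc <- wardLinkage(jaccardDistances(amat))
    before <- assignments(cutIntoK(hc, 3))
    pc <- pcaReduce(amat, 10)
    invisible(tsneEmbed(pc$scores, perplexity = 5, seed = 1, maxIter = 50))
    after <- assignments(cutIntoK(wardLinkage(jaccardDistances(amat)), 3))
    expect_identical(before, after)
})
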