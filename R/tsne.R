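#' Two-dimensional t-SNE embedding of PCA scores
#'
#' Exact (dense, O(n^2)) t-distributed stochastic neighbour embedding:
#' per-point Gaussian bandwidths are found by bisection to match
#' log(perplexity) entropy, the joint affinities are symmetrized, and the
#' Student-t low-dimensional map is optimized by momentum gradient descent
#' with early exaggeration. Reproducible under a fixed seed. The embedding
#' is a visual diagnostic of cluster boundaries only and is never used as
#' clustering input.
#'
#' @param scores numeric matrix of input coordinates (genes x components),
#'   typically `pcaReduce(...)$scores`.
#' @param perplexity effective neighbourhood size; must be < number of rows.
#' @param seed integer seed for the random initialization.
#' @param maxIter gradient-descent iterations (default 400).
#' @param eta learning rate (default 100).
#' @return list with `coordinates` (n x 2, rownames preserved),
#'   `perplexity`, `seed`, and `kl` (final KL divergence).
#' @export
tsneEmbed <- function(scores, perplexity = 30, seed = 1, maxIter = 400,
                      eta = 100) {
    x <- as.matrix(scores)
    n <- nrow(x)
    if (perplexity >= n)
        stop("perplexity (", perplexity, ") must be smaller than the ",
             "number of genes (", n, ")")
    P <- .tsneAffinities(x, perplexity)
    withr::with_seed(as.integer(seed), {
        y <- matrix(stats::rnorm(n * 2, sd = 1e-4), ncol = 2)
    })
    gains <- matrix(1, n, 2)
    inc <- matrix(0, n, 2)
    exag <- 4
    stopEarlyExag <- min(100L, maxIter %/% 2L)
    Pe <- P * exag
    momentum <- 0.5
    eps <- .Machine$double.eps
    for (iter in seq_len(maxIter)) {
        if (iter == stopEarlyExag + 1L) Pe <- P
        if (iter == 250L) momentum <- 0.8
        d2 <- .sqDist(y)
        w <- 1 / (1 + d2)
        diag(w) <- 0
        Q <- w / sum(w)
        L <- (Pe - Q) * w
        grad <- 4 * (diag(rowSums(L)) %*% y - L %*% y)
        gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
        gains[gains < 0.01] <- 0.01
        inc <- momentum * inc - eta * gains * grad
        y <- y + inc
        y <- sweep(y, 2, colMeans(y))
    }
    d2 <- .sqDist(y)
    w <- 1 / (1 + d2); diag(w) <- 0
    Q <- pmax(w / sum(w), eps)
    kl <- sum(P[P > 0] * log(P[P > 0] / Q[P > 0]))
    rownames(y) <- rownames(x)
    list(coordinates = y, perplexity = perplexity, seed = as.integer(seed),
         kl = kl)
}

#' Sweep t-SNE over a range of perplexities
#'
#' Convenience wrapper producing one embedding per perplexity value, all
#' from the same seed, for visual stability checks of cluster boundaries.
#'
#' @inheritParams tsneEmbed
#' @param perplexities numeric vector of perplexity values.
#' @return named list of [tsneEmbed()] results, one per perplexity.
#' @export
tsneSweep <- function(scores, perplexities = c(5, 30, 100, 250), seed = 1,
                      maxIter = 400) {
    out <- lapply(perplexities, function(p)
        tsneEmbed(scores, perplexity = p, seed = seed, maxIter = maxIter))
    names(out) <- as.character(perplexities)
    out
}

.sqDist <- function(y) {
    s <- rowSums(y^2)
    d2 <- outer(s, s, "+") - 2 * tcrossprod(y)
    d2[d2 < 0] <- 0
    d2
}

# row-conditional Gaussian affinities at fixed entropy, then symmetrized
.tsneAffinities <- function(x, perplexity) {
    n <- nrow(x)
    d2 <- .sqDist(x)
    logU <- log(perplexity)
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
        di <- d2[i, -i]
        beta <- 1
        betamin <- -Inf; betamax <- Inf
        for (tries in seq_len(64)) {
            p <- exp(-di * beta)
            sp <- sum(p)
            if (sp == 0) { H <- 0; pr <- p }
            else {
                pr <- p / sp
                H <- -sum(pr[pr > 0] * log(pr[pr > 0]))
            }
            if (abs(H - logU) < 1e-5) break
            if (H > logU) {
                betamin <- beta
                beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
            } else {
                betamax <- beta
                beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
            }
        }
        P[i, -i] <- pr
    }
    P <- (P + t(P)) / (2 * n)
    pmax(P, .Machine$double.eps)
}
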