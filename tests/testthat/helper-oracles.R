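# Independent oracles: deliberately naive implementations used only to
# check the package's optimized code paths.

# Per-basepair counting oracle for gene-body state coverage: walks every
# basepair of the gene and looks up its annotation directly.
oracleProfile <- function(seg, gene, backgroundIdx = 15L) {
    gr <- segmentRanges(seg)
    S <- nrow(seg@palette@states)
    chr <- as.character(GenomicRanges::seqnames(gene))
    onChr <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
    counts <- numeric(S)
    for (bp in GenomicRanges::start(gene):GenomicRanges::end(gene)) {
        hit <- which(GenomicRanges::start(onChr) <= bp &
                     GenomicRanges::end(onChr) >= bp)
        st <- if (length(hit) == 1L) S4Vectors::mcols(onChr)$state[hit]
              else backgroundIdx
        counts[st] <- counts[st] + 1
    }
    counts / GenomicRanges::width(gene)
}

# Newton-Raphson maximizer of the binomial log-likelihood (fractional
# response y with trial counts N), written independently of the package's
# IRLS: explicit gradient/Hessian, SVD pseudo-inverse steps.
oracleNRResiduals <- function(y, N, X, iter = 200L) {
    beta <- rep(0, ncol(X))
    for (i in seq_len(iter)) {
        mu <- stats::plogis(as.numeric(X %*% beta))
        mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
        grad <- as.numeric(t(X) %*% (N * (y - mu)))
        H <- t(X) %*% (X * (N * mu * (1 - mu)))
        sv <- svd(H)
        pos <- sv$d > max(sv$d) * 1e-12
        step <- sv$v[, pos, drop = FALSE] %*%
            ((t(sv$u[, pos, drop = FALSE]) %*% grad) / sv$d[pos])
        beta <- beta + as.numeric(step)
        if (max(abs(step)) < 1e-14) break
    }
    mu <- stats::plogis(as.numeric(X %*% beta))
    term <- function(a, b) ifelse(a > 0, a * log(a / b), 0)
    dev <- 2 * N * (term(y, mu) + term(1 - y, 1 - mu))
    sign(y - mu) * sqrt(pmax(dev, 0))
}

# Exhaustive Mann-Whitney oracle: enumerates every assignment of the pooled
# values to the two groups and compares rank sums, mirroring the two-sided
# doubled-tail definition.
oracleMWW <- function(a, b) {
    pool <- c(a, b)
    n <- length(pool)
    r <- rank(pool)
    nA <- length(a)
    wObs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    idx <- utils::combn(n, nA)
    w <- apply(idx, 2, function(i) sum(r[i])) - nA * (nA + 1) / 2
    p <- 2 * min(mean(w <= wObs), mean(w >= wObs))
    min(p, 1)
}

# Hypergeometric upper-tail oracle by explicit enumeration of all tables at
# the fixed margins, using exact binomial coefficients.
oracleHyperTail <- function(a, setSize, querySize, universe) {
    xs <- max(0, querySize + setSize - universe):min(setSize, querySize)
    mass <- vapply(xs, function(x)
        choose(setSize, x) * choose(universe - setSize, querySize - x),
        numeric(1))
    mass <- mass / choose(universe, querySize)
    sum(mass[xs >= a])
}

# Mean-ordered dendrogram oracle: walks the hclust merge tree recursively
# and puts the lower-mean subtree first at every merge.
oracleMeanOrder <- function(hc, wts) {
    rec <- function(node) {
        if (node < 0) return(-node)
        left <- rec(hc$merge[node, 1])
        right <- rec(hc$merge[node, 2])
        if (mean(wts[left]) <= mean(wts[right])) c(left, right)
        else c(right, left)
    }
    rec(nrow(hc$merge))
}

# Exact null probability that the package's two-sided MWW p-value (tie-free
# path) falls below alpha, from the exact rank-sum distribution.
oracleMWWLevel <- function(nA, nB, alpha = 0.05) {
    u <- 0:(nA * nB)
    p <- chromCompare:::.mwwPVec(u, nA, nB, rep(0, length(u)))
    sum(stats::dwilcox(u, nA, nB)[p < alpha])
}
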