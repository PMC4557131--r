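#' @include AllClasses.R AllGenerics.R covariates.R
NULL

.tieSum <- function(r) {
    t <- tabulate(match(r, unique(r)))
    sum(t^3 - t)
}

.mwwP <- function(a, b) {
    r <- rank(c(a, b))
    nA <- length(a); nB <- length(b)
    W <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    .mwwPVec(W, nA, nB, .tieSum(r))
}

# Vectorized two-sided MWW p-values from rank-sum statistics W (one per
# feature column); exact where group sizes allow and the column is tie-free,
# else normal approximation with tie and continuity corrections.
.mwwPVec <- function(W, nA, nB, tieSums) {
    n <- nA + nB
    p <- rep(1, length(W))
    exact <- (nA <= 8L && nB <= 8L) & tieSums == 0
    if (any(exact)) {
        We <- W[exact]
        hi <- We > nA * nB / 2
        pe <- numeric(length(We))
        pe[hi] <- stats::pwilcox(We[hi] - 1, nA, nB, lower.tail = FALSE)
        pe[!hi] <- stats::pwilcox(We[!hi], nA, nB)
        p[exact] <- pmin(2 * pe, 1)
    }
    if (any(!exact)) {
        Wa <- W[!exact]
        sigma <- sqrt((nA * nB / 12) *
                      ((n + 1) - tieSums[!exact] / (n * (n - 1))))
        z <- Wa - nA * nB / 2
        z <- (z - sign(z) * 0.5) / sigma
        pa <- 2 * pmin(stats::pnorm(z),
                       stats::pnorm(z, lower.tail = FALSE))
        pa[sigma == 0] <- 1
        p[!exact] <- pmin(pa, 1)
    }
    p
}

# Vectorized MWW over the columns of a matrix (rows = samples).
.mwwPMatrix <- function(X, idxA, idxB) {
    nA <- length(idxA); nB <- length(idxB)
    sub <- X[c(idxA, idxB), , drop = FALSE]
    R <- apply(sub, 2, rank)
    W <- colSums(R[seq_len(nA), , drop = FALSE]) - nA * (nA + 1) / 2
    tieSums <- apply(R, 2, .tieSum)
    .mwwPVec(W, nA, nB, tieSums)
}

#' Two-group test on one feature
#'
#' The supported tests: the two-sided Mann-Whitney-Wilcoxon rank test
#' ("mww", exact enumeration when both groups have at most 8 values and no
#' ties, else the normal approximation with tie and continuity
#' corrections), Welch's two-sided t-test ("t"), and the two-sided
#' variance-ratio F-test ("f", p = 2 min(tail, 1 - tail)).
#'
#' Because the rank test depends only on value order, its p-values are
#' invariant to any positive rescaling of the inputs.
#'
#' @param a,b numeric value vectors for the two groups.
#' @param test one of "mww", "t", "f".
#' @return two-sided p-value in (0, 1].
#' @examples
#' groupTest(c(1, 2, 3), c(4, 5, 6))  # 0.1 (exact)
#' @export
groupTest <- function(a, b, test = c("mww", "t", "f")) {
    test <- match.arg(test)
    if (length(a) < 1L || length(b) < 1L)
        stop("both groups must be non-empty")
    if (test != "mww" && (length(a) < 2L || length(b) < 2L))
        stop("t/F tests need at least 2 values per group")
    switch(test,
        mww = .mwwP(a, b),
        t = tryCatch(stats::t.test(a, b)$p.value, error = function(e) {
            warning("degenerate t-test (constant data); p = 1")
            1
        }),
        f = stats::var.test(a, b)$p.value)
}

#' Multiple-testing adjustment
#'
#' Bonferroni, Benjamini-Hochberg step-up, or Benjamini-Yekutieli step-up
#' (with the sum(1/i) dependency factor).
#'
#' @param p raw p-values in [0, 1].
#' @param method "bonferroni", "bh" or "by".
#' @return adjusted p-values, monotone in the raw values, capped at 1.
#' @export
adjustPvalues <- function(p, method = c("bh", "by", "bonferroni")) {
    method <- match.arg(method)
    if (length(p) == 0L) return(numeric(0))
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = c(bh = "BH", by = "BY",
                                  bonferroni = "bonferroni")[method])
}

#' Compare two groups of epigenomes across all features
#'
#' Tests every feature column of a (corrected) feature matrix between the
#' two groups, adjusts the p-values over all tested features (constant
#' columns included in m), and flags features with adjusted p below alpha
#' as significant. Genes owning at least one significant feature are the
#' distinguishing genes.
#'
#' @param cm a [CorrectedMatrix-class] (or raw [FeatureMatrix-class], e.g.
#'   to assess the uncorrected pipeline).
#' @param spec a [GroupSpec-class]; all its ids must be rows of \code{cm}.
#' @param test,correction see [groupTest()] and [adjustPvalues()].
#' @param alpha significance cutoff on adjusted p.
#' @return a [ComparisonResult-class].
#' @export
compareGroups <- function(cm, spec, test = c("mww", "t", "f"),
                          correction = c("bh", "by", "bonferroni"),
                          alpha = 0.05) {
    test <- match.arg(test)
    correction <- match.arg(correction)
    if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
    X <- cm@values
    missing <- setdiff(c(spec@idsA, spec@idsB), rownames(X))
    if (length(missing) > 0L)
        stop("epigenomes absent from the matrix: ",
             paste(missing, collapse = ", "))
    idxA <- match(spec@idsA, rownames(X))
    idxB <- match(spec@idsB, rownames(X))
    if (test != "mww" && (length(idxA) < 2L || length(idxB) < 2L))
        stop("t/F tests need at least 2 epigenomes per group")
    p <- if (test == "mww") {
        .mwwPMatrix(X, idxA, idxB)
    } else {
        vapply(seq_len(ncol(X)), function(j)
            groupTest(X[idxA, j], X[idxB, j], test), numeric(1))
    }
    padj <- adjustPvalues(p, correction)
    medA <- apply(X[idxA, , drop = FALSE], 2, stats::median)
    medB <- apply(X[idxB, , drop = FALSE], 2, stats::median)
    tab <- data.frame(
        feature = colnames(X), gene = cm@geneIds, state = cm@stateIndex,
        p = p, p_adj = padj, direction = sign(medB - medA),
        significant = padj < alpha, stringsAsFactors = FALSE)
    new("ComparisonResult", table = tab, alpha = alpha, test = test,
        correction = correction, spec = spec)
}

setMethod("resultTable", "ComparisonResult", function(x) x@table)

setMethod("significantFeatures", "ComparisonResult",
    function(x) x@table$feature[x@table$significant])

setMethod("distinguishingGenes", "ComparisonResult",
    function(x) unique(x@table$gene[x@table$significant]))

setMethod("show", "ComparisonResult", function(object) {
    cat(sprintf(
        "ComparisonResult (%s, %s vs %s): %d/%d significant features, %d genes (%s, %s, alpha=%g)\n",
        object@spec@property, object@spec@traitA, object@spec@traitB,
        sum(object@table$significant), nrow(object@table),
        length(distinguishingGenes(object)), object@test,
        object@correction, object@alpha))
})

#' Per-gene summary of a comparison
#'
#' @param result a [ComparisonResult-class].
#' @return data.frame of distinguishing genes: gene, number of significant
#'   features, minimum adjusted p, significant-state list; ranked by
#'   (n features desc, min adjusted p asc).
#' @export
distinguishingGeneTable <- function(result) {
    tab <- result@table[result@table$significant, , drop = FALSE]
    if (nrow(tab) == 0L)
        return(data.frame(gene = character(0), n_features = integer(0),
                          min_p_adj = numeric(0), states = character(0),
                          stringsAsFactors = FALSE))
    mnem <- result@spec  # silence lint; states reported numerically
    sp <- split(tab, tab$gene)
    out <- data.frame(
        gene = names(sp),
        n_features = vapply(sp, nrow, integer(1)),
        min_p_adj = vapply(sp, function(d) min(d$p_adj), numeric(1)),
        states = vapply(sp, function(d)
            paste(sort(d$state), collapse = ","), character(1)),
        stringsAsFactors = FALSE)
    out[order(-out$n_features, out$min_p_adj, out$gene), , drop = FALSE]
}

#' Write a per-feature comparison table to TSV
#' @param result a [ComparisonResult-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeComparisonResult <- function(result, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#feature\tgene\tstate\tp\tp_adj\tdirection\tsignificant",
               con)
    t <- result@table
    writeLines(sprintf("%s\t%s\t%d\t%.17g\t%.17g\t%g\t%s", t$feature,
                       t$gene, t$state, t$p, t$p_adj, t$direction,
                       ifelse(t$significant, "TRUE", "FALSE")), con)
    invisible(path)
}
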