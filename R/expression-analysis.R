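#' @include AllClasses.R comparison.R
NULL

#' Per-gene differential expression between two groups
#'
#' Two-sided Mann-Whitney-Wilcoxon test of expression values (RPKM or
#' covariate-corrected residuals) between the groups for every requested
#' gene, with Benjamini-Hochberg correction across the tested genes; a gene
#' is differentially expressed (DE) when its adjusted p is below alpha.
#' Epigenomes without expression data are excluded; genes absent from the
#' matrix are flagged \code{no_data} and do not count towards m.
#'
#' @param expr numeric matrix, genes x epigenomes.
#' @param spec a [GroupSpec-class].
#' @param genes gene ids to test; default all matrix rows.
#' @param alpha DE cutoff on adjusted p.
#' @return data.frame: gene, p, p_adj, de, no_data.
#' @export
differentialExpression <- function(expr, spec, genes = rownames(expr),
                                   alpha = 0.05) {
    idsA <- intersect(spec@idsA, colnames(expr))
    idsB <- intersect(spec@idsB, colnames(expr))
    if (length(idsA) < 1L || length(idsB) < 1L)
        stop("need expression data for at least one epigenome per group")
    present <- genes %in% rownames(expr)
    tested <- genes[present]
    p <- if (length(tested) > 0L)
        .mwwPMatrix(t(expr[tested, c(idsA, idsB), drop = FALSE]),
                    seq_along(idsA), length(idsA) + seq_along(idsB))
    else numeric(0)
    padj <- adjustPvalues(p, "bh")
    out <- data.frame(gene = genes, p = NA_real_, p_adj = NA_real_,
                      de = FALSE, no_data = !present,
                      stringsAsFactors = FALSE)
    out$p[present] <- p
    out$p_adj[present] <- padj
    out$de[present] <- padj < alpha
    out
}

#' Proportion of DE genes inside and outside a gene list
#'
#' Splits a differential-expression table by membership in a gene list
#' (e.g. the distinguishing genes of a comparison) and returns the 2x2
#' counts feeding [logOddsRatio()]: a = in-list & DE, b = in-list & not DE,
#' c = out-of-list & DE, d = neither. Genes without expression data are
#' dropped first.
#'
#' @param de data.frame from [differentialExpression()].
#' @param geneList gene ids defining the "in-list" margin.
#' @return list with counts (a, b, c, d), proportions in/out of list, and
#'   the number of genes dropped for missing data.
#' @export
deProportions <- function(de, geneList) {
    kept <- de[!de$no_data, , drop = FALSE]
    inList <- kept$gene %in% geneList
    a <- sum(inList & kept$de); b <- sum(inList & !kept$de)
    c_ <- sum(!inList & kept$de); d <- sum(!inList & !kept$de)
    list(counts = c(a = a, b = b, c = c_, d = d),
         propIn = if (a + b > 0) a / (a + b) else NA_real_,
         propOut = if (c_ + d > 0) c_ / (c_ + d) else NA_real_,
         nDropped = sum(de$no_data))
}

#' Pooled expression difference of a gene group
#'
#' Pools all (gene, epigenome) expression values of the group's genes into
#' one sample per epigenome group and applies a single two-sided
#' Mann-Whitney-Wilcoxon test — the cluster-level expression check used for
#' annotated gene clusters.
#'
#' @param clusterGenes gene ids of the cluster.
#' @param expr numeric matrix, genes x epigenomes.
#' @param spec a [GroupSpec-class].
#' @return two-sided p-value.
#' @export
clusterExpressionTest <- function(clusterGenes, expr, spec) {
    if (length(clusterGenes) == 0L) stop("empty gene cluster")
    g <- intersect(clusterGenes, rownames(expr))
    idsA <- intersect(spec@idsA, colnames(expr))
    idsB <- intersect(spec@idsB, colnames(expr))
    a <- as.numeric(expr[g, idsA, drop = FALSE])
    b <- as.numeric(expr[g, idsB, drop = FALSE])
    if (length(a) == 0L || length(b) == 0L)
        stop("no pooled expression values for one group")
    groupTest(a, b, "mww")
}

#' Log odds ratio linking two gene classifications
#'
#' For counts a (distinguishing & DE), b (distinguishing & not DE), c
#' (non-distinguishing & DE) and d (neither): ln(OR) = ln(ad / bc), standard
#' error sqrt(1/a + 1/b + 1/c + 1/d), 95\% CI lnOR +/- 1.96 SE, z =
#' |lnOR| / SE. The association is significant when 0 lies outside the CI.
#' The reported p-value uses the printed approximation
#' exp(-0.717 z - 0.416 z^2); the exact two-sided normal p is attached as
#' \code{pNormal}. Any zero cell triggers the Haldane-Anscombe +0.5
#' correction on all cells (flagged); two zero cells in one row or column
#' leave the odds ratio undefined and raise an error.
#'
#' @param a,b,c,d non-negative counts.
#' @return an [OddsRatioResult-class].
#' @examples
#' logOddsRatio(10, 10, 5, 20)  # lnOR = ln 4, SE = sqrt(0.45)
#' @export
logOddsRatio <- function(a, b, c, d) {
    cnt <- c(a = a, b = b, c = c, d = d)
    if (any(cnt < 0)) stop("counts must be non-negative")
    zero <- cnt == 0
    if ((zero["a"] && zero["b"]) || (zero["c"] && zero["d"]) ||
        (zero["a"] && zero["c"]) || (zero["b"] && zero["d"]))
        stop("two empty cells in one margin: odds ratio undefined")
    haldane <- any(zero)
    if (haldane) cnt <- cnt + 0.5
    lnOR <- log(cnt["a"] * cnt["d"] / (cnt["b"] * cnt["c"]))
    se <- sqrt(sum(1 / cnt))
    z <- abs(lnOR) / se
    new("OddsRatioResult", counts = cnt, lnOR = unname(lnOR),
        se = unname(se), ciLow = unname(lnOR - 1.96 * se),
        ciHigh = unname(lnOR + 1.96 * se), z = unname(z),
        p = unname(exp(-0.717 * z - 0.416 * z^2)),
        pNormal = unname(2 * stats::pnorm(-z)), haldane = haldane)
}

setMethod("show", "OddsRatioResult", function(object) {
    cat(sprintf(
        "OddsRatioResult: lnOR = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.4g%s\n",
        object@lnOR, object@se, object@ciLow, object@ciHigh, object@p,
        if (object@haldane) " [Haldane +0.5]" else ""))
})

#' Is an odds-ratio association significant?
#'
#' TRUE when the 95\% confidence interval for ln(OR) excludes 0.
#' @param x an [OddsRatioResult-class].
#' @return logical(1).
#' @export
isSignificantOR <- function(x) x@ciLow > 0 || x@ciHigh < 0

#' Write an odds-ratio report row to TSV
#' @param or an [OddsRatioResult-class] (or list of them, named by
#'   comparison).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeOddsRatio <- function(or, path) {
    if (is(or, "OddsRatioResult")) or <- list(comparison = or)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(
        "#comparison\ta\tb\tc\td\tlnOR\tse\tci_low\tci_high\tz\tp\tsignificant",
        con)
    for (nm in names(or)) {
        o <- or[[nm]]
        writeLines(sprintf(
            "%s\t%g\t%g\t%g\t%g\t%.17g\t%.17g\t%.17g\t%.17g\t%.17g\t%.17g\t%s",
            nm, o@counts["a"], o@counts["b"], o@counts["c"], o@counts["d"],
            o@lnOR, o@se, o@ciLow, o@ciHigh, o@z, o@p,
            ifelse(isSignificantOR(o), "TRUE", "FALSE")), con)
    }
    invisible(path)
}
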