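#' @include AllClasses.R comparison.R
#' @importFrom ape as.phylo write.tree
NULL

#' Sample distinguishing features for visualisation
#'
#' Greedy gene-first sampling: genes are ranked by number of significant
#' features (descending), ties broken by the adjusted p-value of their most
#' significant feature, then by gene id; whole genes are taken in rank order
#' until the cap would be crossed, and the crossing gene contributes its
#' features in ascending adjusted-p order, truncated so the feature count
#' equals the cap exactly. When the total is within the cap everything is
#' kept.
#'
#' @param result a [ComparisonResult-class].
#' @param cap maximum number of features (default 10000).
#' @return a [SampledSet-class].
#' @export
sampleFeatures <- function(result, cap = 10000) {
    if (cap < 1) stop("cap must be >= 1")
    stats <- distinguishingGeneTable(result)
    if (nrow(stats) == 0L) {
        warning("no significant features to sample")
        return(new("SampledSet", features = character(0),
                   genes = character(0), geneStats = stats, cap = cap))
    }
    sig <- result@table[result@table$significant, , drop = FALSE]
    feats <- character(0)
    genes <- character(0)
    for (i in seq_len(nrow(stats))) {
        g <- stats$gene[i]
        f <- sig[sig$gene == g, , drop = FALSE]
        f <- f[order(f$p_adj, f$state), , drop = FALSE]
        room <- cap - length(feats)
        if (room <= 0L) break
        feats <- c(feats, utils::head(f$feature, room))
        genes <- c(genes, g)
        if (nrow(f) >= room) break
    }
    new("SampledSet", features = feats, genes = genes,
        geneStats = stats[stats$gene %in% genes, , drop = FALSE],
        cap = cap)
}

setMethod("show", "SampledSet", function(object) {
    cat(sprintf("SampledSet: %d features over %d genes (cap %g)\n",
                length(object@features), length(object@genes), object@cap))
})

#' Dominant chromatin state per (epigenome, gene)
#'
#' The state with the largest raw coverage fraction of the gene body, from
#' the uncorrected feature matrix (covariate correction never changes the
#' dominant state). Ties break towards the lowest state index.
#'
#' @param fm a raw [FeatureMatrix-class].
#' @param genes gene ids (columns of the result); default all.
#' @param epigenomes epigenome ids (rows); default all.
#' @return integer matrix of state indices, epigenomes x genes.
#' @export
dominantStateMatrix <- function(fm, genes = NULL, epigenomes = NULL) {
    if (is(fm, "CorrectedMatrix"))
        stop("dominant states must come from raw coverage fractions")
    if (is.null(genes)) genes <- unique(fm@geneIds)
    if (is.null(epigenomes)) epigenomes <- rownames(fm@values)
    bad <- setdiff(genes, fm@geneIds)
    if (length(bad) > 0L)
        stop("genes absent from the matrix: ", paste(bad, collapse = ", "))
    out <- matrix(NA_integer_, nrow = length(epigenomes),
                  ncol = length(genes),
                  dimnames = list(epigenomes, genes))
    for (g in genes) {
        cols <- which(fm@geneIds == g)
        cols <- cols[order(fm@stateIndex[cols])]
        block <- fm@values[epigenomes, cols, drop = FALSE]
        out[, g] <- fm@stateIndex[cols][max.col(block, ties.method =
                                                    "first")]
    }
    out
}

#' Cluster genes by complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with complete linkage on Euclidean distances
#' between gene vectors, cut into k clusters. Clusters holding at least
#' \code{annotateMin} of the clustered elements are marked annotated (the
#' ones worth labelling on a heatmap and analysing downstream); smaller
#' clusters keep their labels but are not annotated.
#'
#' @param mat numeric matrix with genes as rows (each row one gene's
#'   vector, e.g. its corrected feature values across epigenomes).
#' @param k number of clusters.
#' @param annotateMin minimum fraction of elements for annotation.
#' @return a [GeneClustering-class].
#' @export
clusterGenes <- function(mat, k = 4L, annotateMin = 0.05) {
    if (nrow(mat) < 2L) stop("need at least 2 genes to cluster")
    if (k > nrow(mat)) stop("k exceeds the number of genes")
    hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = "complete")
    labels <- stats::cutree(hc, k = k)
    sizes <- table(labels)
    annotated <- stats::setNames(as.vector(sizes) >=
                                     annotateMin * nrow(mat),
                                 names(sizes))
    new("GeneClustering", hclust = hc, labels = labels, k = as.integer(k),
        annotated = annotated)
}

setMethod("show", "GeneClustering", function(object) {
    cat(sprintf(
        "GeneClustering: %d genes in %d clusters (%d annotated)\n",
        length(object@labels), object@k, sum(object@annotated)))
})

# leaf order of a dendrogram reordered by subtree means: at every merge the
# lower-mean subtree comes first
.meanOrderedLeaves <- function(mat, wts) {
    if (nrow(mat) == 1L) return(1L)
    hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = "complete")
    d <- stats::reorder(stats::as.dendrogram(hc), wts, agglo.FUN = mean)
    stats::order.dendrogram(d)
}

#' Mean-ordered heatmap row/column orderings
#'
#' Rows and columns are ordered by hierarchical clustering (complete
#' linkage, Euclidean) with dendrogram leaves rotated so that at every merge
#' the subtree with the smaller mean comes first. In \code{"within-group"}
#' mode the rows of each group are clustered and ordered separately and the
#' two orderings concatenated (group A first) — the convention used for
#' dominant-state heatmaps, whose orderings expression heatmaps then reuse
#' verbatim. A single-row group is its own ordering.
#'
#' @param mat numeric matrix.
#' @param mode "joint" or "within-group".
#' @param spec a [GroupSpec-class]; required for within-group mode (rows of
#'   \code{mat} must be named by epigenome id).
#' @return list with integer vectors \code{rowOrder} and \code{colOrder}.
#' @export
orderHeatmap <- function(mat, mode = c("joint", "within-group"),
                         spec = NULL) {
    mode <- match.arg(mode)
    if (nrow(mat) == 0L || ncol(mat) == 0L) stop("empty matrix")
    colOrder <- .meanOrderedLeaves(t(mat), colMeans(mat))
    if (mode == "joint") {
        rowOrder <- .meanOrderedLeaves(mat, rowMeans(mat))
    } else {
        if (is.null(spec)) stop("within-group ordering needs a GroupSpec")
        ra <- match(intersect(spec@idsA, rownames(mat)), rownames(mat))
        rb <- match(intersect(spec@idsB, rownames(mat)), rownames(mat))
        ordA <- ra[.meanOrderedLeaves(mat[ra, , drop = FALSE],
                                      rowMeans(mat[ra, , drop = FALSE]))]
        ordB <- rb[.meanOrderedLeaves(mat[rb, , drop = FALSE],
                                      rowMeans(mat[rb, , drop = FALSE]))]
        rowOrder <- c(ordA, ordB)
    }
    list(rowOrder = rowOrder, colOrder = colOrder)
}

#' Feature-combination matrix for heatmap export
#'
#' States x genes integer matrix over the sampled features: a cell holds
#' the state index when that (gene, state) pair is a significant feature,
#' NA otherwise, so a palette colour scale maps each state to its colour.
#'
#' @param sampled a [SampledSet-class].
#' @param result the [ComparisonResult-class] it was sampled from.
#' @param palette a [StatePalette-class] (sets the row count).
#' @return integer matrix, states x genes, NA for absent combinations.
#' @export
featureCombinationMatrix <- function(sampled, result,
                                     palette = roadmap15Palette()) {
    S <- nStates(palette)
    genes <- sampled@genes
    out <- matrix(NA_integer_, nrow = S, ncol = length(genes),
                  dimnames = list(palette@states$mnemonic, genes))
    tab <- result@table[result@table$feature %in% sampled@features, ,
                        drop = FALSE]
    out[cbind(tab$state, match(tab$gene, genes))] <- tab$state
    out
}

#' Expression heatmap matrix
#'
#' log2(RPKM + 1)-transformed expression for the sampled genes; epigenomes
#' without expression data appear as all-NA rows so the heatmap stays
#' row-aligned with the dominant-state heatmap.
#'
#' @param expr numeric matrix, genes x epigenomes.
#' @param genes gene ids (columns of the result).
#' @param epigenomes epigenome ids (rows of the result).
#' @return numeric matrix, epigenomes x genes.
#' @export
expressionHeatmapMatrix <- function(expr, genes, epigenomes) {
    out <- matrix(NA_real_, nrow = length(epigenomes),
                  ncol = length(genes),
                  dimnames = list(epigenomes, genes))
    e <- intersect(epigenomes, colnames(expr))
    g <- intersect(genes, rownames(expr))
    out[e, g] <- t(log2(expr[g, e, drop = FALSE] + 1))
    out
}

#' Export a gene-cluster dendrogram as Newick
#' @param clustering a [GeneClustering-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDendrogram <- function(clustering, path) {
    ape::write.tree(ape::as.phylo(clustering@hclust), file = path)
    invisible(path)
}

#' Write cluster assignments to TSV
#' @param clustering a [GeneClustering-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeClusters <- function(clustering, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#gene\tcluster\tannotated", con)
    writeLines(sprintf("%s\t%d\t%s", names(clustering@labels),
                       clustering@labels,
                       ifelse(clustering@annotated[as.character(
                           clustering@labels)], "TRUE", "FALSE")), con)
    invisible(path)
}

#' Write an integer/numeric heatmap matrix to TSV
#' @param mat matrix with dimnames.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMatrixTSV <- function(mat, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#id\t", paste(colnames(mat), collapse = "\t")), con)
    body <- vapply(seq_len(nrow(mat)), function(i)
        paste(c(rownames(mat)[i],
                ifelse(is.na(mat[i, ]), "NA",
                       sprintf("%.17g", mat[i, ]))), collapse = "\t"),
        character(1))
    writeLines(body, con)
    invisible(path)
}
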