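#' @include AllClasses.R AllGenerics.R palette.R io-segmentation.R
#' @importFrom GenomicRanges findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits
NULL

.backgroundIndex <- function(palette, backgroundState) {
    idx <- resolveStates(backgroundState, palette)
    if (is.na(idx))
        stop("background state not in palette: ", backgroundState)
    idx
}

# bp of each gene body covered by each state, plus uncovered bp assigned to
# the background state; genes is a GRanges, returns genes x S count matrix.
.coverageCounts <- function(seg, genes, backgroundIdx) {
    S <- nStates(seg@palette)
    segr <- seg@ranges
    counts <- matrix(0, nrow = length(genes), ncol = S)
    # genes on chromosomes absent from the segmentation simply get no hits
    hits <- suppressWarnings(findOverlaps(genes, segr))
    if (length(hits) > 0L) {
        ov <- width(suppressWarnings(pintersect(
            genes[queryHits(hits)], segr[subjectHits(hits)])))
        st <- mcols(segr)$state[subjectHits(hits)]
        key <- (st - 1L) * length(genes) + queryHits(hits)
        agg <- rowsum(ov, key)
        counts[as.integer(rownames(agg))] <- agg
    }
    uncovered <- width(genes) - rowSums(counts)
    counts[, backgroundIdx] <- counts[, backgroundIdx] + uncovered
    attr(counts, "uncoveredBp") <- sum(uncovered)
    counts
}

.applyFlanks <- function(genes, seg, flankUp, flankDown) {
    if (flankUp == 0 && flankDown == 0) return(genes)
    chromEnd <- tapply(end(seg@ranges),
                       as.character(seqnames(seg@ranges)), max)
    ce <- chromEnd[as.character(seqnames(genes))]
    ce[is.na(ce)] <- Inf
    st <- pmax(1L, start(genes) - as.integer(flankUp))
    en <- as.integer(pmin(end(genes) + flankDown, ce))
    GRanges(seqnames(genes), IRanges(st, en), gene_id = mcols(genes)$gene_id)
}

#' Chromatin-state coverage profile of one gene
#'
#' The raw feature encoding: for gene X and state Y, the fraction of gene-
#' body basepairs annotated as Y in the epigenome's segmentation. Basepairs
#' without any annotation are assigned to the background state (default the
#' quiescent state) with a warning, since complete segmentations tile the
#' genome and gaps indicate input problems.
#'
#' @param seg a [Segmentation-class].
#' @param gene single-range GRanges (or a range of a genes GRanges).
#' @param backgroundState mnemonic receiving unannotated basepairs.
#' @param allowMissingChrom if TRUE, a gene on a chromosome absent from the
#'   segmentation yields an all-background profile with a warning instead of
#'   an error.
#' @return numeric vector of length S (named by mnemonic) summing to 1,
#'   with attributes \code{geneId} and \code{coveredLength} (bp covered by
#'   actual annotation).
#' @examples
#' pal <- roadmap15Palette()
#' seg <- Segmentation("E1", GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 151), c(150, 300)), state = c(4L, 15L)), pal)
#' gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
#'     gene_id = "G1")
#' p <- geneStateProfile(seg, gene)  # 0.5 Tx, 0.5 Quies
#' @export
geneStateProfile <- function(seg, gene, backgroundState = "Quies",
                             allowMissingChrom = FALSE) {
    stopifnot(length(gene) == 1L)
    bg <- .backgroundIndex(seg@palette, backgroundState)
    chr <- as.character(seqnames(gene))
    if (!chr %in% as.character(seqnames(seg@ranges))) {
        if (!allowMissingChrom)
            stop(sprintf("chromosome %s absent from segmentation '%s'",
                         chr, seg@epigenome))
        warning(sprintf("chromosome %s absent; all-background profile", chr))
    }
    counts <- .coverageCounts(seg, gene, bg)
    if (attr(counts, "uncoveredBp") > 0 &&
        chr %in% as.character(seqnames(seg@ranges)))
        warning(sprintf("%d unannotated bp assigned to background state",
                        attr(counts, "uncoveredBp")))
    p <- counts[1L, ] / width(gene)
    names(p) <- seg@palette@states$mnemonic
    attr(p, "geneId") <- mcols(gene)$gene_id
    attr(p, "coveredLength") <- width(gene) - attr(counts, "uncoveredBp")
    p
}

#' Build the epigenomes x (gene, state) feature matrix
#'
#' One row per epigenome, |genes| x S columns of gene-body state-coverage
#' fractions; within each gene the S fractions sum to 1. Column order is
#' genes in input order, states 1..S within each gene; column names are
#' \code{"GENEID|STATEINDEX"}. Optional flank extension widens each gene
#' body upstream/downstream (clipped at chromosome ends) to include
#' proximal regulatory territory.
#'
#' @param segmentations list of [Segmentation-class] (one per epigenome), or
#'   a named list subset via \code{epigenomes}.
#' @param genes GRanges of gene models ([readGenes()]).
#' @param epigenomes ids to include, in row order; default all, input order.
#' @param flankUp,flankDown bp of flank added before the gene start / after
#'   the gene end (strand-agnostic).
#' @param backgroundState mnemonic receiving unannotated basepairs.
#' @param allowMissingChrom tolerate genes on chromosomes missing from a
#'   segmentation (all-background profile).
#' @return a [FeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(segmentations, genes, epigenomes = NULL,
                               flankUp = 0, flankDown = 0,
                               backgroundState = "Quies",
                               allowMissingChrom = FALSE) {
    segIds <- unname(vapply(segmentations, function(s) s@epigenome,
                            character(1)))
    names(segmentations) <- segIds
    if (is.null(epigenomes)) epigenomes <- segIds
    missing <- setdiff(epigenomes, segIds)
    if (length(missing) > 0L)
        stop("no segmentation for epigenome(s): ",
             paste(missing, collapse = ", "))
    palette <- segmentations[[1L]]@palette
    S <- nStates(palette)
    bg <- .backgroundIndex(palette, backgroundState)
    geneIdsU <- mcols(genes)$gene_id
    nG <- length(genes)
    epigenomes <- unname(epigenomes)
    vals <- matrix(NA_real_, nrow = length(epigenomes), ncol = nG * S,
                   dimnames = list(epigenomes, NULL))
    totalUncovered <- 0
    effLengths <- NULL
    for (e in epigenomes) {
        seg <- segmentations[[e]]
        if (!identical(seg@palette@states$mnemonic,
                       palette@states$mnemonic))
            stop("segmentations must share one palette")
        gext <- .applyFlanks(genes, seg, flankUp, flankDown)
        if (is.null(effLengths)) effLengths <- width(gext)
        chrMissing <- !(as.character(seqnames(gext)) %in%
                            as.character(seqnames(seg@ranges)))
        if (any(chrMissing) && !allowMissingChrom)
            stop(sprintf("chromosome %s absent from segmentation '%s'",
                         as.character(seqnames(gext))[chrMissing][1L], e))
        counts <- .coverageCounts(seg, gext, bg)
        totalUncovered <- totalUncovered + attr(counts, "uncoveredBp") -
            sum(width(gext)[chrMissing])
        vals[e, ] <- as.vector(t(counts / width(gext)))
    }
    if (totalUncovered > 0)
        warning(sprintf(
            "%d unannotated gene-body bp assigned to background state",
            totalUncovered))
    geneCol <- rep(geneIdsU, each = S)
    stateCol <- rep(seq_len(S), times = nG)
    colnames(vals) <- paste0(geneCol, "|", stateCol)
    new("FeatureMatrix", values = vals, geneIds = geneCol,
        stateIndex = stateCol,
        geneLengths = stats::setNames(as.numeric(effLengths), geneIdsU),
        palette = palette)
}

#' Shannon entropy of a state profile, in bits
#'
#' @param p probability vector (sums to 1); 0 log 0 is taken as 0.
#' @return entropy in bits.
#' @examples
#' profileEntropy(rep(1 / 15, 15))  # log2(15)
#' @export
profileEntropy <- function(p) {
    if (any(p < 0)) stop("probabilities must be non-negative")
    if (abs(sum(p) - 1) > 1e-6) stop("profile must sum to 1")
    nz <- p[p > 0]
    -sum(nz * log2(nz))
}

#' Kullback-Leibler divergence between state profiles, in bits
#'
#' Returns +Inf when some q_i = 0 with p_i > 0 (documented convention).
#' @param p,q probability vectors of equal length.
#' @return divergence D(p || q) >= 0, in bits.
#' @export
klDivergence <- function(p, q) {
    if (length(p) != length(q)) stop("profiles must have equal length")
    if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
    nz <- p > 0
    if (any(q[nz] == 0)) return(Inf)
    sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Feature column identifiers
#' @param x a FeatureMatrix.
#' @return character vector "GENEID|STATEINDEX".
#' @export
featureIds <- function(x) colnames(x@values)

setMethod("epigenomeIds", "FeatureMatrix", function(x) rownames(x@values))
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
setMethod("featureGenes", "FeatureMatrix", function(x) x@geneIds)
setMethod("featureStates", "FeatureMatrix", function(x) x@stateIndex)
setMethod("geneBodyLengths", "FeatureMatrix", function(x) x@geneLengths)

setMethod("show", "FeatureMatrix", function(object) {
    cat(sprintf(
        "%s: %d epigenomes x %d features (%d genes x %d states)\n",
        class(object), nrow(object@values), ncol(object@values),
        length(unique(object@geneIds)), nStates(object@palette)))
})

#' Write a feature matrix to TSV
#'
#' Rows are epigenomes; "#"-prefixed metadata lines record the palette and
#' gene lengths so the object round-trips exactly.
#' @param fm a [FeatureMatrix-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#palette:\t",
                      paste(fm@palette@states$mnemonic, collapse = "\t")),
               con)
    writeLines(paste0("#genelengths:\t",
                      paste(names(fm@geneLengths), fm@geneLengths,
                            sep = "=", collapse = "\t")), con)
    writeLines(paste0("#id\t", paste(colnames(fm@values), collapse = "\t")),
               con)
    body <- vapply(seq_len(nrow(fm@values)), function(i)
        paste(c(rownames(fm@values)[i],
                sprintf("%.17g", fm@values[i, ])), collapse = "\t"),
        character(1))
    writeLines(body, con)
    invisible(path)
}

#' Read a feature matrix written by [writeFeatureMatrix()]
#' @param path TSV file.
#' @param palette optional palette; reconstructed from the metadata line
#'   (mnemonics only) when omitted.
#' @return a [FeatureMatrix-class].
#' @export
readFeatureMatrix <- function(path, palette = NULL) {
    lines <- readLines(path, warn = FALSE)
    palLine <- strsplit(sub("^#palette:\t", "",
                            lines[startsWith(lines, "#palette:")]),
                        "\t")[[1L]]
    if (is.null(palette)) palette <- statePalette(palLine)
    glLine <- strsplit(sub("^#genelengths:\t", "",
                           lines[startsWith(lines, "#genelengths:")]),
                       "\t")[[1L]]
    glParts <- strsplit(glLine, "=", fixed = TRUE)
    geneLengths <- stats::setNames(
        as.numeric(vapply(glParts, `[`, character(1), 2L)),
        vapply(glParts, `[`, character(1), 1L))
    hdr <- strsplit(sub("^#id\t", "", lines[startsWith(lines, "#id\t")]),
                    "\t")[[1L]]
    body <- lines[!startsWith(lines, "#")]
    cells <- strsplit(body, "\t", fixed = TRUE)
    ids <- vapply(cells, `[`, character(1), 1L)
    vals <- t(vapply(cells, function(x) as.numeric(x[-1L]),
                     numeric(length(hdr))))
    dimnames(vals) <- list(ids, hdr)
    parts <- strsplit(hdr, "|", fixed = TRUE)
    new("FeatureMatrix", values = vals,
        geneIds = vapply(parts, `[`, character(1), 1L),
        stateIndex = as.integer(vapply(parts, `[`, character(1), 2L)),
        geneLengths = geneLengths, palette = palette)
}

#' Write a feature matrix in long format
#'
#' Interoperability export: one row per (epigenome, gene, state) with the
#' coverage fraction.
#' @inheritParams writeFeatureMatrix
#' @export
writeFeatureMatrixLong <- function(fm, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#epigenome\tgene\tstate\tvalue", con)
    mnem <- fm@palette@states$mnemonic
    for (i in seq_len(nrow(fm@values)))
        writeLines(sprintf("%s\t%s\t%s\t%.17g", rownames(fm@values)[i],
                           fm@geneIds, mnem[fm@stateIndex],
                           fm@values[i, ]), con)
    invisible(path)
}
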