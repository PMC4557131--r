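#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' StatePalette: an ordered chromatin-state alphabet
#'
#' Holds the ordered set of chromatin states a segmentation may use: 1-based
#' consecutive indices, unique mnemonics (e.g. \code{"Tx"}, \code{"Quies"}),
#' display names and hex colours. The default is the 15-state model built on
#' the five core histone marks (H3K4me3, H3K4me1, H3K36me3, H3K9me3,
#' H3K27me3); any alphabet works, so segmentations from other models can be
#' supplied with a matching palette.
#'
#' @slot states data.frame with columns \code{index}, \code{mnemonic},
#'   \code{name}, \code{color}.
#' @seealso [statePalette()], [roadmap15Palette()]
#' @export
setClass("StatePalette", slots = c(states = "data.frame"))

setValidity("StatePalette", function(object) {
    st <- object@states
    need <- c("index", "mnemonic", "name", "color")
    if (!all(need %in% names(st)))
        return(paste("states must have columns:", paste(need, collapse = ", ")))
    if (nrow(st) < 1L) return("palette must contain at least one state")
    if (!identical(as.integer(st$index), seq_len(nrow(st))))
        return("state indices must be consecutive 1..S in order")
    if (anyDuplicated(st$mnemonic))
        return("state mnemonics must be unique")
    TRUE
})

#' Segmentation: one epigenome's chromatin-state tiling
#'
#' A genome-wide set of non-overlapping labelled intervals for a single
#' epigenome. Coordinates are 0-based half-open internally (BED convention);
#' the \code{GRanges} slot stores the usual 1-based starts, and all public
#' arithmetic uses interval widths so the convention cannot drift.
#'
#' @slot epigenome character(1) epigenome identifier.
#' @slot ranges GRanges, sorted, with an integer \code{state} metadata column.
#' @slot palette the [StatePalette-class] the state indices refer to.
#' @export
setClass("Segmentation",
    slots = c(epigenome = "character", ranges = "GRanges",
              palette = "StatePalette"))

setValidity("Segmentation", function(object) {
    if (length(object@epigenome) != 1L || is.na(object@epigenome) ||
        !nzchar(object@epigenome))
        return("epigenome must be a single non-empty id")
    gr <- object@ranges
    if (length(gr) == 0L) return(TRUE)
    st <- mcols(gr)$state
    if (is.null(st)) return("ranges must carry a 'state' metadata column")
    S <- nrow(object@palette@states)
    if (any(is.na(st)) || any(st < 1L) || any(st > S))
        return("state indices must lie in the palette range")
    if (any(width(gr) < 1L)) return("intervals must satisfy end > start")
    for (chr in unique(as.character(seqnames(gr)))) {
        g <- gr[seqnames(gr) == chr]
        o <- order(start(g))
        if (any(start(g)[o][-1] < end(g)[o][-length(g)]))
            return(sprintf("overlapping intervals on %s", chr))
    }
    TRUE
})

#' FeatureMatrix: epigenomes x (gene, state) coverage fractions
#'
#' The method's central object: one row per epigenome, one column per
#' (gene, chromatin state) pair, each value the fraction of the gene body
#' annotated as that state. Within every epigenome the S values of one gene
#' sum to 1. Column names are \code{"GENEID|STATEINDEX"}.
#'
#' @slot values numeric matrix, rows = epigenomes, columns = features.
#' @slot geneIds character, gene id per column.
#' @slot stateIndex integer, state index per column.
#' @slot geneLengths named numeric, gene-body length in bp per gene id
#'   (the binomial trial count used during covariate correction).
#' @slot palette the [StatePalette-class].
#' @export
setClass("FeatureMatrix",
    slots = c(values = "matrix", geneIds = "character",
              stateIndex = "integer", geneLengths = "numeric",
              palette = "StatePalette"))

setValidity("FeatureMatrix", function(object) {
    v <- object@values
    if (ncol(v) != length(object@geneIds) ||
        ncol(v) != length(object@stateIndex))
        return("column annotations must match the value matrix")
    if (is.null(rownames(v))) return("rows must be named by epigenome id")
    if (anyDuplicated(rownames(v))) return("duplicate epigenome ids")
    if (anyNA(v)) return("feature values must not be missing")
    gl <- object@geneLengths
    if (!all(unique(object@geneIds) %in% names(gl)))
        return("every gene must have a recorded length")
    TRUE
})

#' CorrectedMatrix: covariate-corrected feature values
#'
#' Same shape as the [FeatureMatrix-class] it was derived from, but holding
#' deviance residuals from per-feature binomial logistic regressions on the
#' covariate design (tested property excluded). Values are unbounded reals;
#' the sign equals the sign of observed minus fitted coverage.
#'
#' @slot testedProperty the metadata property excluded from the design.
#' @slot diagnostics data.frame per feature: converged, iterations,
#'   null and residual deviance.
#' @export
setClass("CorrectedMatrix", contains = "FeatureMatrix",
    slots = c(testedProperty = "character", diagnostics = "data.frame"))

#' CovariateDesign: fractional-membership explanatory variables
#'
#' One row per epigenome; an intercept column plus one column per category
#' level of every encoded property. A sample annotated with n levels of a
#' property carries 1/n in each matching column; a sample missing the
#' property carries an all-zero block.
#'
#' @slot design numeric matrix (rows = epigenomes).
#' @slot property character, owning property per column ("(Intercept)" for
#'   the intercept).
#' @export
setClass("CovariateDesign",
    slots = c(design = "matrix", property = "character"))

setValidity("CovariateDesign", function(object) {
    if (ncol(object@design) != length(object@property))
        return("one property tag per design column required")
    if (anyNA(object@design)) return("design must be complete")
    if (any(object@design < 0 | object@design > 1))
        return("design values must lie in [0, 1]")
    TRUE
})

#' GroupSpec: a two-group comparison of epigenomes
#'
#' Names the compared property (e.g. donor sex), the two trait labels, and
#' the resolved, disjoint epigenome id lists.
#'
#' @slot property,traitA,traitB character(1).
#' @slot idsA,idsB character vectors of epigenome ids.
#' @export
setClass("GroupSpec",
    slots = c(property = "character", traitA = "character",
              traitB = "character", idsA = "character", idsB = "character"))

setValidity("GroupSpec", function(object) {
    if (length(object@idsA) < 1L || length(object@idsB) < 1L)
        return("both groups must be non-empty")
    if (length(intersect(object@idsA, object@idsB)) > 0L)
        return("groups must be disjoint")
    TRUE
})

#' ComparisonResult: per-feature group-difference statistics
#'
#' @slot table data.frame with one row per feature: \code{feature},
#'   \code{gene}, \code{state}, \code{p}, \code{p_adj}, \code{direction}
#'   (sign of median(B) - median(A) on corrected values), \code{significant}.
#' @slot alpha significance cutoff on adjusted p.
#' @slot test,correction the test and multiple-testing method used.
#' @slot spec the [GroupSpec-class] compared.
#' @export
setClass("ComparisonResult",
    slots = c(table = "data.frame", alpha = "numeric", test = "character",
              correction = "character", spec = "GroupSpec"))

#' SampledSet: distinguishing features sampled for visualisation
#'
#' @slot features ordered feature ids (at most \code{cap}).
#' @slot genes ordered gene ids (by significant-feature count, then min
#'   adjusted p).
#' @slot geneStats data.frame: gene, n significant features, min adjusted p.
#' @slot cap the sampling cap.
#' @export
setClass("SampledSet",
    slots = c(features = "character", genes = "character",
              geneStats = "data.frame", cap = "numeric"))

#' GeneClustering: complete-linkage gene clusters
#'
#' @slot hclust the \code{stats::hclust} tree (complete linkage, Euclidean).
#' @slot labels named integer cluster label per gene.
#' @slot k number of clusters at the cut.
#' @slot annotated named logical: clusters holding at least the annotation
#'   fraction (default 5\%) of clustered elements.
#' @export
setClass("GeneClustering",
    slots = c(hclust = "ANY", labels = "integer", k = "integer",
              annotated = "logical"))

#' OddsRatioResult: distinguishing genes vs differential expression
#'
#' The 2x2 analysis linking epigenomically distinguishing genes to
#' differentially expressed genes: a = distinguishing & DE, b =
#' distinguishing & not DE, c = non-distinguishing & DE, d = neither.
#'
#' @slot counts named numeric(4) (a, b, c, d), after any continuity
#'   correction.
#' @slot lnOR log odds ratio ln(ad/bc).
#' @slot se sqrt(1/a + 1/b + 1/c + 1/d).
#' @slot ciLow,ciHigh 95\% confidence bounds lnOR +/- 1.96 se.
#' @slot z \code{abs(lnOR)/se}.
#' @slot p the printed approximation exp(-0.717 z - 0.416 z^2).
#' @slot pNormal exact two-sided normal p, for reference.
#' @slot haldane TRUE if the +0.5 zero-cell correction was applied.
#' @export
setClass("OddsRatioResult",
    slots = c(counts = "numeric", lnOR = "numeric", se = "numeric",
              ciLow = "numeric", ciHigh = "numeric", z = "numeric",
              p = "numeric", pNormal = "numeric", haldane = "logical"))

#' RandomizationReport: label-shuffling null calibration
#'
#' @slot comparison free-text comparison id.
#' @slot nTrials number of shuffles.
#' @slot counts per-trial significant-feature counts.
#' @slot nWithAny number of trials with at least one significant feature.
#' @slot fractionWithAny nWithAny / nTrials.
#' @slot seed master seed.
#' @export
setClass("RandomizationReport",
    slots = c(comparison = "character", nTrials = "integer",
              counts = "integer", nWithAny = "integer",
              fractionWithAny = "numeric", seed = "integer"))

#' SyntheticCohortSpec: parameters of a simulated cohort
#'
#' Defines a fully self-contained test cohort: chromosome lengths, gene count
#' and length range, baseline state frequencies and dwell lengths, a planted
#' group effect (source state rewritten to target state over a contiguous
#' fraction of each planted gene body in group B), the covariate scheme, and
#' the coupling of expression to transcribed-state coverage.
#'
#' @slot nPerGroup epigenomes per group.
#' @slot chromLengths named numeric, bp per chromosome.
#' @slot nGenes number of genes.
#' @slot geneLengthRange min/max gene length, bp.
#' @slot binSize segmentation granularity, bp (ChromHMM-style bins).
#' @slot stateFreq baseline per-state bin frequencies (sums to 1).
#' @slot meanDwellBins mean geometric dwell length, in bins.
#' @slot nPlanted number of genes carrying the planted effect.
#' @slot sourceState,targetState mnemonics of the planted switch.
#' @slot effectSize fraction of each planted gene body switched in group B.
#' @slot sourceEnrichment fraction of planted gene-body bins set to the
#'   source state in every epigenome (deterministic, evenly spread), so
#'   that with a value above 0.5 the source state — and after a full
#'   switch the target state — is dominant by construction.
#' @slot nLabs number of processing labs.
#' @slot exprCoupling log-scale coefficient tying mean expression to
#'   transcribed-state (Tx, TxWk, TxFlnk) coverage.
#' @slot exprBase,exprSd baseline log-RPKM mean and noise sd.
#' @slot seed master seed.
#' @export
setClass("SyntheticCohortSpec",
    slots = c(nPerGroup = "integer", chromLengths = "numeric",
              nGenes = "integer", geneLengthRange = "numeric",
              binSize = "integer", stateFreq = "numeric",
              meanDwellBins = "numeric", nPlanted = "integer",
              sourceState = "character", targetState = "character",
              effectSize = "numeric", sourceEnrichment = "numeric",
              nLabs = "integer", exprCoupling = "numeric",
              exprBase = "numeric", exprSd = "numeric", seed = "integer"))

setValidity("SyntheticCohortSpec", function(object) {
    if (object@nPerGroup < 1L || object@nGenes < 1L)
        return("counts must be >= 1")
    if (object@effectSize < 0 || object@effectSize > 1)
        return("effectSize must lie in [0, 1]")
    if (max(object@geneLengthRange) > max(object@chromLengths))
        return("genes must fit on a chromosome")
    if (abs(sum(object@stateFreq) - 1) > 1e-8)
        return("stateFreq must sum to 1")
    TRUE
})
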