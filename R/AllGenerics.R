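#' @include AllClasses.R
NULL

#' Epigenome identifiers of an object
#' @param x a Segmentation, FeatureMatrix or GroupSpec.
#' @return character vector of epigenome ids.
#' @export
setGeneric("epigenomeIds", function(x) standardGeneric("epigenomeIds"))

#' Feature value matrix (rows = epigenomes, columns = features)
#' @param x a FeatureMatrix or CorrectedMatrix.
#' @return numeric matrix.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Per-column gene ids of a feature matrix
#' @param x a FeatureMatrix.
#' @return character vector, one gene id per feature column.
#' @export
setGeneric("featureGenes", function(x) standardGeneric("featureGenes"))

#' Per-column state indices of a feature matrix
#' @param x a FeatureMatrix.
#' @return integer vector, one state index per feature column.
#' @export
setGeneric("featureStates", function(x) standardGeneric("featureStates"))

#' Gene-body lengths recorded in a feature matrix
#' @param x a FeatureMatrix.
#' @return named numeric vector of bp lengths.
#' @export
setGeneric("geneBodyLengths", function(x) standardGeneric("geneBodyLengths"))

#' State palette of an object
#' @param x a StatePalette-carrying object.
#' @return a [StatePalette-class].
#' @export
setGeneric("paletteOf", function(x) standardGeneric("paletteOf"))

#' Significant features of a comparison
#' @param x a ComparisonResult.
#' @return character vector of feature ids with adjusted p below alpha.
#' @export
setGeneric("significantFeatures",
    function(x) standardGeneric("significantFeatures"))

#' Distinguishing genes of a comparison
#'
#' Genes owning at least one significant feature.
#' @param x a ComparisonResult.
#' @return character vector of gene ids.
#' @export
setGeneric("distinguishingGenes",
    function(x) standardGeneric("distinguishingGenes"))

#' Per-feature result table of a comparison
#' @param x a ComparisonResult.
#' @return data.frame (feature, gene, state, p, p_adj, direction,
#'   significant).
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' Design matrix of a covariate encoding
#' @param x a CovariateDesign.
#' @return numeric matrix with an intercept column.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
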