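#' @include AllClasses.R features.R covariates.R comparison.R enrichment.R
#' @include expression-analysis.R structure.R randomization.R
NULL

#' Assemble and validate a pipeline run configuration
#'
#' @param segmentationDir directory of per-epigenome BED files (one
#'   \code{<id>.bed} per epigenome).
#' @param genesPath GTF or BED6 gene annotation.
#' @param metadataPath metadata TSV.
#' @param property,traitA,traitB the comparison.
#' @param outDir output directory.
#' @param expressionPath,gmtPath,palettePath optional inputs.
#' @param covariates covariate properties; NULL = [defaultCovariates()].
#' @param test,correction,alpha see [compareGroups()].
#' @param cap feature-sampling cap ([sampleFeatures()]).
#' @param clusterK gene-cluster count ([clusterGenes()]).
#' @param flankUp,flankDown gene-body flank extension, bp.
#' @param backgroundState,allowMissingChrom see [buildFeatureMatrix()].
#' @param seed master seed.
#' @return validated config list of class \code{"runConfig"}.
#' @export
runConfig <- function(segmentationDir, genesPath, metadataPath, property,
                      traitA, traitB, outDir, expressionPath = NULL,
                      gmtPath = NULL, palettePath = NULL, covariates = NULL,
                      test = "mww", correction = "bh", alpha = 0.05,
                      cap = 10000, clusterK = 4L, flankUp = 0,
                      flankDown = 0, backgroundState = "Quies",
                      allowMissingChrom = FALSE, seed = 1L) {
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    cfg <- list(segmentationDir = segmentationDir, genesPath = genesPath,
                metadataPath = metadataPath, property = property,
                traitA = traitA, traitB = traitB, outDir = outDir,
                expressionPath = expressionPath, gmtPath = gmtPath,
                palettePath = palettePath, covariates = covariates,
                test = test, correction = correction, alpha = alpha,
                cap = cap, clusterK = as.integer(clusterK),
                flankUp = flankUp, flankDown = flankDown,
                backgroundState = backgroundState,
                allowMissingChrom = allowMissingChrom,
                seed = as.integer(seed))
    class(cfg) <- "runConfig"
    cfg
}

#' Load a run configuration from YAML
#'
#' Keys mirror the [runConfig()] arguments; explicit arguments passed via
#' \code{...} override file values.
#' @param path YAML file.
#' @param ... overrides.
#' @return config list of class \code{"runConfig"}.
#' @export
readRunConfig <- function(path, ...) {
    vals <- yaml::read_yaml(path)
    over <- list(...)
    vals[names(over)] <- over
    do.call(runConfig, vals)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full comparison pipeline
#'
#' Reads all inputs, builds the feature matrix, corrects it for covariates
#' (tested property excluded), tests every feature between the two groups,
#' samples distinguishing features, clusters the sampled genes, computes
#' heatmap matrices and orderings, runs gene-set enrichment and the
#' expression analyses (per-gene differential expression, cluster-level
#' pooled tests, the odds ratio linking epigenomic and expression
#' differences), and writes every table plus a JSON manifest to
#' \code{outDir}. Re-running with an identical config reproduces identical
#' outputs.
#'
#' @param config list from [runConfig()] / [readRunConfig()].
#' @return (invisibly) a list bundle: featureMatrix, corrected, result,
#'   sampled, clustering, orders, dominant, enrichment, de, deSplit,
#'   oddsRatio, clusterExpression, manifest.
#' @export
runComparison <- function(config) {
    stopifnot(inherits(config, "runConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    palette <- .stage("palette", if (is.null(config$palettePath))
        roadmap15Palette() else readPalette(config$palettePath))
    genes <- .stage("genes", readGenes(config$genesPath))
    metadata <- .stage("metadata", readMetadata(config$metadataPath))
    segFiles <- sort(list.files(config$segmentationDir,
                                pattern = "\\.bed$", full.names = TRUE))
    segs <- .stage("segmentations",
                   lapply(segFiles, readSegmentation, palette = palette))
    expr <- if (is.null(config$expressionPath)) NULL else
        .stage("expression", readExpression(config$expressionPath))
    sets <- if (is.null(config$gmtPath)) NULL else
        .stage("genesets", readGMT(config$gmtPath))

    fm <- .stage("features", buildFeatureMatrix(
        segs, genes, epigenomes = rownames(metadata),
        flankUp = config$flankUp, flankDown = config$flankDown,
        backgroundState = config$backgroundState,
        allowMissingChrom = config$allowMissingChrom))
    covs <- if (is.null(config$covariates)) defaultCovariates(metadata)
            else config$covariates
    cm <- .stage("correction", correctFeatures(
        fm, metadata, config$property, covariateProperties = covs))
    spec <- .stage("groups", groupSpec(metadata, config$property,
                                       config$traitA, config$traitB))
    result <- .stage("comparison", compareGroups(
        cm, spec, test = config$test, correction = config$correction,
        alpha = config$alpha))
    sampled <- .stage("sampling",
                      suppressWarnings(sampleFeatures(result, config$cap)))

    out <- list(featureMatrix = fm, corrected = cm, result = result,
                sampled = sampled, spec = spec)

    writeFeatureMatrix(fm, file.path(config$outDir, "features.tsv"))
    writeFeatureMatrix(cm, file.path(config$outDir, "corrected.tsv"))
    writeDiagnostics(cm, file.path(config$outDir, "diagnostics.tsv"))
    writeComparisonResult(result, file.path(config$outDir, "results.tsv"))
    gt <- distinguishingGeneTable(result)
    conn <- file(file.path(config$outDir, "genes.tsv"), "w")
    writeLines("#gene\tn_features\tmin_p_adj\tstates", conn)
    if (nrow(gt) > 0L)
        writeLines(sprintf("%s\t%d\t%.17g\t%s", gt$gene, gt$n_features,
                           gt$min_p_adj, gt$states), conn)
    close(conn)

    if (length(sampled@genes) >= 2L) {
        # gene vectors for clustering/ordering: per-epigenome mean of each
        # gene's sampled significant features, on corrected values
        sigTab <- result@table[result@table$feature %in% sampled@features,
                               , drop = FALSE]
        geneMat <- .stage("clustering", {
            vals <- cm@values[, sigTab$feature, drop = FALSE]
            t(vapply(sampled@genes, function(g)
                rowMeans(vals[, sigTab$gene == g, drop = FALSE]),
                numeric(nrow(vals))))
        })
        k <- min(config$clusterK, nrow(geneMat))
        clustering <- .stage("clustering",
                             clusterGenes(geneMat, k = k))
        orders <- .stage("ordering", orderHeatmap(t(geneMat),
                                                  mode = "within-group",
                                                  spec = spec))
        dominant <- .stage("dominant", dominantStateMatrix(
            fm, genes = sampled@genes,
            epigenomes = c(spec@idsA, spec@idsB)))
        out$clustering <- clustering
        out$orders <- orders
        out$dominant <- dominant
        writeClusters(clustering, file.path(config$outDir,
                                            "clusters.tsv"))
        writeDendrogram(clustering, file.path(config$outDir,
                                              "dendrogram.nwk"))
        writeMatrixTSV(dominant, file.path(config$outDir,
                                           "dominant_states.tsv"))
        writeMatrixTSV(featureCombinationMatrix(sampled, result, palette),
                       file.path(config$outDir,
                                 "feature_combinations.tsv"))
    }

    if (!is.null(sets) && length(sampled@genes) > 0L) {
        universe <- intersect(toupper(mcols(genes)$symbol),
                              toupper(unique(unlist(sets))))
        sym <- stats::setNames(toupper(mcols(genes)$symbol),
                               mcols(genes)$gene_id)
        query <- intersect(unname(sym[distinguishingGenes(result)]),
                           universe)
        if (length(query) > 0L) {
            enr <- .stage("enrichment",
                          geneSetEnrichment(query, universe, sets))
            out$enrichment <- enr
            writeEnrichment(enr, file.path(config$outDir,
                                           "enrichment.tsv"))
        }
    }

    if (!is.null(expr)) {
        de <- .stage("expression", differentialExpression(
            expr, spec, genes = mcols(genes)$gene_id,
            alpha = config$alpha))
        split <- deProportions(de, distinguishingGenes(result))
        out$de <- de
        out$deSplit <- split
        conn <- file(file.path(config$outDir, "de.tsv"), "w")
        writeLines("#gene\tp\tp_adj\tde\tno_data", conn)
        writeLines(sprintf("%s\t%.17g\t%.17g\t%s\t%s", de$gene, de$p,
                           de$p_adj, ifelse(de$de, "TRUE", "FALSE"),
                           ifelse(de$no_data, "TRUE", "FALSE")), conn)
        close(conn)
        or <- tryCatch(do.call(logOddsRatio, as.list(split$counts)),
                       error = function(e) NULL)
        if (!is.null(or)) {
            out$oddsRatio <- or
            writeOddsRatio(stats::setNames(
                list(or), sprintf("%s:%s_vs_%s", spec@property,
                                  spec@traitA, spec@traitB)),
                file.path(config$outDir, "oddsratio.tsv"))
        }
        if (!is.null(out$clustering)) {
            ann <- names(out$clustering@annotated)[
                out$clustering@annotated]
            cep <- vapply(ann, function(cl) {
                g <- names(out$clustering@labels)[
                    out$clustering@labels == as.integer(cl)]
                tryCatch(clusterExpressionTest(g, expr, spec),
                         error = function(e) NA_real_)
            }, numeric(1))
            out$clusterExpression <- cep
        }
        writeMatrixTSV(expressionHeatmapMatrix(
            expr, sampled@genes, c(spec@idsA, spec@idsB)),
            file.path(config$outDir, "expression_heatmap.tsv"))
    }

    manifest <- list(
        package = "chromCompare",
        version = as.character(utils::packageVersion("chromCompare")),
        config = unclass(config),
        n_epigenomes = nrow(fm@values),
        n_features = ncol(fm@values),
        n_significant = sum(result@table$significant),
        n_distinguishing_genes = length(distinguishingGenes(result)),
        complete = TRUE)
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
    invisible(out)
}
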