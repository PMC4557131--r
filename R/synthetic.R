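#' @include AllClasses.R features.R io-segmentation.R io-metadata.R
#' @importFrom jsonlite write_json
NULL

.defaultStateFreq <- function() {
    c(TssA = 0.01, TssAFlnk = 0.01, TxFlnk = 0.01, Tx = 0.05, TxWk = 0.10,
      EnhG = 0.01, Enh = 0.05, `ZNF/Rpts` = 0.01, Het = 0.05,
      TssBiv = 0.005, BivFlnk = 0.005, EnhBiv = 0.01, ReprPC = 0.03,
      ReprPCWk = 0.06, Quies = 0.59)
}

#' Specify a synthetic cohort
#'
#' Defaults describe the standard toy cohort: two 2-Mb chromosomes, 200
#' genes of 2-50 kb (log-uniform lengths), 10 + 10 epigenomes, 200-bp
#' segmentation bins with geometric dwell lengths, 20 planted genes whose
#' strong-transcription (Tx) bodies are rewritten to Polycomb repression
#' (ReprPC) in group B, and expression coupled to transcribed-state
#' coverage. See [SyntheticCohortSpec-class] for slot meanings.
#'
#' @param nPerGroup,nGenes,nPlanted,nLabs,binSize,seed integer parameters.
#' @param chromLengths named numeric (bp).
#' @param geneLengthRange numeric(2), bp.
#' @param stateFreq baseline per-state bin frequencies (15-state order).
#' @param meanDwellBins mean segment dwell in bins.
#' @param sourceState,targetState planted switch (mnemonics).
#' @param effectSize fraction of each planted gene body switched.
#' @param sourceEnrichment fraction of planted gene-body bins fixed to the
#'   source state in all epigenomes (> 0.5 makes it dominant by
#'   construction, so the planted switch has material to act on).
#' @param exprCoupling,exprBase,exprSd expression model (log scale).
#' @return a [SyntheticCohortSpec-class].
#' @export
syntheticCohortSpec <- function(nPerGroup = 10L,
                                chromLengths = c(chr1 = 2e6, chr2 = 2e6),
                                nGenes = 200L,
                                geneLengthRange = c(2000, 50000),
                                binSize = 200L,
                                stateFreq = .defaultStateFreq(),
                                meanDwellBins = 5,
                                nPlanted = 20L,
                                sourceState = "Tx",
                                targetState = "ReprPC",
                                effectSize = 1.0,
                                sourceEnrichment = 0.7,
                                nLabs = 2L,
                                exprCoupling = 3,
                                exprBase = 1,
                                exprSd = 0.5,
                                seed = 1L) {
    new("SyntheticCohortSpec", nPerGroup = as.integer(nPerGroup),
        chromLengths = chromLengths, nGenes = as.integer(nGenes),
        geneLengthRange = geneLengthRange, binSize = as.integer(binSize),
        stateFreq = stateFreq, meanDwellBins = meanDwellBins,
        nPlanted = as.integer(nPlanted), sourceState = sourceState,
        targetState = targetState, effectSize = effectSize,
        sourceEnrichment = sourceEnrichment, nLabs = as.integer(nLabs),
        exprCoupling = exprCoupling, exprBase = exprBase, exprSd = exprSd,
        seed = as.integer(seed))
}

#' Read or write a cohort spec as YAML
#'
#' Field names mirror the [syntheticCohortSpec()] arguments;
#' \code{stateFreq} and \code{chromLengths} are named maps.
#' @param path YAML file.
#' @return [readCohortSpec()]: a [SyntheticCohortSpec-class].
#' @export
readCohortSpec <- function(path) {
    vals <- yaml::read_yaml(path)
    for (nm in c("chromLengths", "stateFreq"))
        if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
    do.call(syntheticCohortSpec, vals)
}

#' @rdname readCohortSpec
#' @param spec a [SyntheticCohortSpec-class].
#' @export
writeCohortSpec <- function(spec, path) {
    slots <- methods::slotNames("SyntheticCohortSpec")
    vals <- lapply(slots, function(s) {
        v <- methods::slot(spec, s)
        if (!is.null(names(v))) as.list(v) else v
    })
    names(vals) <- slots
    yaml::write_yaml(vals, path)
    invisible(path)
}

# renewal sequence of per-bin states: geometric dwell, iid state draws
.drawBinStates <- function(nBins, freq, meanDwell) {
    out <- integer(0)
    while (length(out) < nBins) {
        nseg <- max(50L, ceiling((nBins - length(out)) / meanDwell * 1.5))
        st <- sample.int(length(freq), nseg, replace = TRUE, prob = freq)
        dw <- 1L + stats::rgeom(nseg, prob = 1 / meanDwell)
        out <- c(out, rep(st, dw))
    }
    out[seq_len(nBins)]
}

.binsToSegmentation <- function(bins, chromLengths, binSize, epigenome,
                                palette) {
    parts <- lapply(names(bins), function(chr) {
        r <- rle(bins[[chr]])
        ends <- cumsum(r$lengths) * binSize
        starts <- ends - r$lengths * binSize + 1L
        ends <- pmin(ends, chromLengths[[chr]])
        list(chr = rep(chr, length(starts)), start = starts, end = ends,
             state = r$values)
    })
    gr <- GRanges(unlist(lapply(parts, `[[`, "chr")),
                  IRanges(unlist(lapply(parts, `[[`, "start")),
                          unlist(lapply(parts, `[[`, "end"))),
                  state = unlist(lapply(parts, `[[`, "state")))
    Segmentation(epigenome, gr, palette)
}

.geneBinIdx <- function(st, wd, binSize, effectFraction = 1,
                        maxBin = Inf) {
    en <- st - 1 + floor(effectFraction * wd)
    if (en < st) return(integer(0))
    idx <- seq.int(floor((st - 1) / binSize) + 1L, ceiling(en / binSize))
    idx[idx <= maxBin]
}

.exprFromBins <- function(bins, genes, spec, palette, exprSeed) {
    txIdx <- resolveStates(c("TxFlnk", "Tx", "TxWk"), palette)
    txIdx <- txIdx[!is.na(txIdx)]
    ids <- names(bins)
    gid <- mcols(genes)$gene_id
    gchr <- as.character(seqnames(genes))
    gstart <- start(genes); gwd <- width(genes)
    gidx <- lapply(seq_along(genes), function(i)
        .geneBinIdx(gstart[i], gwd[i], spec@binSize))
    set.seed(exprSeed)
    expr <- matrix(0, nrow = length(genes), ncol = length(ids),
                   dimnames = list(gid, ids))
    for (e in ids) {
        isTx <- lapply(bins[[e]], function(b) b %in% txIdx)
        tx <- vapply(seq_along(gidx), function(i) {
            v <- isTx[[gchr[i]]]
            mean(v[gidx[[i]][gidx[[i]] <= length(v)]])
        }, numeric(1))
        expr[, e] <- stats::rlnorm(length(tx),
            meanlog = spec@exprBase + spec@exprCoupling * tx,
            sdlog = spec@exprSd)
    }
    expr
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces segmentations that exactly tile each chromosome (renewal
#' process with geometric dwell lengths at bin granularity), gene models,
#' covariate-structured metadata, expression coupled to transcribed-state
#' coverage, decoy gene sets plus a gene set of the planted genes, and a
#' truth record. Planted genes carry a fixed, evenly spread
#' sourceEnrichment fraction of source-state bins in all epigenomes;
#' group-B epigenomes have the source state rewritten to the
#' target state over the leading \code{effectSize} fraction of each planted
#' gene body.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return list with elements \code{segmentations} (list of
#'   [Segmentation-class]), \code{genes} (GRanges), \code{metadata}
#'   (DataFrame), \code{expression} (matrix), \code{geneSets} (list),
#'   \code{truth} (list), \code{palette}, \code{spec}, and the internal
#'   per-bin state vectors (\code{bins}).
#' @export
generateCohort <- function(spec) {
    validObject(spec)
    palette <- roadmap15Palette()
    S <- nStates(palette)
    if (length(spec@stateFreq) != S)
        stop("stateFreq must have one entry per palette state")
    srcIdx <- .backgroundIndex(palette, spec@sourceState)
    tgtIdx <- .backgroundIndex(palette, spec@targetState)
    set.seed(spec@seed)

    # gene placement: log-uniform lengths, greedy tiling with random gaps
    lens <- round(exp(stats::runif(spec@nGenes,
                                   log(spec@geneLengthRange[1]),
                                   log(spec@geneLengthRange[2]))))
    chrs <- names(spec@chromLengths)
    geneChr <- character(0); geneStart <- integer(0); geneEnd <- integer(0)
    ci <- 1L; pos <- 1L
    for (i in seq_len(spec@nGenes)) {
        gap <- round(stats::runif(1, 200, 2000))
        while (ci <= length(chrs) &&
               pos + gap + lens[i] - 1 > spec@chromLengths[[chrs[ci]]]) {
            ci <- ci + 1L; pos <- 1L
        }
        if (ci > length(chrs))
            stop("infeasible spec: genes do not fit on the chromosomes")
        st <- pos + gap
        geneChr <- c(geneChr, chrs[ci])
        geneStart <- c(geneStart, st)
        geneEnd <- c(geneEnd, st + lens[i] - 1L)
        pos <- st + lens[i]
    }
    gid <- sprintf("G%04d", seq_len(spec@nGenes))
    genes <- GRanges(geneChr, IRanges(geneStart, geneEnd), gene_id = gid,
                     symbol = gid,
                     biotype = rep("protein_coding", spec@nGenes))

    n <- 2L * spec@nPerGroup
    ids <- sprintf("E%02d", seq_len(n))
    group <- ifelse(seq_len(n) %% 2L == 1L, "A", "B")
    sexPat <- c("Male", "Female", "Female", "Male")
    labPat <- rep(paste0("Lab", seq_len(spec@nLabs)),
                  each = 2)[seq_len(2 * spec@nLabs)]
    typePat <- c("PrimaryTissue", "PrimaryCulture", "CellLine")
    statePat <- c("Solid", "Solid", "Liquid")
    anatPat <- c("Brain", "GI", "Blood", "Muscle", "Skin", "Liver")
    metadata <- DataFrame(row.names = ids)
    metadata[["group"]] <- CharacterList(as.list(group))
    metadata[["sex"]] <- CharacterList(
        as.list(sexPat[(seq_len(n) - 1L) %% 4L + 1L]))
    metadata[["lab"]] <- CharacterList(
        as.list(labPat[(seq_len(n) - 1L) %% length(labPat) + 1L]))
    metadata[["type"]] <- CharacterList(
        as.list(typePat[(seq_len(n) - 1L) %% 3L + 1L]))
    metadata[["state"]] <- CharacterList(
        as.list(statePat[(seq_len(n) - 1L) %% 3L + 1L]))
    metadata[["anatomy"]] <- CharacterList(
        as.list(anatPat[(seq_len(n) - 1L) %% 6L + 1L]))

    planted <- sort(sample.int(spec@nGenes, spec@nPlanted))
    # inside planted gene bodies a fixed, evenly spread sourceEnrichment
    # fraction of bins is set to the source state deterministically, so
    # with sourceEnrichment > 0.5 the source (and, after a full switch,
    # the target) is the dominant state by construction; the remaining
    # bins are drawn from the rescaled baseline distribution
    nonSrcFreq <- spec@stateFreq
    nonSrcFreq[srcIdx] <- 0
    nonSrcFreq <- nonSrcFreq / sum(nonSrcFreq)

    nBins <- vapply(spec@chromLengths,
                    function(l) as.integer(ceiling(l / spec@binSize)),
                    integer(1))
    glen <- geneEnd - geneStart + 1L
    plantedIdx <- lapply(planted, function(gi)
        .geneBinIdx(geneStart[gi], glen[gi], spec@binSize,
                    maxBin = nBins[[geneChr[gi]]]))
    plantedSrcSel <- lapply(plantedIdx, function(idx) {
        n <- length(idx)
        k <- round(spec@sourceEnrichment * n)
        i <- seq_len(n)
        (i * k) %/% n > ((i - 1L) * k) %/% n   # exactly k, evenly spread
    })
    effectIdx <- lapply(planted, function(gi)
        .geneBinIdx(geneStart[gi], glen[gi], spec@binSize,
                    effectFraction = spec@effectSize,
                    maxBin = nBins[[geneChr[gi]]]))
    bins <- vector("list", n); names(bins) <- ids
    for (e in seq_len(n)) {
        eb <- lapply(chrs, function(chr)
            .drawBinStates(nBins[[chr]], spec@stateFreq,
                           spec@meanDwellBins))
        names(eb) <- chrs
        # planted genes: deterministic source coverage plus baseline rest
        for (k in seq_along(planted)) {
            chr <- geneChr[planted[k]]
            idx <- plantedIdx[[k]]
            sel <- plantedSrcSel[[k]]
            eb[[chr]][idx[sel]] <- srcIdx
            eb[[chr]][idx[!sel]] <- sample.int(S, sum(!sel),
                                               replace = TRUE,
                                               prob = nonSrcFreq)
        }
        # group B: rewrite source -> target over the leading effect-size
        # fraction of each planted gene body
        if (group[e] == "B" && spec@effectSize > 0) {
            for (k in seq_along(planted)) {
                chr <- geneChr[planted[k]]
                idx <- effectIdx[[k]]
                hit <- idx[eb[[chr]][idx] == srcIdx]
                eb[[chr]][hit] <- tgtIdx
            }
        }
        bins[[e]] <- eb
    }
    segmentations <- lapply(ids, function(e)
        .binsToSegmentation(bins[[e]], spec@chromLengths, spec@binSize, e,
                            palette))
    names(segmentations) <- ids

    exprSeed <- sample.int(.Machine$integer.max, 1)
    gmtSeed <- sample.int(.Machine$integer.max, 1)
    expr <- .exprFromBins(bins, genes, spec, palette, exprSeed)

    set.seed(gmtSeed)
    geneSets <- list(PLANTED_SET = toupper(gid[planted]))
    for (k in seq_len(5))
        geneSets[[sprintf("DECOY_SET_%d", k)]] <-
            toupper(sample(gid, min(20L, spec@nGenes)))

    truth <- list(
        plantedGenes = gid[planted], sourceState = spec@sourceState,
        targetState = spec@targetState, effectSize = spec@effectSize,
        groups = stats::setNames(group, ids),
        labAssignments = stats::setNames(
            vapply(seq_len(n), function(i) metadata[["lab"]][[i]],
                   character(1)), ids),
        biasGenes = character(0))

    list(segmentations = segmentations, genes = genes, metadata = metadata,
         expression = expr, geneSets = geneSets, truth = truth,
         palette = palette, spec = spec, bins = bins)
}

#' Plant a group-correlated confounder
#'
#' Reassigns a covariate (default the processing lab) so that
#' P(level 1 | group B) - P(level 1 | group A) = rho (deterministic counts,
#' random membership), and adds a lab-specific annotation bias: in every
#' level-1 epigenome, the leading \code{biasFraction} of each of
#' \code{nBiasGenes} randomly chosen non-planted gene bodies is rewritten to
#' \code{biasState}. Expression is regenerated from the modified
#' segmentations. A perfect confound (rho = 1) is rejected: correction
#' could not be validated against it.
#'
#' @param cohort list from [generateCohort()].
#' @param rho group/covariate correlation in [0, 1).
#' @param covariate metadata property to confound (default "lab").
#' @param nBiasGenes number of non-planted genes receiving the bias.
#' @param biasState mnemonic written into biased gene bodies.
#' @param biasFraction leading fraction of each biased gene body rewritten.
#' @param seed integer seed.
#' @return the modified cohort (truth records bias genes and labs).
#' @export
plantConfounder <- function(cohort, rho, covariate = "lab",
                            nBiasGenes = 50L, biasState = "Enh",
                            biasFraction = 0.4, seed = 1L) {
    if (rho < 0 || rho >= 1)
        stop("rho must lie in [0, 1); a perfect confound cannot be ",
             "corrected or validated")
    spec <- cohort$spec
    palette <- cohort$palette
    biasIdx <- .backgroundIndex(palette, biasState)
    ids <- rownames(cohort$metadata)
    group <- cohort$truth$groups[ids]
    set.seed(seed)
    levels <- paste0("Lab", 1:2)
    assign <- character(length(ids)); names(assign) <- ids
    for (g in c("A", "B")) {
        memb <- ids[group == g]
        p1 <- if (g == "B") 0.5 + rho / 2 else 0.5 - rho / 2
        n1 <- round(length(memb) * p1)
        lab1 <- sample(memb, n1)
        assign[memb] <- ifelse(memb %in% lab1, levels[1], levels[2])
    }
    cohort$metadata[[covariate]] <- CharacterList(as.list(unname(assign)))

    gid <- mcols(cohort$genes)$gene_id
    nonPlanted <- setdiff(seq_along(gid),
                          match(cohort$truth$plantedGenes, gid))
    biasGenes <- sort(sample(nonPlanted, min(nBiasGenes,
                                             length(nonPlanted))))
    nBins <- vapply(spec@chromLengths,
                    function(l) as.integer(ceiling(l / spec@binSize)),
                    integer(1))
    gchr <- as.character(seqnames(cohort$genes))
    gstart <- start(cohort$genes); gwd <- width(cohort$genes)
    biasIdxList <- lapply(biasGenes, function(gi)
        .geneBinIdx(gstart[gi], gwd[gi], spec@binSize,
                    effectFraction = biasFraction,
                    maxBin = nBins[[gchr[gi]]]))
    for (e in ids[assign == levels[1]]) {
        for (k in seq_along(biasGenes)) {
            cohort$bins[[e]][[gchr[biasGenes[k]]]][biasIdxList[[k]]] <-
                biasIdx
        }
    }
    cohort$segmentations <- lapply(ids, function(e)
        .binsToSegmentation(cohort$bins[[e]], spec@chromLengths,
                            spec@binSize, e, palette))
    names(cohort$segmentations) <- ids
    exprSeed <- sample.int(.Machine$integer.max, 1)
    cohort$expression <- .exprFromBins(cohort$bins, cohort$genes, spec,
                                       palette, exprSeed)
    cohort$truth$labAssignments <- assign
    cohort$truth$biasGenes <- gid[biasGenes]
    cohort$truth$confounder <- list(covariate = covariate, rho = rho,
                                    biasState = biasState,
                                    biasFraction = biasFraction)
    cohort
}

#' Write a cohort to standard-format fixture files
#'
#' Emits one BED per epigenome under \code{segmentations/}, genes as GTF,
#' metadata and expression as TSV, gene sets as GMT, the palette as TSV and
#' the ground truth as JSON. Re-reading the fixtures with the package's
#' readers reproduces the in-memory cohort; identical cohorts produce
#' byte-identical files.
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
writeFixtures <- function(cohort, dir) {
    segDir <- file.path(dir, "segmentations")
    ok <- dir.exists(segDir) || dir.create(segDir, recursive = TRUE)
    if (!ok) stop("cannot create output directory: ", segDir)
    paths <- c()
    for (e in names(cohort$segmentations)) {
        p <- file.path(segDir, paste0(e, ".bed"))
        writeSegmentation(cohort$segmentations[[e]], p)
        paths[paste0("seg_", e)] <- p
    }
    paths["genes"] <- writeGenes(cohort$genes, file.path(dir, "genes.gtf"))
    paths["metadata"] <- writeMetadata(cohort$metadata,
                                       file.path(dir, "metadata.tsv"))
    paths["expression"] <- writeExpression(cohort$expression,
                                           file.path(dir,
                                                     "expression.tsv"))
    paths["genesets"] <- writeGMT(cohort$geneSets,
                                  file.path(dir, "genesets.gmt"),
                                  description = "synthetic")
    paths["palette"] <- writePalette(cohort$palette,
                                     file.path(dir, "palette.tsv"))
    truthPath <- file.path(dir, "truth.json")
    jsonlite::write_json(cohort$truth, truthPath, auto_unbox = TRUE,
                         digits = NA)
    paths["truth"] <- truthPath
    invisible(paths)
}
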