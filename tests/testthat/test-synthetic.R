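test_that("generated segmentations exactly tile every chromosome", {
    co <- toyCohort()
    spec <- co$spec
    for (seg in co$segmentations[1:4]) {
        gr <- segmentRanges(seg)
        for (chr in names(spec@chromLengths)) {
            g <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
            g <- g[order(GenomicRanges::start(g))]
            expect_equal(sum(GenomicRanges::width(g)),
                         unname(spec@chromLengths[[chr]]))
            expect_equal(GenomicRanges::start(g)[1], 1L)
            # abutting: each start continues where the previous ended
            expect_true(all(GenomicRanges::start(g)[-1] ==
                            GenomicRanges::end(g)[-length(g)] + 1L))
        }
    }
})

test_that("a full planted effect flips the dominant state in every group-B epigenome", {
    co <- toyCohort()  # effectSize 1.0, Tx -> ReprPC
    fm <- toyFeatureMatrix()
    dm <- dominantStateMatrix(fm, genes = co$truth$plantedGenes)
    groups <- co$truth$groups[rownames(dm)]
    pal <- co$palette
    src <- resolveStates(co$spec@sourceState, pal)
    tgt <- resolveStates(co$spec@targetState, pal)
    expect_true(all(dm[groups == "A", ] == src))
    expect_true(all(dm[groups == "B", ] == tgt))
})

test_that("cohort generation is deterministic and fixtures are byte-identical", {
    spec <- syntheticCohortSpec(seed = 77L, nGenes = 30L, nPerGroup = 3L,
                                chromLengths = c(chr1 = 6e5),
                                nPlanted = 5L)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    writeFixtures(generateCohort(spec), d1)
    writeFixtures(generateCohort(spec), d2)
    for (f in list.files(d1, recursive = TRUE)) {
        expect_identical(readLines(file.path(d1, f), warn = FALSE),
                         readLines(file.path(d2, f), warn = FALSE),
                         label = f)
    }
})

test_that("fixtures round-trip through the package readers", {
    spec <- syntheticCohortSpec(seed = 78L, nGenes = 25L, nPerGroup = 3L,
                                chromLengths = c(chr1 = 5e5),
                                nPlanted = 4L)
    co <- generateCohort(spec)
    d <- withr::local_tempdir()
    writeFixtures(co, d)

    seg <- readSegmentation(file.path(d, "segmentations", "E01.bed"),
                            epigenome = "E01")
    expect_identical(S4Vectors::mcols(segmentRanges(seg))$state,
                     S4Vectors::mcols(segmentRanges(
                         co$segmentations[["E01"]]))$state)

    genes <- readGenes(file.path(d, "genes.gtf"))
    expect_identical(S4Vectors::mcols(genes)$gene_id,
                     S4Vectors::mcols(co$genes)$gene_id)
    expect_identical(GenomicRanges::start(genes),
                     GenomicRanges::start(co$genes))

    md <- readMetadata(file.path(d, "metadata.tsv"))
    expect_identical(rownames(md), rownames(co$metadata))
    expect_identical(as.list(md$lab), as.list(co$metadata$lab))

    ex <- readExpression(file.path(d, "expression.tsv"))
    expect_identical(ex, co$expression)

    sets <- readGMT(file.path(d, "genesets.gmt"))
    expect_identical(sets$PLANTED_SET, toupper(co$truth$plantedGenes))

    truth <- jsonlite::read_json(file.path(d, "truth.json"),
                                 simplifyVector = TRUE)
    expect_identical(truth$plantedGenes, co$truth$plantedGenes)
})

test_that("a single-state genome yields the all-one-hot feature matrix", {
    freq <- rep(0, 15); freq[15] <- 1
    spec <- syntheticCohortSpec(seed = 79L, nGenes = 10L, nPerGroup = 2L,
                                chromLengths = c(chr1 = 4e5),
                                stateFreq = freq, nPlanted = 0L)
    co <- generateCohort(spec)
    fm <- buildFeatureMatrix(co$segmentations, co$genes)
    v <- featureValues(fm)
    expect_true(all(v[, featureStates(fm) == 15L] == 1))
    expect_true(all(v[, featureStates(fm) != 15L] == 0))
    ent <- apply(v[, featureGenes(fm) == "G0001"], 1, profileEntropy)
    expect_equal(unname(ent), rep(0, nrow(v)))
})

test_that("infeasible cohort specs are rejected", {
    expect_error(syntheticCohortSpec(geneLengthRange = c(2000, 5e6)),
                 "fit")
    expect_error(syntheticCohortSpec(effectSize = 1.5), "effectSize")
    expect_error(generateCohort(syntheticCohortSpec(
        seed = 1L, nGenes = 5000L, chromLengths = c(chr1 = 1e6))),
        "infeasible")
})

test_that("cohort specs round-trip through YAML", {
    spec <- syntheticCohortSpec(seed = 5L, nGenes = 12L,
                                effectSize = 0.4)
    yml <- withr::local_tempfile(fileext = ".yaml")
    writeCohortSpec(spec, yml)
    back <- readCohortSpec(yml)
    for (s in methods::slotNames("SyntheticCohortSpec"))
        expect_equal(methods::slot(back, s), methods::slot(spec, s),
                     label = s)
})

test_that("plantConfounder controls the group/lab correlation", {
    co <- toyCohort()
    expect_error(plantConfounder(co, rho = 1), "perfect")
    co0 <- plantConfounder(co, rho = 0, seed = 2L)
    co6 <- plantConfounder(co, rho = 0.6, seed = 2L)
    labOf <- function(x) vapply(rownames(x$metadata), function(id)
        x$metadata$lab[[match(id, rownames(x$metadata))]][1],
        character(1))
    pLab1 <- function(x, g) {
        ids <- names(x$truth$groups)[x$truth$groups == g]
        mean(labOf(x)[ids] == "Lab1")
    }
    expect_equal(pLab1(co0, "B") - pLab1(co0, "A"), 0)
    expect_equal(pLab1(co6, "B") - pLab1(co6, "A"), 0.6)
    expect_length(co6$truth$biasGenes, 50L)
    expect_length(intersect(co6$truth$biasGenes,
                            co6$truth$plantedGenes), 0L)
})

test_that("every generated cohort passes the io validators", {
    co <- toyCohort()
    for (seg in co$segmentations) expect_true(validObject(seg))
    expect_true(all(co$expression >= 0))
    expect_false(anyDuplicated(rownames(co$metadata)) > 0)
})
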