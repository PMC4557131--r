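test_that("gene state profiles follow the coverage-fraction definition", {
    # BED-style [0,150) Tx, [150,300) Quies; gene [100,200) -> half and half
    seg <- mkSegmentation("E1", "chr1", c(1, 151), c(150, 300), c(4, 15))
    gene <- mkGene("chr1", 101, 200)
    p <- geneStateProfile(seg, gene)
    expect_equal(unname(p[4]), 0.5)
    expect_equal(unname(p[15]), 0.5)
    expect_equal(sum(p), 1)

    inside <- mkGene("chr1", 10, 120)
    seg2 <- mkSegmentation("E1", "chr1", 1, 300, 4)
    p2 <- geneStateProfile(seg2, inside)
    expect_equal(unname(p2[4]), 1)
    expect_equal(sum(p2 > 0), 1L)
})

test_that("profiles match the per-basepair counting oracle exactly", {
    set.seed(11)
    for (rep in 1:5) {
        bounds <- sort(sample(1:3000, 9))
        starts <- c(1, bounds + 1)
        ends <- c(bounds, 3200)
        states <- sample(1:15, 10, replace = TRUE)
        seg <- mkSegmentation("E1", "chr1", starts, ends, states)
        gene <- mkGene("chr1", 1050, 2049)  # 1 kb
        expect_equal(as.numeric(geneStateProfile(seg, gene)),
                     oracleProfile(seg, gene))
    }
})

test_that("uncovered basepairs go to the background state with a warning", {
    seg <- mkSegmentation("E1", "chr1", 1, 150, 4)
    gene <- mkGene("chr1", 101, 200)
    expect_warning(p <- geneStateProfile(seg, gene), "background")
    expect_equal(unname(p[4]), 0.5)
    expect_equal(unname(p[15]), 0.5)

    geneY <- mkGene("chr2", 1, 100)
    expect_error(geneStateProfile(seg, geneY), "absent")
    expect_warning(pY <- geneStateProfile(seg, geneY,
                                          allowMissingChrom = TRUE))
    expect_equal(unname(pY[15]), 1)
})

test_that("feature matrix has gene-major columns and unit gene blocks", {
    co <- toyCohort()
    segs <- co$segmentations[1:3]
    genes <- co$genes[1:2]
    fm <- buildFeatureMatrix(segs, genes)
    expect_equal(dim(featureValues(fm)), c(3L, 30L))
    expect_equal(featureGenes(fm), rep(S4Vectors::mcols(genes)$gene_id,
                                       each = 15))
    expect_equal(featureStates(fm), rep(1:15, 2))
    for (g in unique(featureGenes(fm)))
        expect_equal(unname(rowSums(
            featureValues(fm)[, featureGenes(fm) == g])), rep(1, 3))

    # permuting epigenome order permutes rows only
    fm2 <- buildFeatureMatrix(segs, genes,
                              epigenomes = rev(epigenomeIds(fm)))
    expect_identical(featureValues(fm2),
                     featureValues(fm)[3:1, ])
    expect_error(buildFeatureMatrix(segs, genes, epigenomes = "EXX"),
                 "EXX")
})

test_that("whole-cohort feature matrix blocks sum to one", {
    fm <- toyFeatureMatrix()
    v <- featureValues(fm)
    sums <- t(rowsum(t(v), featureGenes(fm)))
    expect_lt(max(abs(sums - 1)), 1e-9)
    expect_false(anyNA(v))
})

test_that("splitting an interval into abutting same-state pieces changes nothing", {
    seg1 <- mkSegmentation("E1", "chr1", c(1, 201), c(200, 400), c(4, 4))
    seg2 <- mkSegmentation("E1", "chr1", 1, 400, 4)
    gene <- mkGene("chr1", 51, 350)
    expect_equal(geneStateProfile(seg1, gene),
                 geneStateProfile(seg2, gene))
})

test_that("flank extension widens gene bodies and clips at chromosome ends", {
    co <- toyCohort()
    genes <- co$genes[1:3]
    fm0 <- buildFeatureMatrix(co$segmentations[1:2], genes)
    fm1 <- buildFeatureMatrix(co$segmentations[1:2], genes,
                              flankUp = 500, flankDown = 1000)
    gl0 <- geneBodyLengths(fm0)
    gl1 <- geneBodyLengths(fm1)
    expect_true(all(gl1 <= gl0 + 1500))
    expect_true(all(gl1 > gl0))
})

test_that("entropy and divergence follow their closed forms", {
    one <- c(1, rep(0, 14))
    expect_equal(profileEntropy(one), 0)
    expect_equal(profileEntropy(rep(1 / 15, 15)), log2(15))
    expect_equal(profileEntropy(c(0.5, 0.5, rep(0, 13))), 1)
    expect_error(profileEntropy(c(-0.1, 1.1)), "non-negative")

    expect_equal(klDivergence(one, one), 0)
    expect_equal(klDivergence(one, rep(1 / 15, 15)), log2(15))
    p <- c(0.9, 0.1); q <- c(0.5, 0.5)
    expect_gt(klDivergence(p, q), 0)
    expect_gt(klDivergence(q, p), 0)
    expect_false(isTRUE(all.equal(klDivergence(p, q),
                                  klDivergence(q, p))))
    expect_equal(klDivergence(one, c(0, rep(1 / 14, 14))), Inf)
    expect_error(klDivergence(one, c(0.5, 0.5)), "length")
})

test_that("feature matrices round-trip through TSV exactly", {
    fm <- buildFeatureMatrix(toyCohort()$segmentations[1:3],
                             toyCohort()$genes[1:5])
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeFeatureMatrix(fm, tsv)
    back <- readFeatureMatrix(tsv)
    expect_identical(featureValues(back), featureValues(fm))
    expect_identical(featureGenes(back), featureGenes(fm))
    expect_identical(featureStates(back), featureStates(fm))
    expect_equal(geneBodyLengths(back), geneBodyLengths(fm))
})
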