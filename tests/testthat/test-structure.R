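.mkSigTable <- function(genes, nFeats, minPs) {
    rows <- do.call(rbind, lapply(seq_along(genes), function(i) {
        ps <- sort(minPs[i] * seq_len(nFeats[i]))
        data.frame(feature = sprintf("%s|%d", genes[i],
                                     seq_len(nFeats[i])),
                   gene = genes[i], state = seq_len(nFeats[i]),
                   p = ps, p_adj = ps, direction = 1,
                   significant = TRUE, stringsAsFactors = FALSE)
    }))
    rows
}

test_that("feature sampling is greedy by gene rank with exact cap truncation", {
    tab <- .mkSigTable(c("GA", "GB", "GC"), c(5, 5, 2),
                       c(1e-6, 1e-4, 1e-3))
    res <- mkResult(tab)
    s <- sampleFeatures(res, cap = 8)
    expect_length(s@features, 8L)
    expect_identical(s@genes, c("GA", "GB"))
    # GA contributes all 5, GB its best 3 by adjusted p
    expect_identical(s@features,
                     c(sprintf("GA|%d", 1:5), sprintf("GB|%d", 1:3)))

    # cap >= total keeps everything
    sAll <- sampleFeatures(res, cap = 100)
    expect_length(sAll@features, 12L)
    expect_identical(sAll@genes, c("GA", "GB", "GC"))
})

test_that("gene ties break on the most significant feature", {
    tab <- .mkSigTable(c("GX", "GY"), c(3, 3), c(1e-3, 1e-5))
    s <- sampleFeatures(mkResult(tab), cap = 4)
    expect_identical(s@genes[1], "GY")
    expect_identical(s@features[1:3], sprintf("GY|%d", 1:3))
})

test_that("sampling an empty significant set warns and returns empty", {
    tab <- .mkSigTable("GA", 2, 1e-4)
    tab$significant <- FALSE
    expect_warning(s <- sampleFeatures(mkResult(tab)), "no significant")
    expect_length(s@features, 0L)
    expect_error(sampleFeatures(mkResult(tab), cap = 0), "cap")
})

test_that("sampled size equals min(cap, total significant features)", {
    res <- toyResult()
    total <- length(significantFeatures(res))
    skip_if(total < 3)
    for (cap in c(1, total - 1, total, total + 50)) {
        s <- sampleFeatures(res, cap)
        expect_length(s@features, min(cap, total))
        expect_true(all(s@features %in% significantFeatures(res)))
    }
})

test_that("dominant states are the arg-max of raw fractions with low-index ties", {
    seg <- mkSegmentation("E1", "chr1", 1, 1000, 15)
    fm <- buildFeatureMatrix(list(seg), mkGene("chr1", 101, 300, "GQ"))
    expect_equal(unname(dominantStateMatrix(fm)[1, 1]), 15L)

    # 50/50 Tx (4) / Quies (15) -> Tx by the lowest-index rule
    seg2 <- mkSegmentation("E2", "chr1", c(1, 201), c(200, 400),
                           c(4, 15))
    fm2 <- buildFeatureMatrix(list(seg2), mkGene("chr1", 101, 300, "GT"))
    expect_equal(unname(dominantStateMatrix(fm2)[1, 1]), 4L)

    expect_error(dominantStateMatrix(toyCorrected()), "raw")
})

test_that("dominant-state matrix matches the per-basepair oracle argmax", {
    co <- toyCohort()
    segs <- co$segmentations[1:2]
    genes <- co$genes[1:4]
    fm <- buildFeatureMatrix(segs, genes)
    dm <- dominantStateMatrix(fm)
    for (e in 1:2) for (g in 1:4) {
        prof <- oracleProfile(segs[[e]], genes[g])
        expect_equal(dm[e, g], which.max(prof))
    }
})

test_that("complete-linkage clustering recovers separated blobs", {
    set.seed(40)
    blob <- rbind(matrix(rnorm(20 * 6, 0), ncol = 6),
                  matrix(rnorm(20 * 6, 12), ncol = 6))
    rownames(blob) <- sprintf("g%02d", 1:40)
    cl <- clusterGenes(blob, k = 2)
    expect_equal(length(unique(cl@labels[1:20])), 1L)
    expect_equal(length(unique(cl@labels[21:40])), 1L)
    expect_false(cl@labels[1] == cl@labels[21])
    expect_true(all(cl@annotated))

    # identical rows, k = 1: one cluster, zero merge heights
    same <- matrix(3, nrow = 5, ncol = 4,
                   dimnames = list(paste0("g", 1:5), NULL))
    cl1 <- clusterGenes(same, k = 1)
    expect_equal(unname(cl1@labels), rep(1L, 5))
    expect_equal(max(cl1@hclust$height), 0)
    expect_error(clusterGenes(same, k = 10), "exceeds")
})

test_that("small clusters are labelled but not annotated", {
    set.seed(41)
    m <- rbind(matrix(rnorm(97 * 4, 0), ncol = 4),
               matrix(rnorm(3 * 4, 30), ncol = 4))
    rownames(m) <- sprintf("g%03d", 1:100)
    cl <- clusterGenes(m, k = 2)
    sizes <- table(cl@labels)
    small <- names(sizes)[sizes == 3]
    expect_false(cl@annotated[[small]])  # 3% < 5%
    expect_length(cl@labels, 100L)
})

test_that("clustering is invariant to gene input order", {
    set.seed(42)
    m <- matrix(rnorm(30 * 5), ncol = 5,
                dimnames = list(sprintf("g%02d", 1:30), NULL))
    cl1 <- clusterGenes(m, k = 3)
    perm <- sample(30)
    cl2 <- clusterGenes(m[perm, ], k = 3)
    # same partition as sets of gene names
    part <- function(cl) unname(split(names(cl@labels), cl@labels))
    norm <- function(p) sort(vapply(p, function(g)
        paste(sort(g), collapse = ","), character(1)))
    expect_identical(norm(part(cl1)), norm(part(cl2)))
})

test_that("heatmap orderings are mean-ordered dendrogram leaves", {
    set.seed(43)
    m <- matrix(rnorm(7 * 5), nrow = 7,
                dimnames = list(paste0("r", 1:7), paste0("c", 1:5)))
    ord <- orderHeatmap(m)
    hcR <- hclust(dist(m), method = "complete")
    expect_identical(ord$rowOrder, oracleMeanOrder(hcR, rowMeans(m)))
    hcC <- hclust(dist(t(m)), method = "complete")
    expect_identical(ord$colOrder, oracleMeanOrder(hcC, colMeans(m)))

    # reversing input rows yields the same ordering of ids
    rev <- m[7:1, ]
    expect_identical(rownames(m)[ord$rowOrder],
                     rownames(rev)[orderHeatmap(rev)$rowOrder])

    expect_identical(orderHeatmap(m[1, , drop = FALSE])$rowOrder, 1L)
})

test_that("within-group ordering concatenates group A before group B", {
    set.seed(44)
    ids <- sprintf("E%02d", 1:8)
    m <- matrix(rnorm(8 * 6), nrow = 8, dimnames = list(ids, NULL))
    spec <- new("GroupSpec", property = "g", traitA = "A", traitB = "B",
                idsA = ids[1:4], idsB = ids[5:8])
    ord <- orderHeatmap(m, mode = "within-group", spec = spec)
    expect_setequal(rownames(m)[ord$rowOrder[1:4]], spec@idsA)
    expect_setequal(rownames(m)[ord$rowOrder[5:8]], spec@idsB)
    expect_error(orderHeatmap(m, mode = "within-group"), "GroupSpec")
})

test_that("feature-combination and expression heatmap matrices export correctly", {
    tab <- .mkSigTable(c("GA", "GB"), c(2, 1), c(1e-4, 1e-3))
    res <- mkResult(tab)
    s <- sampleFeatures(res, cap = 10)
    fc <- featureCombinationMatrix(s, res)
    expect_equal(dim(fc), c(15L, 2L))
    expect_equal(fc[1, "GA"], 1L)
    expect_equal(fc[2, "GA"], 2L)
    expect_true(is.na(fc[3, "GA"]))

    ex <- matrix(c(3, 7), 1, 2,
                 dimnames = list("GA", c("E1", "E2")))
    hm <- expressionHeatmapMatrix(ex, c("GA", "GB"), c("E1", "E2", "E9"))
    expect_equal(hm["E1", "GA"], log2(4))
    expect_true(all(is.na(hm["E9", ])))   # no expression data -> NA row
    expect_true(all(is.na(hm[, "GB"])))
})

test_that("dendrograms export as readable Newick", {
    set.seed(45)
    m <- matrix(rnorm(6 * 4), nrow = 6,
                dimnames = list(paste0("g", 1:6), NULL))
    cl <- clusterGenes(m, k = 2)
    nwk <- withr::local_tempfile(fileext = ".nwk")
    writeDendrogram(cl, nwk)
    tree <- ape::read.tree(nwk)
    expect_setequal(tree$tip.label, rownames(m))
})
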