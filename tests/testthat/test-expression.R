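.spec2 <- function(ids) {
    n <- length(ids)
    new("GroupSpec", property = "group", traitA = "A", traitB = "B",
        idsA = ids[seq_len(n / 2)], idsB = ids[-seq_len(n / 2)])
}

test_that("differential expression flags planted shifts and nothing else", {
    set.seed(30)
    ids <- sprintf("E%02d", 1:20)
    spec <- .spec2(ids)
    ex <- matrix(rlnorm(50 * 20, sdlog = 0.5), nrow = 50,
                 dimnames = list(sprintf("G%02d", 1:50), ids))
    ex[1:5, spec@idsB] <- ex[1:5, spec@idsB] * 10  # 10-fold planted shift
    de <- differentialExpression(ex, spec)
    expect_setequal(de$gene[de$de], sprintf("G%02d", 1:5))

    # identical distributions -> nothing significant
    ex0 <- matrix(rep(seq_len(50), 20), nrow = 50,
                  dimnames = dimnames(ex))
    de0 <- differentialExpression(ex0, spec)
    expect_false(any(de0$de))
})

test_that("genes without expression data are excluded from m", {
    set.seed(31)
    ids <- sprintf("E%02d", 1:10)
    spec <- .spec2(ids)
    ex <- matrix(rlnorm(30), nrow = 3,
                 dimnames = list(c("G1", "G2", "G3"), ids))
    de <- differentialExpression(ex, spec, genes = c("G1", "G2", "G3",
                                                     "G4"))
    expect_true(de$no_data[de$gene == "G4"])
    expect_true(is.na(de$p_adj[de$gene == "G4"]))
    # m = 3: BH multiplies by tested genes only
    expect_equal(sum(!de$no_data), 3L)
})

test_that("deProportions splits counts for the odds-ratio margins", {
    de <- data.frame(gene = c("A", "B", "C", "D", "E"),
                     p = 0.5, p_adj = 0.5,
                     de = c(TRUE, FALSE, TRUE, FALSE, FALSE),
                     no_data = c(FALSE, FALSE, FALSE, FALSE, TRUE))
    sp <- deProportions(de, c("A", "B"))
    expect_equal(unname(sp$counts), c(1, 1, 1, 1))
    expect_equal(sp$propIn, 0.5)
    expect_equal(sp$nDropped, 1L)
})

test_that("pooled cluster test equals the test on concatenated values", {
    set.seed(32)
    ids <- sprintf("E%02d", 1:12)
    spec <- .spec2(ids)
    ex <- matrix(rlnorm(4 * 12), nrow = 4,
                 dimnames = list(paste0("G", 1:4), ids))
    p <- clusterExpressionTest(paste0("G", 1:4), ex, spec)
    expect_equal(p, groupTest(as.numeric(ex[, spec@idsA]),
                              as.numeric(ex[, spec@idsB])))
    # one gene, identical groups
    ex1 <- ex; ex1[1, ] <- 7
    expect_equal(clusterExpressionTest("G1", ex1, spec), 1)
    expect_error(clusterExpressionTest(character(0), ex, spec), "empty")
})

test_that("a planted cluster-wide shift is detected reliably", {
    set.seed(33)
    ids <- sprintf("E%02d", 1:20)
    spec <- .spec2(ids)
    hits <- 0L
    for (i in 1:100) {
        ex <- matrix(rlnorm(5 * 20), nrow = 5,
                     dimnames = list(paste0("G", 1:5), ids))
        ex[, spec@idsB] <- ex[, spec@idsB] * 3
        if (clusterExpressionTest(paste0("G", 1:5), ex, spec) < 0.05)
            hits <- hits + 1L
    }
    expect_gte(hits, 95L)
})

test_that("log odds ratio reproduces the worked example", {
    or <- logOddsRatio(10, 10, 5, 20)
    expect_equal(or@lnOR, log(4), tolerance = 1e-4)
    expect_equal(or@se, sqrt(0.45), tolerance = 1e-4)
    expect_equal(or@ciLow, log(4) - 1.96 * sqrt(0.45), tolerance = 1e-4)
    expect_equal(or@ciHigh, log(4) + 1.96 * sqrt(0.45), tolerance = 1e-4)
    expect_true(isSignificantOR(or))

    balanced <- logOddsRatio(5, 5, 5, 5)
    expect_equal(balanced@lnOR, 0)
    expect_false(isSignificantOR(balanced))
    # z = 0 -> p = 1 under the printed approximation
    expect_equal(balanced@p, 1)
})

test_that("log odds ratio is antisymmetric and handles zero cells", {
    o1 <- logOddsRatio(10, 10, 5, 20)
    o2 <- logOddsRatio(5, 20, 10, 10)
    expect_equal(o1@lnOR, -o2@lnOR)
    expect_equal(o1@se, o2@se)

    oz <- logOddsRatio(0, 10, 5, 20)
    expect_true(oz@haldane)
    expect_equal(unname(oz@counts), c(0.5, 10.5, 5.5, 20.5))
    expect_error(logOddsRatio(0, 0, 5, 20), "margin")
    expect_error(logOddsRatio(0, 10, 0, 20), "margin")
    expect_error(logOddsRatio(-1, 1, 1, 1), "non-negative")
})

test_that("the printed p(z) approximation tracks the normal tail closely for moderate z", {
    for (z in seq(0.5, 3, by = 0.25)) {
        approx <- exp(-0.717 * z - 0.416 * z^2)
        exact <- 2 * pnorm(-z)
        expect_lt(abs(approx / exact - 1), 0.10)
    }
    # beyond z ~ 3.5 the approximation drifts upward but keeps the order
    # of magnitude; both remain monotone decreasing
    zs <- seq(3, 5, 0.5)
    expect_true(all(diff(exp(-0.717 * zs - 0.416 * zs^2)) < 0))
})
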