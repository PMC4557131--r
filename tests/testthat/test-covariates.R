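test_that("fractional membership encoding follows the 1/n rule", {
    md <- mkMetadata(c("E1", "E2", "E3", "E4"),
        sex = list("Male", c("Male", "Female"), "Female", "Female"),
        lab = list(c("BI", "UCSD"), "BI", "UW", character(0)),
        state = list("Solid", "Liquid", "Solid", "Solid"))
    d <- encodeCovariates(md, c("sex", "lab", "state"))
    X <- designMatrix(d)
    expect_equal(unname(X[, "(Intercept)"]), rep(1, 4))
    # two labs -> 1/2 each
    expect_equal(unname(X["E1", c("lab:BI", "lab:UCSD", "lab:UW")]),
                 c(0.5, 0.5, 0))
    # mixed-sex donors -> 1/2, 1/2
    expect_equal(unname(X["E2", c("sex:Female", "sex:Male")]),
                 c(0.5, 0.5))
    # single-valued -> plain indicator
    expect_equal(unname(X["E3", c("sex:Female", "sex:Male")]), c(1, 0))
    expect_equal(unname(X["E1", c("state:Liquid", "state:Solid")]),
                 c(0, 1))
    # missing property -> all-zero block
    expect_equal(unname(X["E4", c("lab:BI", "lab:UCSD", "lab:UW")]),
                 c(0, 0, 0))
    # within-property rows sum to 1 (or 0 when missing)
    labBlock <- X[, d@property == "lab"]
    expect_equal(unname(rowSums(labBlock)), c(1, 1, 1, 0))
    expect_error(encodeCovariates(md, "nope"), "nope")
})

test_that("deviance residuals match glm and an independent Newton oracle", {
    set.seed(42)
    n <- 8
    N <- sample(200:2000, n)
    X <- cbind(1, f1 = rep(c(1, 0), 4), f2 = rep(c(0, 1), 4),
               l1 = c(1, 1, 1, 0.5, 0, 0, 0, 0.5),
               l2 = c(0, 0, 0, 0.5, 1, 1, 1, 0.5))
    for (rep in 1:5) {
        y <- rbinom(n, N, plogis(-1 + 0.8 * X[, 2] + 0.3 * X[, 4])) / N
        r <- devianceResiduals(y, N, X)
        fit <- suppressWarnings(
            glm(y ~ X[, -1], family = binomial, weights = N))
        expect_lt(max(abs(r - residuals(fit, type = "deviance"))), 1e-6)
        expect_lt(max(abs(r - oracleNRResiduals(y, N, X))), 1e-6)
    }
})

test_that("perfect fits give zero residuals", {
    # all y equal, intercept-only
    r <- devianceResiduals(rep(0.3, 8), 1000, matrix(1, 8, 1))
    expect_lt(max(abs(r)), 1e-8)
    # design that separates the two observed levels exactly (saturated)
    X <- cbind(1, rep(c(1, 0), each = 4))
    y <- rep(c(0.2, 0.7), each = 4)
    r2 <- devianceResiduals(y, 500, X)
    expect_lt(max(abs(r2)), 1e-6)
})

test_that("residual sign tracks observed minus fitted coverage", {
    set.seed(3)
    y <- runif(10)
    r <- devianceResiduals(y, 100, matrix(1, 10, 1))
    fitted <- attr(r, "fitted")
    expect_equal(sign(r[r != 0]), sign((y - fitted)[r != 0]))
})

test_that("residuals are invariant to design parameterization", {
    set.seed(7)
    X <- cbind(1, rep(c(1, 0), 5), rep(c(0, 1), 5))
    y <- rbinom(10, 300, 0.4) / 300
    r1 <- devianceResiduals(y, 300, X)
    r2 <- devianceResiduals(y, 300, cbind(X, X[, 2], X[, 3]))
    expect_equal(as.numeric(r1), as.numeric(r2), tolerance = 1e-10)
})

test_that("invalid residual inputs error", {
    expect_error(devianceResiduals(c(0.2, 1.4), 10, matrix(1, 2, 1)),
                 "0, 1")
    expect_error(devianceResiduals(c(0.2, 0.4), 0.5, matrix(1, 2, 1)),
                 ">= 1")
})

test_that("feature correction excludes the tested property and matches per-column fits", {
    co <- toyCohort()
    fm <- buildFeatureMatrix(co$segmentations, co$genes[1:10])
    expect_message(
        cm <- correctFeatures(fm, co$metadata, "sex",
                              covariateProperties = c("sex", "lab",
                                                      "type", "state")),
        "excluding tested property")
    # column-by-column: equality with isolated single-feature fits
    d <- encodeCovariates(co$metadata, c("lab", "type", "state"),
                          ids = epigenomeIds(fm))
    gl <- geneBodyLengths(fm)
    set.seed(5)
    for (j in sample(ncol(featureValues(fm)), 8)) {
        r <- devianceResiduals(featureValues(fm)[, j],
                               gl[featureGenes(fm)[j]], d)
        # near-zero residuals carry BLAS-order noise of ~1e-6; residual
        # magnitudes are O(10-100), so 1e-5 absolute is exact agreement
        expect_lt(max(abs(unname(featureValues(cm)[, j]) -
                          as.numeric(r))), 1e-5)
    }
    expect_error(correctFeatures(fm, co$metadata, "nope"), "nope")
})

test_that("row order of the corrected matrix follows the input rows", {
    co <- toyCohort()
    fm1 <- buildFeatureMatrix(co$segmentations, co$genes[1:5])
    ids <- rev(epigenomeIds(fm1))
    fm2 <- buildFeatureMatrix(co$segmentations, co$genes[1:5],
                              epigenomes = ids)
    cm1 <- suppressWarnings(correctFeatures(fm1, co$metadata, "group"))
    cm2 <- suppressWarnings(correctFeatures(fm2, co$metadata, "group"))
    expect_identical(rownames(featureValues(cm2)), ids)
    expect_lt(max(abs(featureValues(cm2) -
                      featureValues(cm1)[ids, ])), 1e-5)
})

test_that("expression correction is least squares on the same design", {
    co <- toyCohort()
    ex <- co$expression[1:20, ]
    res <- correctExpression(ex, co$metadata, "group")
    # normal-equation oracle
    X <- designMatrix(encodeCovariates(co$metadata,
                                       defaultCovariates(co$metadata),
                                       ids = colnames(ex)))
    Xr <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
    H <- Xr %*% solve(crossprod(Xr)) %*% t(Xr)
    oracle <- t((diag(ncol(ex)) - H) %*% t(ex))
    expect_lt(max(abs(res - oracle)), 1e-8)

    # intercept-only design -> mean-centred values
    md1 <- mkMetadata(colnames(ex), group = as.list(
        rep(c("A", "B"), length.out = ncol(ex))))
    res1 <- correctExpression(ex, md1, "group",
                              covariateProperties = character(0))
    expect_equal(res1, ex - rowMeans(ex), tolerance = 1e-10,
                 ignore_attr = TRUE)

    # constant gene -> all-zero residuals, no error
    ex2 <- rbind(ex, CONST = 5)
    res2 <- correctExpression(ex2, co$metadata, "group")
    expect_equal(unname(res2["CONST", ]), rep(0, ncol(ex)),
                 tolerance = 1e-10)
})

test_that("a pure-noise covariate perturbs residuals only slightly at scale", {
    set.seed(21)
    deltas <- vapply(c(20, 80), function(n) {
        X <- cbind(1, rep(c(1, 0), n / 2))
        y <- rbinom(n, 400, plogis(-0.5 + X[, 2])) / 400
        r1 <- devianceResiduals(y, 400, X)
        r2 <- devianceResiduals(y, 400, cbind(X, rnorm(n)))
        sqrt(mean((r1 - r2)^2))
    }, numeric(1))
    expect_lt(deltas[2], deltas[1])
})
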