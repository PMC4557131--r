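#' @include AllClasses.R AllGenerics.R features.R io-metadata.R
NULL

#' Default covariate property names
#'
#' The four external properties corrected for by default when present in the
#' metadata: donor sex, processing lab, sample type and solid/liquid sample
#' state.
#' @param metadata DataFrame from [readMetadata()].
#' @return character vector of property names found in the metadata.
#' @export
defaultCovariates <- function(metadata)
    intersect(c("sex", "lab", "type", "state"), names(metadata))

#' Encode metadata as fractional-membership explanatory variables
#'
#' Each property contributes one column per observed level. A sample
#' annotated with n levels of a property gets 1/n in each matching column
#' (e.g. an epigenome processed by two labs carries 1/2 in both lab
#' columns); a single-valued sample gets a plain 1/0 indicator; a sample
#' with the property missing gets an all-zero block. An intercept column is
#' always included.
#'
#' @param metadata DataFrame from [readMetadata()].
#' @param properties property columns to encode.
#' @param ids epigenome ids (row order); default all metadata rows.
#' @return a [CovariateDesign-class].
#' @export
encodeCovariates <- function(metadata, properties, ids = NULL) {
    if (is.null(ids)) ids <- rownames(metadata)
    miss <- setdiff(properties, names(metadata))
    if (length(miss) > 0L)
        stop("properties not in metadata: ", paste(miss, collapse = ", "))
    cols <- list(`(Intercept)` = rep(1, length(ids)))
    prop <- "(Intercept)"
    ridx <- match(ids, rownames(metadata))
    if (anyNA(ridx))
        stop("epigenome ids missing from metadata: ",
             paste(ids[is.na(ridx)], collapse = ", "))
    for (p in properties) {
        levels <- propertyLevels(metadata, p)
        vals <- metadata[[p]][ridx]
        for (lv in levels) {
            cols[[paste0(p, ":", lv)]] <- vapply(vals, function(v) {
                if (length(v) == 0L) 0 else (lv %in% v) / length(v)
            }, numeric(1))
            prop <- c(prop, p)
        }
    }
    design <- do.call(cbind, cols)
    rownames(design) <- ids
    new("CovariateDesign", design = design, property = prop)
}

setMethod("designMatrix", "CovariateDesign", function(x) x@design)
setMethod("epigenomeIds", "CovariateDesign",
          function(x) rownames(x@design))

setMethod("show", "CovariateDesign", function(object) {
    props <- setdiff(unique(object@property), "(Intercept)")
    cat(sprintf("CovariateDesign: %d epigenomes x %d columns (%s)\n",
                nrow(object@design), ncol(object@design),
                paste(props, collapse = ", ")))
})

.ylogy <- function(y, mu) {
    r <- y * log(y / mu)
    r[y <= 0] <- 0
    r
}

.binomDevianceCells <- function(Y, MU, W)
    2 * W * (.ylogy(Y, MU) + .ylogy(1 - Y, 1 - MU))

# Batched IRLS for per-column binomial logistic fits sharing one design.
# Complete one-hot level blocks plus an intercept are rank-deficient by
# construction; the design is reduced once to a full-rank column basis
# (pivoted QR), which leaves fitted values and hence residuals unchanged
# and independent of level ordering.
.irlsBinomial <- function(Y, W, X, maxIter = 25L, tol = 1e-12,
                          clip = 1e-10) {
    n <- nrow(Y); C <- ncol(Y)
    qrX <- qr(X)
    Xr <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    p <- ncol(Xr)
    # p^2 x n unfolding of the per-observation outer products, so that
    # X' W_j X for every column j is a single matrix product
    Xouter <- t(Xr[, rep(seq_len(p), times = p), drop = FALSE] *
                Xr[, rep(seq_len(p), each = p), drop = FALSE])
    MU <- (W * Y + 0.5) / (W + 1)
    ETA <- log(MU / (1 - MU))
    dev <- colSums(.binomDevianceCells(Y, MU, W))
    mu0 <- colSums(W * Y) / colSums(W)
    MU0 <- matrix(mu0, n, C, byrow = TRUE)
    nullDev <- colSums(.binomDevianceCells(Y, MU0, W))
    active <- rep(TRUE, C)
    iters <- integer(C)
    converged <- rep(FALSE, C)
    for (it in seq_len(maxIter)) {
        if (!any(active)) break
        varmu <- MU * (1 - MU)
        Wir <- W * varmu
        Z <- ETA + (Y - MU) / varmu
        A <- Xouter %*% Wir[, active, drop = FALSE]   # p^2 x C_active
        B <- crossprod(Xr, (Wir * Z)[, active, drop = FALSE])
        beta <- .batchCholSolve(A, B)
        solved <- attr(beta, "ok")
        idx <- which(active)
        active[idx[!solved]] <- FALSE
        if (any(solved))
            ETA[, idx[solved]] <- Xr %*% beta[, solved, drop = FALSE]
        MU <- stats::plogis(ETA)
        MU[MU < clip] <- clip
        MU[MU > 1 - clip] <- 1 - clip
        newdev <- colSums(.binomDevianceCells(Y, MU, W))
        done <- active &
            (abs(newdev - dev) / (abs(newdev) + 0.1) < tol)
        iters[active] <- it
        converged[done] <- TRUE
        active <- active & !done
        dev <- newdev
    }
    cells <- .binomDevianceCells(Y, MU, W)
    cells[cells < 0] <- 0
    list(residuals = sign(Y - MU) * sqrt(cells), fitted = MU,
         converged = converged, iterations = iters,
         nullDeviance = nullDev, deviance = dev)
}

#' Deviance residuals of a binomial logistic fit
#'
#' Fits logit(pi) = beta0 + sum(beta_i x_i) by iteratively reweighted least
#' squares with prior weights N (the fractional response y = successes / N
#' formulation) and returns the signed deviance residuals
#' d_i = sign(y_i - pihat_i) * sqrt(dev_i). These residuals are the
#' covariate-corrected feature values: positive when the observed coverage
#' exceeds the covariate-predicted coverage.
#'
#' @param y fractions in [0, 1], one per epigenome.
#' @param weights binomial trial counts N (>= 1), recycled.
#' @param design a [CovariateDesign-class] or numeric design matrix with
#'   intercept.
#' @param maxIter,tol IRLS iteration cap and deviance-change tolerance.
#' @return numeric residual vector with attributes \code{converged},
#'   \code{iterations} and \code{fitted}.
#' @export
devianceResiduals <- function(y, weights, design, maxIter = 25L,
                              tol = 1e-12) {
    X <- if (is(design, "CovariateDesign")) design@design else design
    if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
    w <- rep_len(weights, length(y))
    if (any(w < 1)) stop("trial counts must be >= 1")
    fit <- .irlsBinomial(matrix(y, ncol = 1), matrix(w, ncol = 1), X,
                         maxIter = maxIter, tol = tol)
    r <- as.numeric(fit$residuals)
    attr(r, "converged") <- fit$converged[1L]
    attr(r, "iterations") <- fit$iterations[1L]
    attr(r, "fitted") <- as.numeric(fit$fitted)
    r
}

#' Covariate-correct a feature matrix
#'
#' Replaces every raw (gene, state) coverage fraction by its deviance
#' residual from a per-feature binomial logistic regression on the covariate
#' design, excluding the tested property so the group signal is not
#' regressed away. The binomial trial count for a feature is the gene-body
#' length N = end - start, converting each fraction into y * N successes and
#' (1 - y) * N failures.
#'
#' @param fm a [FeatureMatrix-class].
#' @param metadata DataFrame from [readMetadata()].
#' @param testedProperty metadata property under comparison (excluded from
#'   the design).
#' @param covariateProperties properties to correct for; defaults to
#'   [defaultCovariates()]. The tested property is dropped from this list
#'   automatically (with a message) if present.
#' @param maxIter,tol IRLS controls.
#' @return a [CorrectedMatrix-class] (same shape; diagnostics attached).
#' @export
correctFeatures <- function(fm, metadata, testedProperty,
                            covariateProperties = defaultCovariates(metadata),
                            maxIter = 25L, tol = 1e-12) {
    if (!testedProperty %in% names(metadata))
        stop("tested property not in metadata: ", testedProperty)
    if (testedProperty %in% covariateProperties) {
        message("excluding tested property '", testedProperty,
                "' from the covariate design")
        covariateProperties <- setdiff(covariateProperties, testedProperty)
    }
    ids <- rownames(fm@values)
    design <- encodeCovariates(metadata, covariateProperties, ids = ids)
    W <- matrix(fm@geneLengths[fm@geneIds], nrow = length(ids),
                ncol = ncol(fm@values), byrow = TRUE)
    fit <- .irlsBinomial(fm@values, W, design@design, maxIter = maxIter,
                         tol = tol)
    if (any(!fit$converged))
        warning(sum(!fit$converged), " feature fit(s) not converged after ",
                maxIter, " iterations")
    res <- fit$residuals
    dimnames(res) <- dimnames(fm@values)
    new("CorrectedMatrix", values = res, geneIds = fm@geneIds,
        stateIndex = fm@stateIndex, geneLengths = fm@geneLengths,
        palette = fm@palette, testedProperty = testedProperty,
        diagnostics = data.frame(
            feature = colnames(fm@values), converged = fit$converged,
            iterations = fit$iterations,
            null_deviance = fit$nullDeviance,
            residual_deviance = fit$deviance,
            stringsAsFactors = FALSE))
}

#' Covariate-correct an expression matrix
#'
#' Same design as [correctFeatures()], but ordinary least squares per gene
#' (RPKM is unbounded, so linear rather than logistic regression); returns
#' the raw residuals.
#'
#' @param expr numeric matrix, genes x epigenomes ([readExpression()]).
#' @inheritParams correctFeatures
#' @return matrix of residuals, genes x epigenomes (same columns).
#' @export
correctExpression <- function(expr, metadata, testedProperty,
                              covariateProperties =
                                  defaultCovariates(metadata)) {
    if (!testedProperty %in% names(metadata))
        stop("tested property not in metadata: ", testedProperty)
    covariateProperties <- setdiff(covariateProperties, testedProperty)
    ids <- intersect(colnames(expr), rownames(metadata))
    design <- encodeCovariates(metadata, covariateProperties, ids = ids)
    X <- design@design
    qrX <- qr(X)
    Xr <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    res <- t(qr.resid(qr(Xr), t(expr[, ids, drop = FALSE])))
    dimnames(res) <- list(rownames(expr), ids)
    res
}

#' Write per-feature correction diagnostics to TSV
#' @param cm a [CorrectedMatrix-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDiagnostics <- function(cm, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(
        "#feature\tconverged\titerations\tnull_deviance\tresidual_deviance",
        con)
    d <- cm@diagnostics
    writeLines(sprintf("%s\t%s\t%d\t%.17g\t%.17g", d$feature,
                       ifelse(d$converged, "TRUE", "FALSE"), d$iterations,
                       d$null_deviance, d$residual_deviance), con)
    invisible(path)
}
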