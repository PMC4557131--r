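#' @include AllClasses.R comparison.R covariates.R
NULL

#' Shuffle the group labels of a comparison
#'
#' Draws a new group A uniformly without replacement from the pooled
#' epigenomes X = A u B, retaining the original group sizes; group B is the
#' complement. The real grouping may be drawn by chance (uniform sampling).
#'
#' @param spec a [GroupSpec-class].
#' @param seed integer seed (required: every shuffle is reproducible).
#' @return a shuffled [GroupSpec-class].
#' @export
shuffleLabels <- function(spec, seed) {
    pool <- c(spec@idsA, spec@idsB)
    if (length(pool) < 2L) stop("need at least 2 epigenomes to shuffle")
    set.seed(seed)
    idsA <- sample(pool, length(spec@idsA))
    new("GroupSpec", property = spec@property,
        traitA = paste0(spec@traitA, "'"),
        traitB = paste0(spec@traitB, "'"),
        idsA = idsA, idsB = setdiff(pool, idsA))
}

#' Label-shuffling null calibration of a comparison
#'
#' Repeats the full test on randomly relabelled groups of matched size and
#' counts how often any significant feature appears — if the real
#' comparison picks up biology, shuffled groupings should essentially never
#' produce hits. Per-trial seeds are spawned up front from the master seed,
#' so individual trials are reproducible and the report is independent of
#' execution order.
#'
#' The covariate design excludes only the tested property and every fit
#' uses all pooled epigenomes, so the corrected matrix is mathematically
#' identical for every relabelling; by default the correction supplied in
#' \code{cm} is reused. Set \code{recorrect = TRUE} to recompute it each
#' trial from \code{fm} (same result, at full cost).
#'
#' @param cm the [CorrectedMatrix-class] of the real comparison.
#' @param spec a [GroupSpec-class].
#' @param test,correction,alpha as in [compareGroups()].
#' @param nTrials number of shuffles (default 100).
#' @param seed master seed.
#' @param recorrect recompute the covariate correction per trial.
#' @param fm,metadata,covariateProperties inputs for recorrection (needed
#'   only when \code{recorrect = TRUE}).
#' @return a [RandomizationReport-class].
#' @export
runRandomization <- function(cm, spec, test = "mww", correction = "bh",
                             alpha = 0.05, nTrials = 100L, seed = 1L,
                             recorrect = FALSE, fm = NULL, metadata = NULL,
                             covariateProperties = NULL) {
    if (nTrials < 1L) stop("nTrials must be >= 1")
    set.seed(seed)
    trialSeeds <- sample.int(.Machine$integer.max, nTrials)
    pool <- c(spec@idsA, spec@idsB)
    nA <- length(spec@idsA)
    fastMWW <- !recorrect && test == "mww"
    if (fastMWW) {
        # ranks are invariant under label shuffling: precompute once
        sub <- cm@values[pool, , drop = FALSE]
        R <- apply(sub, 2, rank)
        tieSums <- apply(R, 2, .tieSum)
    }
    counts <- vapply(seq_len(nTrials), function(i) {
        sspec <- shuffleLabels(spec, trialSeeds[i])
        if (fastMWW) {
            idxA <- match(sspec@idsA, pool)
            W <- colSums(R[idxA, , drop = FALSE]) - nA * (nA + 1) / 2
            p <- .mwwPVec(W, nA, length(sspec@idsB), tieSums)
            return(sum(adjustPvalues(p, correction) < alpha))
        }
        mat <- if (recorrect) {
            if (is.null(fm) || is.null(metadata))
                stop("recorrect = TRUE needs fm and metadata")
            cp <- if (is.null(covariateProperties))
                defaultCovariates(metadata) else covariateProperties
            correctFeatures(fm, metadata, spec@property,
                            covariateProperties = cp)
        } else cm
        res <- compareGroups(mat, sspec, test = test,
                             correction = correction, alpha = alpha)
        length(significantFeatures(res))
    }, integer(1))
    new("RandomizationReport",
        comparison = sprintf("%s:%s_vs_%s", spec@property, spec@traitA,
                             spec@traitB),
        nTrials = as.integer(nTrials), counts = counts,
        nWithAny = sum(counts > 0L),
        fractionWithAny = mean(counts > 0L), seed = as.integer(seed))
}

setMethod("show", "RandomizationReport", function(object) {
    cat(sprintf(
        "RandomizationReport %s: %d/%d trials with any significant feature (%.3f)\n",
        object@comparison, object@nWithAny, object@nTrials,
        object@fractionWithAny))
})

#' Roll up randomization reports across comparisons
#'
#' @param reports list of [RandomizationReport-class].
#' @return data.frame with one row per comparison plus a "total" row
#'   aggregating all trials.
#' @export
rollupRandomization <- function(reports) {
    rows <- data.frame(
        comparison = vapply(reports, function(r) r@comparison,
                            character(1)),
        n_trials = vapply(reports, function(r) r@nTrials, integer(1)),
        n_with_any = vapply(reports, function(r) r@nWithAny, integer(1)),
        stringsAsFactors = FALSE)
    rows$fraction_with_any <- rows$n_with_any / rows$n_trials
    total <- data.frame(comparison = "total",
                        n_trials = sum(rows$n_trials),
                        n_with_any = sum(rows$n_with_any),
                        stringsAsFactors = FALSE)
    total$fraction_with_any <- total$n_with_any / total$n_trials
    rbind(rows, total)
}

#' Write a randomization report (or roll-up) to TSV
#' @param x a [RandomizationReport-class] or a roll-up data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeRandomization <- function(x, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (is(x, "RandomizationReport")) {
        writeLines("#comparison\ttrial\tn_significant", con)
        writeLines(sprintf("%s\t%d\t%d", x@comparison,
                           seq_len(x@nTrials), x@counts), con)
    } else {
        writeLines("#comparison\tn_trials\tn_with_any\tfraction_with_any",
                   con)
        writeLines(sprintf("%s\t%d\t%d\t%.17g", x$comparison, x$n_trials,
                           x$n_with_any, x$fraction_with_any), con)
    }
    invisible(path)
}
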