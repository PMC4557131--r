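#' @include AllClasses.R comparison.R
NULL

#' Storey q-values
#'
#' Estimates the null proportion pi0 on a lambda grid (0.05 to 0.90, step
#' 0.05) with a cubic smoothing spline evaluated at the grid end, clips it
#' to (0, 1], and multiplies the Benjamini-Hochberg step-up values by pi0.
#' With fewer than 20 p-values the pi0 estimate is unstable, so it falls
#' back to 1 (plain BH) with a warning.
#'
#' @param p p-values in [0, 1].
#' @param lambda grid of tuning values for the pi0 estimate.
#' @return q-values, nondecreasing in p.
#' @export
storeyQvalues <- function(p, lambda = seq(0.05, 0.90, by = 0.05)) {
    if (length(p) < 1L) stop("need at least one p-value")
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    m <- length(p)
    if (m < 20L) {
        warning("fewer than 20 p-values; using pi0 = 1 (plain BH)")
        pi0 <- 1
    } else {
        pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l),
                       numeric(1))
        fit <- stats::smooth.spline(lambda, pi0l, df = 3)
        pi0 <- stats::predict(fit, x = max(lambda))$y
        pi0 <- min(max(pi0, 1 / m), 1)
    }
    pi0 * stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation of a gene list
#'
#' One-sided hypergeometric upper-tail p (equivalently one-sided Fisher's
#' exact test) per gene set, against a fixed gene universe, with Storey
#' q-values across all tested sets. Sets are intersected with the universe
#' first; sets with empty intersection are skipped.
#'
#' @param query gene symbols of interest (must be contained in the
#'   universe; matched case-insensitively).
#' @param universe all symbols eligible for selection.
#' @param sets named list of symbol vectors ([readGMT()]).
#' @return data.frame: set, overlap, query_size, set_size, universe_size,
#'   p, q; sorted by q then p.
#' @export
geneSetEnrichment <- function(query, universe, sets) {
    query <- unique(toupper(query))
    universe <- unique(toupper(universe))
    if (length(query) == 0L) stop("empty query gene list")
    out <- setdiff(query, universe)
    if (length(out) > 0L)
        stop("query genes outside the universe: ",
             paste(utils::head(out, 5L), collapse = ", "))
    N <- length(universe)
    n <- length(query)
    rows <- lapply(names(sets), function(nm) {
        s <- intersect(toupper(sets[[nm]]), universe)
        if (length(s) == 0L) return(NULL)
        a <- length(intersect(query, s))
        K <- length(s)
        p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(set = nm, overlap = a, query_size = n, set_size = K,
                   universe_size = N, p = p, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L)
        return(data.frame(set = character(0), overlap = integer(0),
                          query_size = integer(0), set_size = integer(0),
                          universe_size = integer(0), p = numeric(0),
                          q = numeric(0), stringsAsFactors = FALSE))
    df <- do.call(rbind, rows)
    df$q <- suppressWarnings(storeyQvalues(df$p))
    df[order(df$q, df$p, df$set), , drop = FALSE]
}

#' Write an enrichment table to TSV
#' @param enr data.frame from [geneSetEnrichment()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeEnrichment <- function(enr, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#set\toverlap\tquery_size\tset_size\tuniverse_size\tp\tq",
               con)
    if (nrow(enr) > 0L)
        writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t%.17g\t%.17g", enr$set,
                           enr$overlap, enr$query_size, enr$set_size,
                           enr$universe_size, enr$p, enr$q), con)
    invisible(path)
}
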