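#' @include AllClasses.R
NULL

#' Read a gene expression matrix (RPKM)
#'
#' TSV with a header line (optionally "#"-prefixed): first column gene id,
#' remaining columns epigenome ids. Epigenomes without expression data are
#' simply absent as columns (never zero-filled); downstream analyses
#' exclude them.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x epigenomes, non-negative.
#' @export
readExpression <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("expression file has no data rows: ", path)
    header <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
    epi <- header[-1L]
    cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
    genes <- vapply(cells, `[`, character(1), 1L)
    if (anyDuplicated(genes))
        stop("duplicate gene ids in expression matrix")
    vals <- matrix(NA_real_, nrow = length(genes), ncol = length(epi),
                   dimnames = list(genes, epi))
    for (i in seq_along(cells)) {
        raw <- cells[[i]][-1L]
        if (length(raw) != length(epi))
            stop(sprintf("expression row %d has %d values, expected %d",
                         i, length(raw), length(epi)))
        num <- suppressWarnings(as.numeric(raw))
        if (anyNA(num)) {
            j <- which(is.na(num))[1L]
            stop(sprintf("non-numeric expression value '%s' at gene %s, %s",
                         raw[j], genes[i], epi[j]))
        }
        vals[i, ] <- num
    }
    if (any(vals < 0)) stop("negative RPKM values are not allowed")
    vals
}

#' Write an expression matrix to TSV
#' @param expr numeric matrix, genes x epigenomes.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeExpression <- function(expr, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#gene\t", paste(colnames(expr), collapse = "\t")),
               con)
    body <- vapply(seq_len(nrow(expr)), function(i)
        paste(c(rownames(expr)[i],
                sprintf("%.17g", expr[i, ])),
              collapse = "\t"), character(1))
    writeLines(body, con)
    invisible(path)
}
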