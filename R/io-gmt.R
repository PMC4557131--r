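#' @include AllClasses.R
NULL

#' Read a GMT gene-set collection
#'
#' Each line holds a set name, a description, and tab-separated member gene
#' symbols. Symbols are upper-cased for matching and deduplicated within a
#' set. The format is validated strictly: lines with fewer than three
#' fields, empty sets and duplicated set names are errors.
#'
#' @param path GMT file.
#' @param source free-text tag recording where the collection came from.
#' @return named list of character vectors of gene symbols, with attributes
#'   \code{source} and \code{description} (named character of per-set
#'   descriptions).
#' @export
readGMT <- function(path, source = basename(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("GMT file is empty: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop(sprintf("GMT line %d has %d fields; need name, description, ",
                     which(nf < 3L)[1L], nf[nf < 3L][1L]),
             "and at least one symbol")
    nm <- vapply(fields, `[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop("duplicate gene-set names: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    sets <- lapply(fields, function(f) {
        syms <- unique(toupper(trimws(f[-(1:2)])))
        syms[nzchar(syms)]
    })
    if (any(lengths(sets) == 0L))
        stop("empty gene set: ", nm[lengths(sets) == 0L][1L])
    names(sets) <- nm
    attr(sets, "source") <- source
    attr(sets, "description") <- stats::setNames(
        vapply(fields, `[`, character(1), 2L), nm)
    sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of symbol vectors.
#' @param path output file.
#' @param description per-set descriptions (recycled).
#' @return the path, invisibly.
#' @export
writeGMT <- function(sets, path, description = "") {
    description <- rep_len(description, length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description[i], sets[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}
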