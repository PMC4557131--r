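#' @include AllClasses.R
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges CharacterList
NULL

#' Read an epigenome metadata table
#'
#' TSV with a header line (optionally "#"-prefixed); the first column holds
#' epigenome ids, the remaining columns property values (donor sex,
#' processing lab, sample type, solid/liquid state, ...). Cells listing
#' several values (e.g. an epigenome processed by two labs) are split on
#' \code{delim}; empty cells become missing (zero values).
#'
#' @param path TSV file.
#' @param delim separator inside multi-valued cells (default ";").
#' @return a \code{S4Vectors::DataFrame} whose rownames are epigenome ids
#'   and whose columns are \code{CharacterList}s of per-sample values.
#' @export
readMetadata <- function(path, delim = ";") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 1L) stop("metadata file is empty: ", path)
    header <- sub("^#", "", lines[1L])
    cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
    if (length(cols) < 2L || any(!nzchar(cols)))
        stop("metadata header must name an id column and >=1 property")
    body <- lines[-1L]
    if (length(body) == 0L) stop("metadata has no data rows: ", path)
    cells <- strsplit(body, "\t", fixed = TRUE)
    cells <- lapply(cells, function(x) c(x, rep("", length(cols) -
                                                    length(x))))
    ids <- vapply(cells, `[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicate epigenome ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    out <- DataFrame(row.names = ids)
    for (j in seq_along(cols)[-1L]) {
        vals <- vapply(cells, `[`, character(1), j)
        split_vals <- strsplit(vals, delim, fixed = TRUE)
        split_vals <- lapply(split_vals,
                             function(v) trimws(v[nzchar(trimws(v))]))
        out[[cols[j]]] <- CharacterList(split_vals)
    }
    out
}

#' Write an epigenome metadata table
#'
#' Tab-separated with a "#"-prefixed header; multi-valued cells joined with
#' \code{delim}.
#' @param metadata DataFrame from [readMetadata()].
#' @param path output file.
#' @param delim multi-value separator.
#' @return the path, invisibly.
#' @export
writeMetadata <- function(metadata, path, delim = ";") {
    props <- names(metadata)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#id\t", paste(props, collapse = "\t")), con)
    for (i in seq_len(nrow(metadata))) {
        row <- vapply(props, function(p)
            paste(metadata[[p]][[i]], collapse = delim), character(1))
        writeLines(paste(c(rownames(metadata)[i], row), collapse = "\t"),
                   con)
    }
    invisible(path)
}

#' Values of one property for one epigenome
#' @param metadata DataFrame from [readMetadata()].
#' @param id epigenome id.
#' @param property property column name.
#' @return character vector (possibly empty when the value is missing).
#' @export
propertyValues <- function(metadata, id, property) {
    if (!property %in% names(metadata))
        stop("unknown metadata property: ", property)
    as.character(metadata[[property]][[match(id, rownames(metadata))]])
}

#' Observed levels of a metadata property
#' @inheritParams propertyValues
#' @return sorted character vector of distinct values.
#' @export
propertyLevels <- function(metadata, property) {
    if (!property %in% names(metadata))
        stop("unknown metadata property: ", property)
    sort(unique(unlist(metadata[[property]])))
}

#' Resolve a two-group comparison from metadata
#'
#' An epigenome joins group A when its property values include
#' \code{traitA} and not \code{traitB} (and vice versa); epigenomes
#' annotated with both traits are ambiguous and excluded with a warning,
#' as are epigenomes with neither.
#'
#' @param metadata DataFrame from [readMetadata()].
#' @param property property column to compare on.
#' @param traitA,traitB the two trait labels.
#' @return a [GroupSpec-class].
#' @export
groupSpec <- function(metadata, property, traitA, traitB) {
    if (!property %in% names(metadata))
        stop("unknown metadata property: ", property)
    vals <- metadata[[property]]
    hasA <- vapply(vals, function(v) traitA %in% v, logical(1))
    hasB <- vapply(vals, function(v) traitB %in% v, logical(1))
    both <- hasA & hasB
    if (any(both))
        warning(sum(both), " epigenome(s) annotated with both traits, ",
                "excluded from the comparison")
    ids <- rownames(metadata)
    new("GroupSpec", property = property, traitA = traitA, traitB = traitB,
        idsA = ids[hasA & !both], idsB = ids[hasB & !both])
}

setMethod("epigenomeIds", "GroupSpec", function(x) c(x@idsA, x@idsB))

setMethod("show", "GroupSpec", function(object) {
    cat(sprintf("GroupSpec %s: %s (n=%d) vs %s (n=%d)\n", object@property,
                object@traitA, length(object@idsA), object@traitB,
                length(object@idsB)))
})
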