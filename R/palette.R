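#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a state palette
#'
#' @param mnemonic character vector of unique state mnemonics, in index order.
#' @param name display names (defaults to the mnemonics).
#' @param color hex colours (defaults to a grey ramp).
#' @return a [StatePalette-class].
#' @examples
#' statePalette(c("Tx", "Quies"))
#' @export
statePalette <- function(mnemonic, name = mnemonic,
                         color = grDevices::grey.colors(length(mnemonic))) {
    new("StatePalette", states = data.frame(
        index = seq_along(mnemonic), mnemonic = as.character(mnemonic),
        name = as.character(name), color = toupper(as.character(color)),
        stringsAsFactors = FALSE))
}

#' The 15-state reference palette
#'
#' The widely used 15-state model trained on the five core histone marks
#' (H3K4me3, H3K4me1, H3K36me3, H3K9me3, H3K27me3), with its conventional
#' mnemonics, display names and colours.
#'
#' @return a [StatePalette-class] with 15 states.
#' @examples
#' roadmap15Palette()
#' @export
roadmap15Palette <- function() {
    new("StatePalette", states = data.frame(
        index = 1:15,
        mnemonic = c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG",
                     "Enh", "ZNF/Rpts", "Het", "TssBiv", "BivFlnk", "EnhBiv",
                     "ReprPC", "ReprPCWk", "Quies"),
        name = c("Active TSS", "Flanking Active TSS",
                 "Transcription at gene 5' and 3'", "Strong transcription",
                 "Weak transcription", "Genic enhancers", "Enhancers",
                 "ZNF genes & repeats", "Heterochromatin",
                 "Bivalent/Poised TSS", "Flanking Bivalent TSS/Enh",
                 "Bivalent Enhancer", "Repressed PolyComb",
                 "Weak Repressed PolyComb", "Quiescent/Low"),
        color = c("#FF0000", "#FF4500", "#32CD32", "#008000", "#006400",
                  "#C2E105", "#FFFF00", "#66CDAA", "#8A91D0", "#CD5C5C",
                  "#E9967A", "#BDB76B", "#808080", "#C0C0C0", "#FFFFFF"),
        stringsAsFactors = FALSE))
}

#' Number of states in a palette
#' @param x a StatePalette.
#' @return integer.
#' @export
nStates <- function(x) nrow(x@states)

#' Resolve state labels against a palette
#'
#' Accepts bare mnemonics ("Tx"), prefixed mnemonics ("4_Tx") or bare
#' numeric indices ("4"), the dialects found across segmentation releases.
#'
#' @param labels character vector of state labels.
#' @param palette a [StatePalette-class].
#' @return integer state indices; NA where a label is unknown.
#' @export
resolveStates <- function(labels, palette) {
    st <- palette@states
    labels <- as.character(labels)
    idx <- match(labels, st$mnemonic)
    miss <- is.na(idx)
    if (any(miss)) {
        # "4_Tx" dialect: numeric prefix + underscore + mnemonic
        m <- regmatches(labels[miss],
                        regexec("^([0-9]+)_(.+)$", labels[miss]))
        pref <- vapply(m, function(g) {
            if (length(g) == 3L) {
                i <- match(g[3L], st$mnemonic)
                if (!is.na(i) && i == as.integer(g[2L])) return(i)
                if (!is.na(i)) return(i)  # mnemonic wins over prefix
            }
            NA_integer_
        }, integer(1))
        idx[miss] <- pref
        miss <- is.na(idx)
    }
    if (any(miss)) {
        num <- suppressWarnings(as.integer(labels[miss]))
        num[!is.na(num) & (num < 1L | num > nrow(st))] <- NA_integer_
        idx[miss] <- num
    }
    idx
}

#' Read a palette from TSV
#'
#' Expects tab-separated columns index, mnemonic, name, color; comment lines
#' start with "#".
#' @param path file path.
#' @return a [StatePalette-class].
#' @export
readPalette <- function(path) {
    lines <- readLines(path, warn = FALSE)
    # only whole comment lines are dropped: colors are "#RRGGBB" values
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 4L))
        stop("palette lines need index, mnemonic, name, color: ", path)
    df <- data.frame(index = as.integer(vapply(parts, `[`, "", 1L)),
                     mnemonic = vapply(parts, `[`, "", 2L),
                     name = vapply(parts, `[`, "", 3L),
                     color = vapply(parts, `[`, "", 4L),
                     stringsAsFactors = FALSE)
    df <- df[order(df$index), , drop = FALSE]
    new("StatePalette", states = data.frame(
        index = as.integer(df$index), mnemonic = df$mnemonic,
        name = df$name, color = toupper(df$color),
        stringsAsFactors = FALSE))
}

#' Write a palette to TSV
#' @param palette a [StatePalette-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePalette <- function(palette, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#index\tmnemonic\tname\tcolor", con)
    st <- palette@states
    writeLines(sprintf("%d\t%s\t%s\t%s", st$index, st$mnemonic, st$name,
                       st$color), con)
    invisible(path)
}

setMethod("paletteOf", "StatePalette", function(x) x)
setMethod("paletteOf", "Segmentation", function(x) x@palette)
setMethod("paletteOf", "FeatureMatrix", function(x) x@palette)

setMethod("show", "StatePalette", function(object) {
    cat(sprintf("StatePalette with %d states: %s\n", nStates(object),
                paste(object@states$mnemonic, collapse = ", ")))
})
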