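#' @include AllClasses.R AllGenerics.R palette.R
#' @importFrom rtracklayer import export
NULL

#' Construct a Segmentation from a GRanges
#'
#' @param epigenome epigenome id.
#' @param ranges GRanges with an integer \code{state} metadata column
#'   (1-based starts, as usual for GRanges).
#' @param palette a [StatePalette-class].
#' @param merge merge adjacent same-state intervals.
#' @return a [Segmentation-class].
#' @export
Segmentation <- function(epigenome, ranges, palette = roadmap15Palette(),
                         merge = FALSE) {
    ranges <- ranges[order(as.character(seqnames(ranges)), start(ranges))]
    if (merge && length(ranges) > 1L) {
        same <- as.character(seqnames(ranges))[-1] ==
                    as.character(seqnames(ranges))[-length(ranges)] &
                start(ranges)[-1] == end(ranges)[-length(ranges)] + 1L &
                mcols(ranges)$state[-1] ==
                    mcols(ranges)$state[-length(ranges)]
        grp <- cumsum(c(TRUE, !same))
        ranges <- GRanges(
            seqnames = tapply(as.character(seqnames(ranges)), grp,
                              `[`, 1L),
            IRanges(start = as.integer(tapply(start(ranges), grp, min)),
                    end = as.integer(tapply(end(ranges), grp, max))),
            state = as.integer(tapply(mcols(ranges)$state, grp, `[`, 1L)))
    }
    new("Segmentation", epigenome = epigenome, ranges = ranges,
        palette = palette)
}

#' Read a chromatin-state segmentation from BED
#'
#' Parses a BED4+ file (chrom, start, end, state label); labels may be bare
#' mnemonics, "index_mnemonic" strings, or bare indices. Coordinates are
#' interpreted as 0-based half-open per the BED convention.
#'
#' @param path BED file.
#' @param epigenome epigenome id; defaults to the file name without
#'   extension.
#' @param palette a [StatePalette-class].
#' @param merge merge adjacent same-state intervals after reading.
#' @return a [Segmentation-class]. An empty file yields a segmentation with
#'   zero intervals and a warning.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t200\t15_Quies", "chr1\t200\t600\t4_Tx"), bed)
#' seg <- readSegmentation(bed, epigenome = "E001")
#' @export
readSegmentation <- function(path, epigenome = NULL,
                             palette = roadmap15Palette(), merge = FALSE) {
    if (is.null(epigenome))
        epigenome <- sub("\\.[^.]*$", "", basename(path))
    nonblank <- tryCatch(
        any(nzchar(trimws(readLines(path, n = 50L, warn = FALSE)))),
        error = function(e) stop("cannot read ", path, ": ",
                                 conditionMessage(e)))
    if (!nonblank) {
        warning("empty segmentation file: ", path)
        return(Segmentation(epigenome,
                            GRanges(state = integer(0)), palette))
    }
    gr <- rtracklayer::import(path, format = "bed")
    if (any(width(gr) < 1L)) {
        bad <- which(width(gr) < 1L)[1L]
        stop(sprintf("record %d in %s: end <= start", bad, path))
    }
    labels <- mcols(gr)$name
    if (is.null(labels))
        stop("BED file lacks a 4th (state) column: ", path)
    state <- resolveStates(labels, palette)
    if (anyNA(state)) {
        bad <- which(is.na(state))[1L]
        stop(sprintf("record %d in %s: unknown state label '%s'",
                     bad, path, labels[bad]))
    }
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                   state = state)
    Segmentation(epigenome, out, palette, merge = merge)
}

#' Write a segmentation to BED4
#'
#' Emits 0-based half-open intervals with "index_mnemonic" state labels.
#' @param seg a [Segmentation-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSegmentation <- function(seg, path) {
    gr <- seg@ranges
    lab <- paste0(mcols(gr)$state,
                  "_", seg@palette@states$mnemonic[mcols(gr)$state])
    lines <- sprintf("%s\t%d\t%d\t%s", as.character(seqnames(gr)),
                     start(gr) - 1L, end(gr), lab)
    writeLines(lines, path)
    invisible(path)
}

#' GRanges of a segmentation
#' @param seg a [Segmentation-class].
#' @return GRanges with a \code{state} metadata column.
#' @export
segmentRanges <- function(seg) seg@ranges

setMethod("epigenomeIds", "Segmentation", function(x) x@epigenome)

setMethod("show", "Segmentation", function(object) {
    cat(sprintf("Segmentation '%s': %d intervals on %d chromosome(s)\n",
                object@epigenome, length(object@ranges),
                length(unique(as.character(seqnames(object@ranges))))))
})
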