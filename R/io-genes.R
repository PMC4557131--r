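#' @include AllClasses.R palette.R
NULL

#' Read gene models from GTF or BED6
#'
#' Retains gene-level records of the requested biotype (GTF attribute
#' \code{gene_type} or \code{gene_biotype}), drops the listed chromosomes
#' (chrY by default, whose genes are excluded from the analysis), and
#' returns a GRanges with \code{gene_id}, \code{symbol} and \code{biotype}
#' metadata. Gene-body length is \code{width()} of the range; strand is
#' ignored throughout the package, as state coverage is strand-agnostic.
#'
#' @param path GTF (1-based inclusive, converted on read) or BED6 file
#'   (0-based half-open; the name field carries the gene id; no biotype
#'   information, so the biotype filter is not applied).
#' @param biotype biotype to retain from GTF input.
#' @param dropChroms chromosomes to exclude.
#' @param format "auto" (by extension), "gtf" or "bed".
#' @return GRanges of gene models.
#' @export
readGenes <- function(path, biotype = "protein_coding",
                      dropChroms = "chrY", format = c("auto", "gtf", "bed")) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.(gtf|gff2?)(\\.gz)?$", path,
                            ignore.case = TRUE)) "gtf" else "bed"
    }
    if (format == "gtf") {
        gr <- rtracklayer::import(path, format = "gtf")
        gr <- gr[!is.na(mcols(gr)$type) & mcols(gr)$type == "gene"]
        bt <- mcols(gr)$gene_type
        if (is.null(bt)) bt <- mcols(gr)$gene_biotype
        if (is.null(bt))
            stop("GTF lacks gene_type/gene_biotype attributes: ", path)
        gr <- gr[!is.na(bt) & bt == biotype]
        sym <- mcols(gr)$gene_name
        if (is.null(sym)) sym <- mcols(gr)$gene_id
        genes <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                         gene_id = mcols(gr)$gene_id, symbol = sym,
                         biotype = rep(biotype, length(gr)))
    } else {
        df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                                comment.char = "#",
                                stringsAsFactors = FALSE)
        if (ncol(df) < 4L) stop("BED gene file needs at least 4 columns")
        genes <- GRanges(df[[1L]],
                         IRanges(start = df[[2L]] + 1L, end = df[[3L]]),
                         gene_id = as.character(df[[4L]]),
                         symbol = as.character(df[[4L]]),
                         biotype = rep(NA_character_, nrow(df)))
    }
    genes <- genes[!(as.character(seqnames(genes)) %in% dropChroms)]
    if (length(genes) == 0L)
        stop("no genes survive the biotype/chromosome filters in ", path)
    dup <- unique(mcols(genes)$gene_id[duplicated(mcols(genes)$gene_id)])
    if (length(dup) > 0L)
        stop("duplicate gene ids: ", paste(utils::head(dup, 10L),
                                           collapse = ", "))
    genes[order(as.character(seqnames(genes)), start(genes))]
}

#' Write gene models to GTF
#'
#' Emits one gene-level record per gene with \code{gene_id},
#' \code{gene_name} and \code{gene_type} attributes, 1-based inclusive
#' coordinates.
#' @param genes GRanges from [readGenes()] or the cohort generator.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGenes <- function(genes, path) {
    attr <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                    mcols(genes)$gene_id, mcols(genes)$symbol,
                    ifelse(is.na(mcols(genes)$biotype), "protein_coding",
                           mcols(genes)$biotype))
    lines <- sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t+\t.\t%s",
                     as.character(seqnames(genes)), start(genes),
                     end(genes), attr)
    writeLines(lines, path)
    invisible(path)
}
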