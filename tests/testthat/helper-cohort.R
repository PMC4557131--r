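# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, builder(), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

# the standard toy cohort with the default planted effect
toyCohort <- function() cached("cohort", function()
    generateCohort(syntheticCohortSpec(seed = 101L)))

toyFeatureMatrix <- function() cached("fm", function()
    buildFeatureMatrix(toyCohort()$segmentations, toyCohort()$genes))

toyCorrected <- function() cached("cm", function()
    suppressWarnings(correctFeatures(toyFeatureMatrix(),
                                     toyCohort()$metadata, "group")))

toyGroupSpec <- function() cached("gs", function()
    groupSpec(toyCohort()$metadata, "group", "A", "B"))

toyResult <- function() cached("res", function()
    compareGroups(toyCorrected(), toyGroupSpec()))

# tiny hand-built metadata table
mkMetadata <- function(ids, ...) {
    md <- S4Vectors::DataFrame(row.names = ids)
    cols <- list(...)
    for (nm in names(cols))
        md[[nm]] <- IRanges::CharacterList(cols[[nm]])
    md
}

mkSegmentation <- function(epigenome, chrom, starts, ends, states,
                           palette = roadmap15Palette()) {
    Segmentation(epigenome,
                 GenomicRanges::GRanges(chrom,
                     IRanges::IRanges(starts, ends),
                     state = as.integer(states)),
                 palette)
}

mkGene <- function(chrom, start, end, id = "G1") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                           gene_id = id, symbol = id,
                           biotype = "protein_coding")
}

# a minimal ComparisonResult built directly from a feature table
mkResult <- function(tab, alpha = 0.05) {
    spec <- new("GroupSpec", property = "p", traitA = "A", traitB = "B",
                idsA = "E1", idsB = "E2")
    new("ComparisonResult", table = tab, alpha = alpha, test = "mww",
        correction = "bh", spec = spec)
}
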