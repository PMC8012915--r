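# DMR calling from pan-cancer DMS sets: contiguity runs on the manifest,
# site-count and density gates, merging of coordinately close regions,
# tabular export and collection intersection.

# Assemble DMR records in one construction so all records share seqlevels.
.dmrRecords <- function(chrom, startPos, endPos, memberList) {
    n <- lengths(memberList)
    len <- endPos - startPos
    gr <- GRanges(chrom, IRanges(startPos, endPos))
    S4Vectors::mcols(gr)$n_dms <- as.integer(n)
    S4Vectors::mcols(gr)$dmr_length <- as.integer(len)
    S4Vectors::mcols(gr)$density <- n / len
    S4Vectors::mcols(gr)$member_probes <- IRanges::CharacterList(memberList)
    GenomicRanges::sort(gr)
}

#' Call differentially methylated regions from a DMS set
#'
#' A candidate run is a maximal set of consecutive manifest probes (in
#' manifest order within a chromosome) that are all flagged as DMSs; any
#' intervening non-DMS probe breaks the run. A run becomes a DMR iff it has
#' at least `minSites` member sites and a CpG density of at least
#' `minDensityPerKb` sites per kilobase. Region length is `end - start`
#' (positions of the first and last member probe) and the stored density is
#' the per-bp value `n_dms / length`.
#'
#' @param dms Probe ids (character), or a `GRanges` DMS set as returned by
#'   [panCancerDms()] (its names are used).
#' @param manifest The probe manifest; every DMS must be present in it.
#' @param minSites Minimum member sites per region (inclusive), default 10.
#' @param minDensityPerKb Minimum density in DMS per kb (inclusive),
#'   default 3 (i.e. 0.003 per bp).
#' @return A `GRanges` sorted by (chrom, start), pairwise disjoint, with
#'   metadata columns `n_dms`, `dmr_length`, `density` (per bp) and
#'   `member_probes`.
#' @examples
#' mf <- generateManifest(50, meanSpacingBp = 50, seed = 3)
#' callDmrs(names(mf)[5:20], mf)
#' @export
callDmrs <- function(dms, manifest, minSites = 10L, minDensityPerKb = 3.0) {
    manifest <- validManifest(manifest)
    ids <- if (is(dms, "GRanges")) names(dms) else as.character(dms)
    absent <- setdiff(ids, names(manifest))
    if (length(absent))
        stop("DMS probe(s) absent from manifest: ",
             paste(utils::head(absent, 5L), collapse = ", "))
    flag <- names(manifest) %in% ids
    chrom <- as.character(seqnames(manifest))
    # run boundaries: flag switches or chromosome changes
    newRun <- flag & (!c(FALSE, flag[-length(flag)]) |
                      c(TRUE, chrom[-1L] != chrom[-length(chrom)]))
    runId <- cumsum(newRun)
    runId[!flag] <- NA_integer_
    keepC <- character(); keepS <- integer(); keepE <- integer()
    keepM <- list()
    for (r in unique(runId[!is.na(runId)])) {
        idx <- which(!is.na(runId) & runId == r)
        n <- length(idx)
        if (n < minSites) next
        s <- start(manifest)[idx[1L]]
        e <- start(manifest)[idx[n]]
        if (e <= s) next
        if (n / (e - s) < minDensityPerKb / 1000) next
        keepC <- c(keepC, chrom[idx[1L]])
        keepS <- c(keepS, s); keepE <- c(keepE, e)
        keepM <- c(keepM, list(names(manifest)[idx]))
    }
    .dmrRecords(keepC, keepS, keepE, keepM)
}

#' Merge coordinately close DMRs
#'
#' Same-chromosome regions whose gap (`next start - previous end`) is at
#' most `maxGapBp` are combined: member counts are summed, the span runs
#' from the earliest start to the latest end, and length and density are
#' recomputed. Idempotent.
#'
#' @param dmrs Sorted, disjoint `GRanges` from [callDmrs()].
#' @param maxGapBp Maximum gap in bp for merging (inclusive), default 1000.
#' @return A `GRanges` of the same shape.
#' @export
mergeDmrs <- function(dmrs, maxGapBp = 1000L) {
    if (length(dmrs) < 2L) return(dmrs)
    dmrs <- GenomicRanges::sort(dmrs)
    # reduce() merges when the inter-range gap width (next.start - prev.end
    # - 1) is below min.gapwidth, i.e. next.start - prev.end <= maxGapBp
    red <- GenomicRanges::reduce(granges(dmrs), min.gapwidth = maxGapBp,
                                 with.revmap = TRUE)
    members <- lapply(seq_along(red), function(i)
        unlist(S4Vectors::mcols(dmrs)$member_probes[
            S4Vectors::mcols(red)$revmap[[i]]], use.names = FALSE))
    .dmrRecords(as.character(seqnames(red)), start(red), end(red), members)
}

#' Tabulate DMRs in publication style
#'
#' One row per region: chromosome, member DMS count, density rounded
#' half-even to `densityDecimals` (the per-bp value), a
#' `chrom:start-end` coordinate string, and the length `end - start`.
#'
#' @param dmrs `GRanges` from [callDmrs()] or [mergeDmrs()].
#' @param densityDecimals Decimals for the printed density, default 5.
#' @return A `data.frame` with columns `chrom`, `n_dms`, `density`,
#'   `coordinate`, `length`.
#' @export
dmrTable <- function(dmrs, densityDecimals = 5L) {
    if (length(dmrs) == 0L)
        return(data.frame(chrom = character(), n_dms = integer(),
                          density = numeric(), coordinate = character(),
                          length = integer()))
    data.frame(
        chrom = as.character(seqnames(dmrs)),
        n_dms = S4Vectors::mcols(dmrs)$n_dms,
        density = round(S4Vectors::mcols(dmrs)$density, densityDecimals),
        coordinate = sprintf("%s:%d-%d", as.character(seqnames(dmrs)),
                             start(dmrs), end(dmrs)),
        length = S4Vectors::mcols(dmrs)$dmr_length,
        stringsAsFactors = FALSE)
}

#' Intersect two DMR collections
#'
#' Returns the regions of `a` that overlap at least `minOverlapBp` with some
#' region of `b`, with overlap measured on the half-open reading `[start,
#' end)` of the stored 1-based inclusive coordinates (so two regions merely
#' sharing an endpoint overlap by 1 bp).
#'
#' @param a,b Sorted `GRanges` DMR collections.
#' @param minOverlapBp Minimum half-open overlap in bp, default 1.
#' @return The qualifying subset of `a`.
#' @export
intersectCollections <- function(a, b, minOverlapBp = 1L) {
    if (length(a) == 0L || length(b) == 0L) return(a[0])
    lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
    GenomeInfoDb::seqlevels(a) <- lv
    GenomeInfoDb::seqlevels(b) <- lv
    # closed-interval overlap is half-open overlap + 1
    hits <- GenomicRanges::findOverlaps(a, b,
        minoverlap = minOverlapBp + 1L)
    a[sort(unique(S4Vectors::queryHits(hits)))]
}

#' Write DMRs as a BED file
#'
#' Converts the 1-based inclusive spans to BED's 0-based half-open
#' convention (`bed_start = start - 1`, `bed_end = end`); the score column
#' carries the member DMS count.
#'
#' @param dmrs `GRanges` of DMRs.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeDmrBed <- function(dmrs, path) {
    if (length(dmrs) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    df <- data.frame(chrom = as.character(seqnames(dmrs)),
                     start = start(dmrs) - 1L,
                     end = end(dmrs),
                     name = sprintf("DMR_%03d", seq_along(dmrs)),
                     score = S4Vectors::mcols(dmrs)$n_dms)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
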