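test_that("runs below the site-count or density gate are rejected", {
    # 9 contiguous DMSs: below the >= 10 site floor
    rows9 <- data.frame(chrom = "chr1", n_dms = 9L,
                        start = 1000L, end = 1800L)
    mf <- runManifest(rows9)
    expect_length(callDmrs(names(mf), mf), 0L)
    # 10 DMSs over 5000 bp: density 2/kb < 3/kb
    sparse <- data.frame(chrom = "chr1", n_dms = 10L,
                         start = 1000L, end = 6000L)
    mf2 <- runManifest(sparse)
    expect_length(callDmrs(names(mf2), mf2), 0L)
    # same 10 DMSs over 1000 bp pass both gates
    dense <- data.frame(chrom = "chr1", n_dms = 10L,
                        start = 1000L, end = 2000L)
    mf3 <- runManifest(dense)
    got <- callDmrs(names(mf3), mf3)
    expect_length(got, 1L)
    expect_identical(mcols(got)$n_dms, 10L)
    expect_identical(mcols(got)$dmr_length, 1000L)
})

test_that("an intervening non-DMS probe breaks a run", {
    rows <- data.frame(chrom = "chr1", n_dms = 21L,
                       start = 1000L, end = 2000L)
    mf <- runManifest(rows)
    ids <- names(mf)
    # drop the middle probe from the DMS set: two runs of 10, each 450 bp
    got <- callDmrs(ids[-11], mf)
    expect_length(got, 2L)
    expect_identical(mcols(got)$n_dms, c(10L, 10L))
})

test_that("call output is invariant to DMS input order and validated", {
    rows <- data.frame(chrom = c("chr1", "chr2"), n_dms = c(12L, 15L),
                       start = c(1000L, 5000L), end = c(2000L, 6000L))
    mf <- runManifest(rows)
    ids <- runProbeIds(mf, rows)
    a <- callDmrs(ids, mf)
    b <- callDmrs(rev(ids), mf)
    expect_identical(dmrTable(a), dmrTable(b))
    expect_length(a, 2L)
    # density * length = n_dms exactly, pre-rounding
    expect_identical(mcols(a)$density * mcols(a)$dmr_length,
                     as.numeric(mcols(a)$n_dms))
    expect_error(callDmrs(c(ids, "cgNOPE"), mf), "absent from manifest")
})

test_that("merging respects the gap rule, chromosome barrier, idempotence", {
    rows <- data.frame(chrom = c("chr1", "chr1"), n_dms = c(10L, 12L),
                       start = c(1000L, 2100L), end = c(2000L, 3100L))
    mf <- runManifest(rows)
    dmrs <- callDmrs(runProbeIds(mf, rows), mf)
    expect_length(dmrs, 2L)
    gap <- 2100L - 2000L  # 100 bp
    # gap == maxGapBp merges (inclusive rule)
    m1 <- mergeDmrs(dmrs, maxGapBp = gap)
    expect_length(m1, 1L)
    expect_identical(mcols(m1)$n_dms, 22L)
    expect_identical(start(m1), 1000L)
    expect_identical(end(m1), 3100L)
    expect_identical(mcols(m1)$dmr_length, 2100L)
    # gap - 1 does not
    expect_length(mergeDmrs(dmrs, maxGapBp = gap - 1L), 2L)
    # idempotence
    expect_identical(dmrTable(mergeDmrs(m1, maxGapBp = gap)), dmrTable(m1))
    # different chromosomes never merge regardless of coordinates
    rows2 <- data.frame(chrom = c("chr1", "chr2"), n_dms = c(10L, 10L),
                        start = c(1000L, 2100L), end = c(2000L, 3100L))
    mf2 <- runManifest(rows2)
    dmrs2 <- callDmrs(runProbeIds(mf2, rows2), mf2)
    expect_length(mergeDmrs(dmrs2, maxGapBp = 1e6), 2L)
})

test_that("tabulation rounds half-even and is exact at high precision", {
    rows <- data.frame(chrom = "chr2", n_dms = 13L,
                       start = 53940358L, end = 53943729L)
    mf <- runManifest(rows)
    dmr <- callDmrs(names(mf), mf)
    tab <- dmrTable(dmr)
    expect_identical(tab$density, 0.00386)
    expect_identical(tab$length, 3371L)
    expect_identical(tab$coordinate, "chr2:53940358-53943729")
    tab12 <- dmrTable(dmr, densityDecimals = 12L)
    expect_lt(abs(tab12$density - 13 / 3371), 1e-12)
    expect_identical(nrow(dmrTable(dmr[0])), 0L)
})

test_that("collection intersection uses half-open overlap", {
    mk <- function(chrom, s, e) {
        g <- GRanges(chrom, IRanges(s, e))
        mcols(g)$n_dms <- 10L
        mcols(g)$dmr_length <- e - s
        mcols(g)$density <- 10 / (e - s)
        mcols(g)$member_probes <- IRanges::CharacterList(list(character()))
        g
    }
    a <- mk("chr1", 100L, 200L)
    expect_identical(dmrTable(intersectCollections(a, a)), dmrTable(a))
    expect_length(intersectCollections(a, mk("chr2", 100L, 200L)), 0L)
    # [100,200) vs [199,300): 1 bp of half-open overlap -> retained
    expect_length(intersectCollections(a, mk("chr1", 199L, 300L)), 1L)
    # [100,200) vs [200,300): endpoints touch, no half-open overlap
    expect_length(intersectCollections(a, mk("chr1", 200L, 300L)), 0L)
    expect_length(intersectCollections(a, mk("chr1", 150L, 300L),
                                       minOverlapBp = 50L), 1L)
    expect_length(intersectCollections(a, mk("chr1", 151L, 300L),
                                       minOverlapBp = 50L), 0L)
})

test_that("BED export converts to 0-based half-open coordinates", {
    rows <- data.frame(chrom = "chr7", n_dms = 10L,
                       start = 27150584L, end = 27150796L)
    mf <- runManifest(rows)
    dmr <- callDmrs(names(mf), mf)
    path <- withr::local_tempfile(fileext = ".bed")
    writeDmrBed(dmr, path)
    bed <- read.delim(path, header = FALSE)
    expect_identical(bed$V2, 27150583L)
    expect_identical(bed$V3, 27150796L)
    expect_identical(bed$V5, 10L)
})
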