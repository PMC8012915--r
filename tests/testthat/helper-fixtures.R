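# Shared fixtures, built in code at test time.

# The nine published common-DMR rows used as golden values: member DMS
# count, first/last probe coordinate, printed per-bp density and length.
goldenDmrRows <- function() {
    data.frame(
        chrom = c("chr1", "chr2", "chr5", "chr5", "chr6", "chr6", "chr6",
                  "chr7", "chr7"),
        n_dms = c(12L, 13L, 10L, 10L, 15L, 19L, 21L, 13L, 10L),
        start = c(25130211L, 53940358L, 140777418L, 140733599L, 31804202L,
                  29629141L, 30202939L, 27150841L, 27150584L),
        end = c(25130851L, 53943729L, 140779995L, 140734635L, 31804754L,
                29629693L, 30203549L, 27151918L, 27150796L),
        density = c(0.01875, 0.00386, 0.00388, 0.00965, 0.02717, 0.03442,
                    0.03443, 0.01207, 0.04717),
        length = c(640L, 3371L, 2577L, 1036L, 552L, 552L, 610L, 1077L,
                   212L),
        stringsAsFactors = FALSE)
}

# A manifest embedding the given runs: each run contributes n_dms probes
# with the exact first/last coordinates and evenly spaced interior probes.
# A separator probe is placed midway between consecutive runs on the same
# chromosome (as on a real array, where non-DMS probes break contiguity).
# Optionally adds `backgroundPerChrom` probes per chromosome, placed far
# (>= 10 kb) below the runs so every run stays a maximal contiguous window.
runManifest <- function(rows, backgroundPerChrom = 0L, spacingBp = 500L) {
    pos <- list(); chrom <- list()
    for (k in seq_len(nrow(rows))) {
        p <- unique(round(seq(rows$start[k], rows$end[k],
                              length.out = rows$n_dms[k])))
        stopifnot(length(p) == rows$n_dms[k])
        pos[[k]] <- p
        chrom[[k]] <- rep(rows$chrom[k], length(p))
    }
    for (ch in unique(rows$chrom)) {
        r <- rows[rows$chrom == ch, ]
        if (nrow(r) < 2L) next
        r <- r[order(r$start), ]
        sep <- (r$end[-nrow(r)] + r$start[-1L]) %/% 2L
        pos <- c(pos, list(sep))
        chrom <- c(chrom, list(rep(ch, length(sep))))
    }
    if (backgroundPerChrom > 0L) {
        for (ch in unique(rows$chrom)) {
            base <- min(rows$start[rows$chrom == ch]) - 100000L
            p <- base - spacingBp * seq_len(backgroundPerChrom)
            pos <- c(pos, list(sort(p)))
            chrom <- c(chrom, list(rep(ch, backgroundPerChrom)))
        }
    }
    gr <- GRanges(unlist(chrom), IRanges(unlist(pos), width = 1L))
    names(gr) <- sprintf("cg%08d", seq_along(gr))
    validManifest(gr)
}

# Probe ids of a manifest falling inside the given runs.
runProbeIds <- function(manifest, rows) {
    ids <- character()
    for (k in seq_len(nrow(rows))) {
        hit <- as.character(seqnames(manifest)) == rows$chrom[k] &
            start(manifest) >= rows$start[k] &
            start(manifest) <= rows$end[k]
        ids <- c(ids, names(manifest)[hit])
    }
    unique(ids)
}
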