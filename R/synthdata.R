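# Seeded generators for probe manifests, beta-value cohorts with planted
# hypermethylated runs, and expression cohorts with group-dependent block
# correlation. These emulate multi-cancer 450K-style study designs so the
# whole pipeline is testable without array downloads.

# Deterministic sub-seed: one master seed, one stream per (tag) so that
# regenerating a single cohort or matrix reproduces it independently of
# generation order. Kept below 2^31 - 1.
subSeed <- function(master, tag) {
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((as.double(master) * 48271 + h * 7919) %% 2147483647)
}

#' Generate a synthetic CpG probe manifest
#'
#' Probes are spread over the requested chromosomes (as evenly as possible)
#' with inter-probe gaps drawn as `1 + Poisson(meanSpacingBp - 1)`, a
#' positive integer distribution with mean `meanSpacingBp`.
#'
#' @param nProbes Number of probes (>= 1).
#' @param chroms Chromosome names.
#' @param meanSpacingBp Mean inter-probe gap in bp (>= 1).
#' @param seed Integer seed; the output is reproducible under a fixed seed.
#' @return A sorted, named `GRanges` manifest (one width-1 range per probe).
#' @examples
#' mf <- generateManifest(100, c("chr1", "chr2"), meanSpacingBp = 500, seed = 7)
#' @export
generateManifest <- function(nProbes, chroms = "chr1",
                             meanSpacingBp = 500L, seed = 1L) {
    if (nProbes < 1L) stop("nProbes must be >= 1")
    if (meanSpacingBp < 1L) stop("meanSpacingBp must be >= 1")
    if (length(chroms) < 1L) stop("at least one chromosome is required")
    set.seed(subSeed(seed, "manifest"))
    per <- diff(round(seq(0, nProbes, length.out = length(chroms) + 1L)))
    grl <- vector("list", length(chroms))
    offset <- 0L
    for (i in seq_along(chroms)) {
        n <- per[i]
        if (n == 0L) next
        gaps <- 1L + stats::rpois(n, lambda = meanSpacingBp - 1)
        pos <- 10000L + cumsum(gaps)
        grl[[i]] <- GRanges(chroms[i], IRanges(pos, width = 1L))
        offset <- offset + n
    }
    gr <- suppressWarnings(do.call(c, grl[per > 0L]))
    names(gr) <- sprintf("cg%08d", seq_along(gr))
    validManifest(gr)
}

#' Describe a planted differentially methylated run
#'
#' Ground-truth record for the beta generator: a contiguous set of manifest
#' probes whose tumor mean is shifted by `deltaBeta` (tumor minus normal) in
#' a fraction of the cancer-type cohorts. A positive `deltaBeta` models a
#' normally-unmethylated locus acquiring methylation in tumors.
#'
#' @param chrom Chromosome of the run.
#' @param start,end Positions of the first and last planted probe.
#' @param nProbes Number of probes in the run (>= 2).
#' @param deltaBeta Mean tumor-minus-normal beta shift, in (-1, 1).
#' @param affectedCohortFraction Fraction of cohorts carrying the shift,
#'   in (0, 1].
#' @return A one-row `data.frame`; `rbind()` rows to plant several runs.
#' @export
plantedDMR <- function(chrom, start, end, nProbes, deltaBeta,
                       affectedCohortFraction = 1) {
    if (end <= start) stop("end must exceed start")
    if (nProbes < 2L) stop("a planted run needs >= 2 probes")
    if (abs(deltaBeta) >= 1) stop("deltaBeta must lie in (-1, 1)")
    if (affectedCohortFraction <= 0 || affectedCohortFraction > 1)
        stop("affectedCohortFraction must lie in (0, 1]")
    data.frame(chrom = chrom, start = start, end = end,
               n_probes = as.integer(nProbes), delta_beta = deltaBeta,
               affected_cohort_fraction = affectedCohortFraction,
               stringsAsFactors = FALSE)
}

# Manifest probes covered by each planted run; errors if a run has no
# matching probes or fewer than n_probes of them.
.plantedProbes <- function(manifest, planted) {
    if (is.null(planted) || nrow(planted) == 0L) return(character())
    out <- character()
    for (k in seq_len(nrow(planted))) {
        hit <- as.character(seqnames(manifest)) == planted$chrom[k] &
            start(manifest) >= planted$start[k] &
            start(manifest) <= planted$end[k]
        ids <- names(manifest)[hit]
        if (length(ids) < planted$n_probes[k])
            stop(sprintf(
                "planted region %s:%d-%d expects %d probes but the manifest has %d there",
                planted$chrom[k], planted$start[k], planted$end[k],
                planted$n_probes[k], length(ids)))
        out <- c(out, ids)
    }
    unique(out)
}

#' Generate multi-cancer beta-value cohorts with planted DMRs
#'
#' Each probe draws one baseline methylation level from a Beta(`a`, `b`)
#' distribution (shared across cohorts, modeling tissue-of-origin
#' maintenance). Planted probes instead draw a low baseline leaving headroom
#' for the shift, so the planted tumor-minus-normal difference is the stated
#' `delta_beta`. Per-sample noise is applied on the logit scale and
#' back-transformed, keeping values inside (0, 1); a small per-cohort offset
#' (sd `cohortSd`) emulates batch/tissue heterogeneity. Tumor samples at
#' planted probes are shifted in the first
#' `ceiling(affected_cohort_fraction * nCohorts)` cohorts.
#'
#' @param manifest Probe manifest from [generateManifest()] or
#'   [readManifest()].
#' @param nCohorts Number of cancer-type cohorts.
#' @param nNormal,nTumor Samples per group per cohort (>= 1).
#' @param planted `data.frame` of planted runs from [plantedDMR()], or
#'   `NULL` for a null cohort set.
#' @param baselineShape Length-2 shape pair `(a, b)` for probe baselines;
#'   the default (0.85, 0.85) gives the bimodal beta landscape typical of
#'   450K arrays.
#' @param noiseSd Per-sample logit-scale noise sd.
#' @param cohortSd Sd of the per-cohort baseline offset (beta scale).
#' @param seed Master seed; cohort/group sub-seeds derive from it.
#' @return A [BetaCohortSet-class]; planted truth is kept in
#'   `metadata(x)$planted`.
#' @examples
#' mf <- generateManifest(200, meanSpacingBp = 100, seed = 1)
#' bcs <- generateBetaCohorts(mf, nCohorts = 2, nNormal = 10, nTumor = 10,
#'                            seed = 1)
#' @export
generateBetaCohorts <- function(manifest, nCohorts = 3L, nNormal = 40L,
                                nTumor = 40L, planted = NULL,
                                baselineShape = c(0.85, 0.85),
                                noiseSd = 0.5, cohortSd = 0.02, seed = 1L) {
    manifest <- validManifest(manifest)
    if (nNormal < 1L || nTumor < 1L) stop("need >= 1 sample per group")
    if (nCohorts < 1L) stop("need >= 1 cohort")
    nP <- length(manifest)
    plantedIds <- .plantedProbes(manifest, planted)
    isPlanted <- names(manifest) %in% plantedIds

    set.seed(subSeed(seed, "baselines"))
    mu <- stats::rbeta(nP, baselineShape[1], baselineShape[2])
    mu <- pmin(pmax(mu, 0.02), 0.98)
    # planted probes model a CpG-island-like locus: unmethylated in normal
    # tissue when the planted shift is positive (hypermethylation), and the
    # mirror image for negative shifts, so baseline + shift stays well
    # inside (0, 1) and the stated delta is fully expressed
    if (any(isPlanted)) {
        delta <- numeric(nP)
        for (k in seq_len(nrow(planted))) {
            hit <- as.character(seqnames(manifest)) == planted$chrom[k] &
                start(manifest) >= planted$start[k] &
                start(manifest) <= planted$end[k]
            delta[hit] <- planted$delta_beta[k]
        }
        dP <- delta[isPlanted]
        lo <- ifelse(dP >= 0, 0.10, pmax(0.60, 0.02 - dP))
        hi <- ifelse(dP >= 0, pmin(0.40, 0.98 - dP), 0.90)
        mu[isPlanted] <- lo + (hi - lo) * stats::rbeta(sum(isPlanted), 2, 2)
    } else {
        delta <- numeric(nP)
    }

    nAffected <- if (is.null(planted) || nrow(planted) == 0L) 0L else
        as.integer(ceiling(max(planted$affected_cohort_fraction) * nCohorts))
    cohorts <- sprintf("cohort%02d", seq_len(nCohorts))

    drawGroup <- function(m, n, tag) {
        set.seed(subSeed(seed, tag))
        eps <- matrix(stats::rnorm(nP * n, sd = noiseSd), nrow = nP)
        v <- stats::plogis(stats::qlogis(m) + eps)
        pmin(pmax(v, 1e-6), 1 - 1e-6)
    }

    mats <- vector("list", 2L * nCohorts)
    sheets <- vector("list", 2L * nCohorts)
    for (i in seq_len(nCohorts)) {
        set.seed(subSeed(seed, paste0("offset-", cohorts[i])))
        off <- stats::rnorm(1L, sd = cohortSd)
        mN <- pmin(pmax(mu + off, 1e-6), 1 - 1e-6)
        shift <- if (i <= nAffected) delta else numeric(nP)
        mT <- pmin(pmax(mu + off + shift, 1e-6), 1 - 1e-6)
        bN <- drawGroup(mN, nNormal, paste0(cohorts[i], "-normal"))
        bT <- drawGroup(mT, nTumor, paste0(cohorts[i], "-tumor"))
        idN <- sprintf("%s_N%03d", cohorts[i], seq_len(nNormal))
        idT <- sprintf("%s_T%03d", cohorts[i], seq_len(nTumor))
        colnames(bN) <- idN; colnames(bT) <- idT
        mats[[2L * i - 1L]] <- bN
        mats[[2L * i]] <- bT
        sheets[[2L * i - 1L]] <- data.frame(sample_id = idN,
            cohort = cohorts[i], group = "normal", stringsAsFactors = FALSE)
        sheets[[2L * i]] <- data.frame(sample_id = idT,
            cohort = cohorts[i], group = "tumor", stringsAsFactors = FALSE)
    }
    beta <- do.call(cbind, mats)
    rownames(beta) <- names(manifest)
    sheet <- do.call(rbind, sheets)
    bcs <- BetaCohortSet(manifest, beta, sheet)
    metadata(bcs)$planted <- planted
    metadata(bcs)$planted_probes <- plantedIds
    metadata(bcs)$affected_cohorts <- cohorts[seq_len(nAffected)]
    bcs
}

# Target correlation matrix for one group of an expression cohort.
.targetCorr <- function(genes, blocks, rWithin, rBetween,
                        distalGene = NULL, distalR = 0) {
    all <- c(genes, distalGene)
    p <- length(all)
    C <- matrix(rBetween, p, p, dimnames = list(all, all))
    for (b in unique(blocks)) {
        idx <- which(all %in% names(blocks)[blocks == b])
        C[idx, idx] <- rWithin
    }
    if (!is.null(distalGene)) {
        C[distalGene, genes] <- distalR
        C[genes, distalGene] <- distalR
    }
    diag(C) <- 1
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
        stop(sprintf(paste0(
            "target correlation matrix is not positive semi-definite ",
            "(min eigenvalue %.4g) for rWithin=%.2f, rBetween=%.2f, ",
            "distalR=%.2f"), min(ev), rWithin, rBetween, distalR))
    C
}

#' Generate expression cohorts with group-dependent block correlation
#'
#' Models an ordered gene cluster (default: the HOXA locus genes plus the
#' distal gene TAX1BP1) whose co-expression is modular in normal tissue
#' (within-block correlation `rWithinNormal`, between-block `rBetween`) and
#' attenuated in tumors (`rWithinTumor`); the distal gene is uncorrelated
#' with the cluster in normal samples and correlated at `distalGeneRTumor`
#' with every cluster gene in tumors. Samples are drawn from a multivariate
#' normal with the validated target correlation via its Cholesky factor, on
#' a log-expression scale (mean 5, unit variance).
#'
#' @param genes Ordered gene names of the cluster.
#' @param blockAssignment Named character vector gene -> block label,
#'   partitioning `genes`. Default: HOXA1-HOXA6 vs HOXA7-HOXA13.
#' @param nCohorts,nNormal,nTumor Cohorts and samples per group per cohort.
#' @param rWithinNormal,rWithinTumor,rBetween Target Pearson correlations,
#'   each in (-1, 1).
#' @param distalGene Name of the distal gene, or `NULL` to omit it.
#' @param distalGeneRTumor Tumor-only correlation of the distal gene with
#'   all cluster genes.
#' @param seed Master seed.
#' @return An [ExpressionCohortSet-class].
#' @export
generateExpressionCohorts <- function(
        genes = paste0("HOXA", c(1:7, 9:11, 13)),
        blockAssignment = NULL,
        nCohorts = 3L, nNormal = 40L, nTumor = 40L,
        rWithinNormal = 0.8, rWithinTumor = 0.2, rBetween = 0.1,
        distalGene = "TAX1BP1", distalGeneRTumor = 0.35, seed = 1L) {
    if (is.null(blockAssignment)) {
        rank <- as.integer(sub("^HOXA", "", genes))
        blockAssignment <- stats::setNames(
            ifelse(rank <= 6L, "block1", "block2"), genes)
    }
    if (!setequal(names(blockAssignment), genes))
        stop("blockAssignment must partition the gene list")
    for (r in c(rWithinNormal, rWithinTumor, rBetween, distalGeneRTumor))
        if (abs(r) >= 1) stop("target correlations must lie in (-1, 1)")
    Cn <- .targetCorr(genes, blockAssignment, rWithinNormal, rBetween,
                      distalGene, distalR = 0)
    Ct <- .targetCorr(genes, blockAssignment, rWithinTumor, rBetween,
                      distalGene, distalR = distalGeneRTumor)
    allGenes <- c(genes, distalGene)
    p <- length(allGenes)
    draw <- function(C, n, tag) {
        set.seed(subSeed(seed, tag))
        # small PSD jitter only if a zero eigenvalue blocks the Cholesky
        L <- tryCatch(chol(C), error = function(e)
            chol(C + diag(1e-8, p)))
        X <- matrix(stats::rnorm(n * p), nrow = n) %*% L
        t(X) + 5
    }
    cohorts <- sprintf("cohort%02d", seq_len(nCohorts))
    mats <- list(); sheets <- list()
    for (i in seq_len(nCohorts)) {
        eN <- draw(Cn, nNormal, paste0("expr-", cohorts[i], "-normal"))
        eT <- draw(Ct, nTumor, paste0("expr-", cohorts[i], "-tumor"))
        rownames(eN) <- rownames(eT) <- allGenes
        idN <- sprintf("%s_N%03d", cohorts[i], seq_len(nNormal))
        idT <- sprintf("%s_T%03d", cohorts[i], seq_len(nTumor))
        colnames(eN) <- idN; colnames(eT) <- idT
        mats <- c(mats, list(eN, eT))
        sheets <- c(sheets, list(
            data.frame(sample_id = idN, cohort = cohorts[i],
                       group = "normal", stringsAsFactors = FALSE),
            data.frame(sample_id = idT, cohort = cohorts[i],
                       group = "tumor", stringsAsFactors = FALSE)))
    }
    ExpressionCohortSet(do.call(cbind, mats), do.call(rbind, sheets),
                        blockAssignment)
}
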