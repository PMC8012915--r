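# Per-probe differential methylation statistics: Welch test, BH FDR, AUROC,
# and cross-cancer aggregation into a pan-cancer DMS set.

# Vectorised Welch t-test over matrix rows; returns two-sided p-values.
# Zero variance in both groups: p = 1 when the means agree (no evidence by
# convention), p = 0 when they differ (infinite separation).
.rowWelchP <- function(x, y) {
    n1 <- ncol(x); n2 <- ncol(y)
    m1 <- rowMeans(x); m2 <- rowMeans(y)
    v1 <- rowSums((x - m1)^2) / (n1 - 1L)
    v2 <- rowSums((y - m2)^2) / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    p <- 2 * stats::pt(-abs(tt), df)
    degenerate <- se2 == 0
    if (any(degenerate)) {
        p[degenerate & m1 == m2] <- 1
        p[degenerate & m1 != m2] <- 0
    }
    p
}

#' Two-sided Welch t-test for one CpG site
#'
#' Compares tumor against normal beta values with unequal-variance
#' (Welch-Satterthwaite) degrees of freedom. When both groups have zero
#' variance and equal means the test is degenerate and p = 1 is returned by
#' convention (with a message).
#'
#' @param normal,tumor Numeric vectors of beta values, >= 2 each.
#' @return Two-sided p-value in `[0, 1]`.
#' @examples
#' siteTest(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))
#' @export
siteTest <- function(normal, tumor) {
    if (length(normal) < 2L || length(tumor) < 2L)
        stop("need at least 2 values per group")
    if (stats::var(normal) == 0 && stats::var(tumor) == 0 &&
        mean(normal) == mean(tumor)) {
        message("degenerate site (zero variance, equal means): p = 1")
        return(1)
    }
    .rowWelchP(matrix(normal, nrow = 1L), matrix(tumor, nrow = 1L))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input order is preserved and values are capped
#' at 1, so `q >= p` always holds.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @examples
#' adjustFdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
adjustFdr <- function(p) {
    if (any(!is.finite(p) | p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Area under the ROC curve for tumor/normal discrimination at one site
#'
#' Tumor is the positive class and the beta value the score:
#' AUC = P(tumor > normal) + 0.5 P(tie), computed exactly from midranks
#' (the Mann-Whitney U statistic divided by the number of pairs).
#'
#' @param normal,tumor Numeric score vectors, >= 1 each.
#' @return AUC in `[0, 1]`.
#' @examples
#' auroc(c(0.1, 0.2, 0.3), c(0.25, 0.35))  # 5/6
#' @export
auroc <- function(normal, tumor) {
    nN <- length(normal); nT <- length(tumor)
    if (nN < 1L || nT < 1L) stop("need at least one value per group")
    r <- rank(c(tumor, normal), ties.method = "average")
    u <- sum(r[seq_len(nT)]) - nT * (nT + 1) / 2
    u / (nN * nT)
}

# Row-wise AUROC for matrices (same ordering convention as auroc()).
.rowAuroc <- function(x, y) {
    nN <- ncol(x); nT <- ncol(y)
    m <- cbind(y, x)
    apply(m, 1L, function(v) {
        r <- rank(v, ties.method = "average")
        (sum(r[seq_len(nT)]) - nT * (nT + 1) / 2) / (nN * nT)
    })
}

#' Per-cohort site statistics
#'
#' For every probe of one cohort: Welch p-value, BH q-value (adjusted within
#' the cohort across all probes), AUROC (tumor positive) and delta-beta
#' (mean tumor minus mean normal).
#'
#' @param x A [BetaCohortSet-class].
#' @param cohort Cohort name; default all cohorts, stacked long-form.
#' @return A `DataFrame` with columns `probe_id`, `chrom`, `pos`, `cohort`,
#'   `p`, `q`, `auc`, `delta_beta`.
#' @export
cohortSiteStats <- function(x, cohort = cohortNames(x)) {
    mf <- manifest(x)
    res <- lapply(cohort, function(co) {
        bn <- cohortMatrix(x, co, "normal")
        bt <- cohortMatrix(x, co, "tumor")
        if (ncol(bn) < 2L || ncol(bt) < 2L)
            stop("cohort ", co, " needs >= 2 samples per group")
        p <- .rowWelchP(bn, bt)
        DataFrame(probe_id = names(mf),
                  chrom = as.character(seqnames(mf)),
                  pos = start(mf),
                  cohort = co,
                  p = p,
                  q = adjustFdr(p),
                  auc = .rowAuroc(bn, bt),
                  delta_beta = rowMeans(bt) - rowMeans(bn))
    })
    do.call(rbind, res)
}

#' Aggregate site statistics across cancer types
#'
#' @param stats Long-form `DataFrame` from [cohortSiteStats()].
#' @param qThreshold Per-cohort FDR significance cut (exclusive: `q <`).
#' @return One row per probe: `mean_auc` (arithmetic mean of per-cohort
#'   AUCs), `n_cohorts`, `n_cohorts_significant`, `mean_delta`.
#' @export
aggregateSiteStats <- function(stats, qThreshold = 0.01) {
    f <- factor(stats$probe_id, levels = unique(stats$probe_id))
    DataFrame(probe_id = levels(f),
              chrom = stats$chrom[!duplicated(f)],
              pos = stats$pos[!duplicated(f)],
              mean_auc = as.numeric(tapply(stats$auc, f, mean)),
              n_cohorts = as.integer(tapply(stats$auc, f, length)),
              n_cohorts_significant =
                  as.integer(tapply(stats$q < qThreshold, f, sum)),
              mean_delta = as.numeric(tapply(stats$delta_beta, f, mean)))
}

#' Pan-cancer differentially methylated sites
#'
#' A probe is a pan-cancer DMS iff its q-value beats `qThreshold` in at
#' least `minSignificantFraction` of the cohorts where it is measured AND
#' its mean AUC across cohorts passes the gate: `mean_auc >=
#' meanAucThreshold` in `"hyper-only"` mode (tumor-positive, matching a
#' hypermethylation screen), or `max(mean_auc, 1 - mean_auc) >=
#' meanAucThreshold` in `"symmetric"` mode. Both boundaries are inclusive.
#'
#' @param stats Long-form `DataFrame` from [cohortSiteStats()].
#' @param manifest The probe manifest (defines output order).
#' @param qThreshold FDR cut, default 0.01.
#' @param meanAucThreshold Mean-AUC gate, default 0.75.
#' @param minSignificantFraction Fraction of cohorts that must be
#'   FDR-significant, default 1 (all cohorts).
#' @param directionMode `"hyper-only"` or `"symmetric"`.
#' @return A `GRanges` subset of the manifest, sorted by (chrom, pos), with
#'   a `direction` column (`"hyper"`/`"hypo"` by the sign of the mean
#'   delta-beta) and the aggregated statistics.
#' @export
panCancerDms <- function(stats, manifest, qThreshold = 0.01,
                         meanAucThreshold = 0.75,
                         minSignificantFraction = 1,
                         directionMode = c("hyper-only", "symmetric")) {
    directionMode <- match.arg(directionMode)
    if (nrow(stats) == 0L) stop("empty statistics table")
    stopifnot(qThreshold > 0, qThreshold <= 1,
              meanAucThreshold > 0, meanAucThreshold <= 1)
    agg <- aggregateSiteStats(stats, qThreshold = qThreshold)
    fracSig <- agg$n_cohorts_significant / agg$n_cohorts
    aucPass <- switch(directionMode,
        "hyper-only" = agg$mean_auc >= meanAucThreshold,
        "symmetric"  = pmax(agg$mean_auc, 1 - agg$mean_auc) >=
                           meanAucThreshold)
    keep <- fracSig >= minSignificantFraction & aucPass
    ids <- agg$probe_id[keep]
    manifest <- validManifest(manifest)
    out <- manifest[names(manifest) %in% ids]
    hit <- match(names(out), agg$probe_id)
    S4Vectors::mcols(out)$direction <-
        ifelse(agg$mean_delta[hit] >= 0, "hyper", "hypo")
    S4Vectors::mcols(out)$mean_auc <- agg$mean_auc[hit]
    S4Vectors::mcols(out)$mean_delta <- agg$mean_delta[hit]
    out
}
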