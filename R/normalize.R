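# Rank-based quantile normalization and cohort-size filtering.

# Assign the reference quantiles to one sample by within-sample rank; tied
# probes all receive the mean of the reference values at the tied rank
# positions (deterministic, order-independent).
.qnAssign <- function(x, ref) {
    ord <- order(x)
    sx <- x[ord]
    grp <- cumsum(c(TRUE, diff(sx) != 0))
    out <- numeric(length(x))
    out[ord] <- stats::ave(ref, grp)
    out
}

#' Quantile-normalize a beta matrix by rank assignment
#'
#' In the default `"rank-mean"` mode the reference vector is the sorted
#' vector of per-probe means across samples; within each sample the value of
#' within-sample rank k is replaced by the k-th smallest reference value, so
#' every output column carries an identical multiset of values and
#' within-sample rank order is preserved. The `"classic"` mode uses the
#' standard quantile-normalization reference (the mean of the per-sample
#' sorted columns) with the same rank assignment.
#'
#' @param x A probes-x-samples numeric matrix, or a [BetaCohortSet-class].
#' @param mode `"rank-mean"` (reference = sorted per-probe means) or
#'   `"classic"` (reference = mean of sorted columns).
#' @param perCohort For a `BetaCohortSet`: normalize each cohort separately
#'   instead of jointly across all samples (default joint, i.e. all samples
#'   enrolled).
#' @param ... Passed between methods.
#' @return An object of the same class with normalized values.
#' @examples
#' m <- cbind(s1 = c(0.1, 0.5, 0.9), s2 = c(0.2, 0.4, 0.6))
#' quantileNormalize(m)  # both columns become (0.15, 0.45, 0.75)
#' @export
setGeneric("quantileNormalize",
           function(x, ...) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix",
    function(x, mode = c("rank-mean", "classic"), ...) {
        mode <- match.arg(mode)
        if (nrow(x) < 1L || ncol(x) < 1L)
            stop("matrix must have at least one probe and one sample")
        if (anyNA(x))
            stop("missing values are not permitted; drop probes first ",
                 "(see dropIncompleteProbes)")
        ref <- switch(mode,
            "rank-mean" = sort(rowMeans(x)),
            "classic"   = rowMeans(apply(x, 2L, sort)))
        out <- apply(x, 2L, .qnAssign, ref = ref)
        dimnames(out) <- dimnames(x)
        out
    })

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "BetaCohortSet",
    function(x, mode = c("rank-mean", "classic"), perCohort = FALSE, ...) {
        mode <- match.arg(mode)
        b <- betaValues(x)
        if (perCohort) {
            for (co in cohortNames(x)) {
                idx <- colData(x)$cohort == co
                b[, idx] <- quantileNormalize(b[, idx, drop = FALSE],
                                              mode = mode)
            }
        } else {
            b <- quantileNormalize(b, mode = mode)
        }
        SummarizedExperiment::assay(x, "beta") <- b
        metadata(x)$normalized <- TRUE
        metadata(x)$qn_mode <- mode
        x
    })

#' Drop probes with missing values across all samples
#'
#' Missingness is not modeled downstream; the policy is to remove a probe
#' everywhere as soon as it is missing in any sample, and report how many
#' were dropped.
#'
#' @param x A [BetaCohortSet-class].
#' @return `x` without incomplete probes.
#' @export
dropIncompleteProbes <- function(x) {
    keep <- rowSums(is.na(betaValues(x))) == 0L
    if (!all(keep))
        message("dropping ", sum(!keep), " probe(s) with missing values")
    x[keep, ]
}

#' Remove cohorts with an undersized normal or tumor group
#'
#' A cohort is kept only if both its normal and its tumor group have at
#' least `minGroupSize` samples (the boundary is inclusive: a group of
#' exactly `minGroupSize` passes). Removals are reported via `message()`.
#'
#' @param x A [BetaCohortSet-class] or [ExpressionCohortSet-class].
#' @param minGroupSize Minimum per-group sample count (default 30, the
#'   per-group floor used for TCGA-style cohorts; use 60 for whole-dataset
#'   GEO-style filtering on `nNormal + nTumor` via `perDataset = TRUE`).
#' @param perDataset If `TRUE`, the threshold applies to the cohort's total
#'   sample count instead of each group separately.
#' @return The filtered object; errors if no cohort survives.
#' @export
filterCohorts <- function(x, minGroupSize = 30L, perDataset = FALSE) {
    if (minGroupSize < 1L) stop("minGroupSize must be >= 1")
    cd <- colData(x)
    keepCohort <- character()
    for (co in cohortNames(x)) {
        nN <- sum(cd$cohort == co & cd$group == "normal")
        nT <- sum(cd$cohort == co & cd$group == "tumor")
        ok <- if (perDataset) (nN + nT) >= minGroupSize
              else nN >= minGroupSize && nT >= minGroupSize
        if (ok) keepCohort <- c(keepCohort, co)
        else message(sprintf(
            "removing cohort %s (normal %d, tumor %d, threshold %d)",
            co, nN, nT, minGroupSize))
    }
    if (!length(keepCohort))
        stop("all cohorts fall below the group-size threshold of ",
             minGroupSize)
    x[, cd$cohort %in% keepCohort]
}
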