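#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData rowData
NULL

#' Validate a probe manifest
#'
#' A manifest is a named, width-1 \link[GenomicRanges]{GRanges}: one CpG probe
#' per record, names are probe ids. It defines the genomic order used by
#' "coordinately contiguous" DMR calling, so positions must be strictly
#' increasing within a chromosome and no two probes may share a locus.
#'
#' @param manifest A `GRanges` with unique names (probe ids).
#' @return The manifest, sorted by (chromosome, position), invisibly usable.
#' @export
validManifest <- function(manifest) {
    if (!is(manifest, "GRanges"))
        stop("manifest must be a GRanges")
    if (length(manifest) == 0L)
        stop("manifest is empty")
    if (is.null(names(manifest)) || anyDuplicated(names(manifest)))
        stop("manifest probe ids (names) must be present and unique")
    if (any(GenomicRanges::width(manifest) != 1L))
        stop("manifest probes must be single positions (width 1)")
    manifest <- GenomicRanges::sort(manifest)
    key <- paste(as.character(seqnames(manifest)), start(manifest))
    if (anyDuplicated(key))
        stop("two probes share the same (chrom, pos)")
    manifest
}

#' BetaCohortSet: multi-cancer beta-value cohorts on a shared manifest
#'
#' A \linkS4class{RangedSummarizedExperiment} holding one `beta` assay
#' (probes x samples, values in [0, 1]) whose `rowRanges` is the shared probe
#' manifest and whose `colData` carries `cohort` (cancer type / dataset) and
#' `group` (`"normal"` or `"tumor"`) for every sample.
#'
#' @aliases BetaCohortSet-class
#' @export
setClass("BetaCohortSet",
    contains = "RangedSummarizedExperiment")

setValidity("BetaCohortSet", function(object) {
    msg <- character()
    if (!("beta" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        # NA is tolerated here so the drop-probe policy can run on the set;
        # non-missing values must be valid beta fractions
        bad <- which(!is.na(b) & (!is.finite(b) | b < 0 | b > 1))
        if (length(bad))
            msg <- c(msg, sprintf(
                "beta values must be in [0,1]; first violation at matrix index %d",
                bad[1L]))
    }
    cd <- colData(object)
    if (!all(c("cohort", "group") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'cohort' and 'group'")
    else if (!all(cd$group %in% c("normal", "tumor")))
        msg <- c(msg, "group labels must be 'normal' or 'tumor'")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (is.null(names(rowRanges(object))))
        msg <- c(msg, "rowRanges must be a named probe manifest")
    if (length(msg)) msg else TRUE
})

#' Construct a BetaCohortSet
#'
#' @param manifest Named width-1 `GRanges` of probes (see [validManifest()]).
#' @param beta Numeric matrix, probes x samples, values in `[0, 1]`; row names
#'   must match the manifest probe ids.
#' @param sampleSheet `data.frame` with columns `sample_id`, `cohort`,
#'   `group` (`normal`/`tumor`), one row per column of `beta`.
#' @return A [BetaCohortSet-class] object.
#' @examples
#' mf <- generateManifest(20, chroms = "chr1", meanSpacingBp = 100, seed = 1)
#' sheet <- data.frame(sample_id = c("s1", "s2"),
#'                     cohort = "cohA", group = c("normal", "tumor"))
#' b <- matrix(runif(40), nrow = 20,
#'             dimnames = list(names(mf), sheet$sample_id))
#' bcs <- BetaCohortSet(mf, b, sheet)
#' @export
BetaCohortSet <- function(manifest, beta, sampleSheet) {
    manifest <- validManifest(manifest)
    if (is.null(rownames(beta)))
        stop("beta matrix must have probe ids as row names")
    if (!setequal(rownames(beta), names(manifest)))
        stop("beta row names do not match the manifest probe ids")
    beta <- beta[names(manifest), , drop = FALSE]
    need <- c("sample_id", "cohort", "group")
    if (!all(need %in% colnames(sampleSheet)))
        stop("sampleSheet needs columns: ", paste(need, collapse = ", "))
    missing <- setdiff(sampleSheet$sample_id, colnames(beta))
    if (length(missing))
        stop("sample(s) in sheet missing from matrix: ",
             paste(missing, collapse = ", "))
    beta <- beta[, sampleSheet$sample_id, drop = FALSE]
    cd <- DataFrame(cohort = sampleSheet$cohort, group = sampleSheet$group,
                    row.names = sampleSheet$sample_id)
    se <- SummarizedExperiment(assays = list(beta = beta),
                               rowRanges = manifest, colData = cd)
    new("BetaCohortSet", se)
}

#' ExpressionCohortSet: per-cohort normal/tumor expression on ordered genes
#'
#' A \linkS4class{SummarizedExperiment} with one `exprs` assay (genes x
#' samples, log-scale expression), a `block` column in `rowData` assigning
#' each clustered gene to a co-expression block (`NA` for genes outside the
#' cluster, e.g. a distal gene), and `cohort`/`group` sample annotation.
#'
#' @aliases ExpressionCohortSet-class
#' @export
setClass("ExpressionCohortSet",
    contains = "SummarizedExperiment")

setValidity("ExpressionCohortSet", function(object) {
    msg <- character()
    if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'exprs' is required")
    cd <- colData(object)
    if (!all(c("cohort", "group") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'cohort' and 'group'")
    else if (!all(cd$group %in% c("normal", "tumor")))
        msg <- c(msg, "group labels must be 'normal' or 'tumor'")
    if (!("block" %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must contain a 'block' assignment")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCohortSet
#'
#' @param exprs Numeric matrix, genes x samples, with gene row names.
#' @param sampleSheet `data.frame` with `sample_id`, `cohort`, `group`.
#' @param blockAssignment Named character vector gene -> block label; genes
#'   absent from it get `NA` (outside the clustered locus).
#' @return An [ExpressionCohortSet-class] object.
#' @export
ExpressionCohortSet <- function(exprs, sampleSheet, blockAssignment) {
    if (is.null(rownames(exprs)))
        stop("expression matrix must have gene row names")
    need <- c("sample_id", "cohort", "group")
    if (!all(need %in% colnames(sampleSheet)))
        stop("sampleSheet needs columns: ", paste(need, collapse = ", "))
    exprs <- exprs[, sampleSheet$sample_id, drop = FALSE]
    block <- unname(blockAssignment[rownames(exprs)])
    rd <- DataFrame(block = block, row.names = rownames(exprs))
    cd <- DataFrame(cohort = sampleSheet$cohort, group = sampleSheet$group,
                    row.names = sampleSheet$sample_id)
    se <- SummarizedExperiment(assays = list(exprs = exprs),
                               rowData = rd, colData = cd)
    new("ExpressionCohortSet", se)
}

# ---- accessors ------------------------------------------------------------

#' Accessors for cohort sets
#'
#' `manifest()` returns the probe manifest `GRanges`; `betaValues()` /
#' `exprValues()` the assay matrix; `sampleSheet()` the sample annotation as
#' a `data.frame`; `cohortNames()` the cohort labels; `cohortMatrix()` the
#' probes-x-samples (or genes-x-samples) submatrix for one cohort and group;
#' `blockAssignment()` the gene -> block map.
#'
#' @param x A [BetaCohortSet-class] or [ExpressionCohortSet-class].
#' @param cohort Cohort name.
#' @param group `"normal"` or `"tumor"`.
#' @return See the description per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname accessors
#' @export
setMethod("manifest", "BetaCohortSet", function(x) rowRanges(x))

#' @rdname accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname accessors
#' @export
setMethod("betaValues", "BetaCohortSet", function(x) assay(x, "beta"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionCohortSet", function(x) assay(x, "exprs"))

#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

.sheet <- function(x) {
    data.frame(sample_id = colnames(x),
               cohort = colData(x)$cohort,
               group = colData(x)$group,
               stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
setMethod("sampleSheet", "BetaCohortSet", .sheet)

#' @rdname accessors
#' @export
setMethod("sampleSheet", "ExpressionCohortSet", .sheet)

#' @rdname accessors
#' @export
setGeneric("cohortNames", function(x) standardGeneric("cohortNames"))

#' @rdname accessors
#' @export
setMethod("cohortNames", "SummarizedExperiment",
          function(x) unique(as.character(colData(x)$cohort)))

#' @rdname accessors
#' @export
setGeneric("cohortMatrix",
           function(x, cohort, group) standardGeneric("cohortMatrix"))

.cohortMatrix <- function(x, cohort, group, assayName) {
    group <- match.arg(group, c("normal", "tumor"))
    if (!cohort %in% colData(x)$cohort)
        stop("unknown cohort: ", cohort)
    keep <- colData(x)$cohort == cohort & colData(x)$group == group
    assay(x, assayName)[, keep, drop = FALSE]
}

#' @rdname accessors
#' @export
setMethod("cohortMatrix", "BetaCohortSet",
          function(x, cohort, group) .cohortMatrix(x, cohort, group, "beta"))

#' @rdname accessors
#' @export
setMethod("cohortMatrix", "ExpressionCohortSet",
          function(x, cohort, group) .cohortMatrix(x, cohort, group, "exprs"))

#' @rdname accessors
#' @export
setGeneric("blockAssignment", function(x) standardGeneric("blockAssignment"))

#' @rdname accessors
#' @export
setMethod("blockAssignment", "ExpressionCohortSet", function(x) {
    b <- rowData(x)$block
    names(b) <- rownames(x)
    b[!is.na(b)]
})

.showCohorts <- function(object, what) {
    cd <- colData(object)
    tab <- table(cohort = cd$cohort, group = cd$group)
    cat(class(object), "with", nrow(object), what, "and",
        ncol(object), "samples\n")
    cat("cohorts (normal/tumor):",
        paste(sprintf("%s (%d/%d)", rownames(tab),
                      tab[, "normal"], tab[, "tumor"]), collapse = ", "),
        "\n")
}

setMethod("show", "BetaCohortSet", function(object) {
    .showCohorts(object, "probes")
    qn <- metadata(object)$normalized
    if (isTRUE(qn)) cat("quantile-normalized:", metadata(object)$qn_mode, "\n")
})

setMethod("show", "ExpressionCohortSet", function(object) {
    .showCohorts(object, "genes")
    b <- blockAssignment(object)
    if (length(b))
        cat("blocks:", paste(sprintf("%s (%d genes)",
            names(table(b)), as.integer(table(b))), collapse = ", "), "\n")
})
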