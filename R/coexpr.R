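# Co-expression block structure and its disruption: Pearson correlation
# matrices per cohort and group, a within-vs-between block contrast, and
# distal-gene association tests.

#' Pearson correlation matrix of a gene expression matrix
#'
#' @param expr Genes x samples numeric matrix, >= 3 samples; genes with zero
#'   variance are an error (named in the message), not a silent `NaN`.
#' @return A symmetric correlation matrix with unit diagonal and an
#'   `nSamples` attribute.
#' @examples
#' x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 3, 2, 4))
#' correlationMatrix(x)["g1", "g2"]  # 0.8
#' @export
correlationMatrix <- function(expr) {
    if (ncol(expr) < 3L) stop("need at least 3 samples")
    if (anyNA(expr)) stop("missing expression values are not permitted")
    v <- apply(expr, 1L, stats::var)
    if (any(v == 0))
        stop("zero-variance gene(s): ",
             paste(rownames(expr)[v == 0], collapse = ", "))
    r <- stats::cor(t(expr), method = "pearson")
    r <- (r + t(r)) / 2  # exact symmetry
    diag(r) <- 1
    attr(r, "nSamples") <- ncol(expr)
    r
}

#' Within- versus between-block correlation contrast
#'
#' Quantifies co-expression modularity for an ordered gene cluster: the mean
#' off-diagonal correlation inside blocks minus the mean correlation across
#' blocks. An optional permutation test shuffles the gene-to-block labels
#' and reports the one-sided probability of a contrast at least as large as
#' observed.
#'
#' @param corr Correlation matrix from [correlationMatrix()].
#' @param blocks Named character vector gene -> block label covering >= 2
#'   blocks; genes absent from `corr` are an error. At least one block must
#'   have >= 2 genes.
#' @param nPermutations Number of label permutations (0 = no test).
#' @param seed Seed for the permutation draw.
#' @return A list with `within_mean`, `between_mean`, `contrast`
#'   (= within - between), and `p_permutation` (`NA` if not requested).
#' @export
blockContrast <- function(corr, blocks, nPermutations = 0L, seed = 1L) {
    genes <- names(blocks)
    missing <- setdiff(genes, rownames(corr))
    if (length(missing))
        stop("block gene(s) absent from matrix: ",
             paste(missing, collapse = ", "))
    if (length(unique(blocks)) < 2L) stop("need at least 2 blocks")
    if (max(table(blocks)) < 2L)
        stop("at least one block must contain >= 2 genes")
    r <- corr[genes, genes, drop = FALSE]
    contrastOf <- function(lab) {
        same <- outer(lab, lab, "==")
        ut <- upper.tri(r)
        mean(r[ut & same]) - mean(r[ut & !same])
    }
    obs <- contrastOf(blocks)
    pPerm <- NA_real_
    if (nPermutations > 0L) {
        set.seed(seed)
        exceed <- sum(vapply(seq_len(nPermutations), function(i)
            contrastOf(sample(blocks)) >= obs, logical(1L)))
        pPerm <- (1 + exceed) / (nPermutations + 1)
    }
    same <- outer(blocks, blocks, "==")
    ut <- upper.tri(r)
    list(within_mean = mean(r[ut & same]),
         between_mean = mean(r[ut & !same]),
         contrast = obs,
         p_permutation = pPerm)
}

#' Association of a distal gene with a gene cluster
#'
#' Pearson correlation and two-sided p-value (t-distributed with n - 2
#' degrees of freedom, via [stats::cor.test()]) between one distal gene and
#' each cluster gene.
#'
#' @param expr Genes x samples matrix containing both the distal gene and
#'   the cluster genes; >= 4 samples.
#' @param distalGene Name of the distal gene.
#' @param clusterGenes Cluster gene names.
#' @param alpha Significance level, default 0.05; `significant = (p < alpha)`.
#' @return A `DataFrame` with one row per cluster gene: `gene`, `r`, `p`,
#'   `significant`.
#' @export
distalAssociation <- function(expr, distalGene, clusterGenes,
                              alpha = 0.05) {
    if (ncol(expr) < 4L) stop("need at least 4 samples")
    if (!distalGene %in% rownames(expr))
        stop("distal gene absent from matrix: ", distalGene)
    missing <- setdiff(clusterGenes, rownames(expr))
    if (length(missing))
        stop("cluster gene(s) absent from matrix: ",
             paste(missing, collapse = ", "))
    d <- expr[distalGene, ]
    res <- lapply(clusterGenes, function(g) {
        ct <- stats::cor.test(d, expr[g, ], method = "pearson")
        data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value)
    })
    out <- DataFrame(do.call(rbind, res))
    out$significant <- out$p < alpha
    out
}

#' Per-cohort co-expression disruption summary
#'
#' For each cohort of an [ExpressionCohortSet-class], computes the block
#' contrast in the normal and the tumor group and their difference
#' (positive = modularity lost in tumors), plus the distal-gene association
#' count per group when a distal gene is present.
#'
#' @param x An [ExpressionCohortSet-class].
#' @param alpha Significance level for distal associations.
#' @return A `DataFrame`, one row per cohort: `cohort`, `contrast_normal`,
#'   `contrast_tumor`, `disruption` and, when applicable,
#'   `n_distal_sig_normal` / `n_distal_sig_tumor`.
#' @export
coexprDisruption <- function(x, alpha = 0.05) {
    blocks <- blockAssignment(x)
    distal <- setdiff(rownames(x), names(blocks))
    rows <- lapply(cohortNames(x), function(co) {
        cn <- correlationMatrix(cohortMatrix(x, co, "normal"))
        ct <- correlationMatrix(cohortMatrix(x, co, "tumor"))
        bn <- blockContrast(cn, blocks)
        bt <- blockContrast(ct, blocks)
        row <- data.frame(cohort = co,
                          contrast_normal = bn$contrast,
                          contrast_tumor = bt$contrast,
                          disruption = bn$contrast - bt$contrast)
        if (length(distal) == 1L) {
            dn <- distalAssociation(cohortMatrix(x, co, "normal"),
                                    distal, names(blocks), alpha)
            dt <- distalAssociation(cohortMatrix(x, co, "tumor"),
                                    distal, names(blocks), alpha)
            row$n_distal_sig_normal <- sum(dn$significant)
            row$n_distal_sig_tumor <- sum(dt$significant)
        }
        row
    })
    DataFrame(do.call(rbind, rows))
}
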