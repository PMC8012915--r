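# TSV readers/writers with validation, pipeline configuration, and the
# end-to-end orchestrator: simulate -> normalize -> per-cohort stats ->
# pan-cancer DMS -> DMR -> merge -> intersect -> co-expression.

#' Read and write probe manifests
#'
#' Manifest TSVs have columns `probe_id`, `chrom`, `pos` (1-based).
#'
#' @param path File path.
#' @return `readManifest()` a validated `GRanges`; `writeManifest()` the
#'   path, invisibly.
#' @export
readManifest <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("probe_id", "chrom", "pos")
    if (!all(need %in% colnames(df)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$probe_id))
        stop("duplicate probe id at line ",
             which(duplicated(df$probe_id))[1L] + 1L)
    gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L))
    names(gr) <- df$probe_id
    validManifest(gr)
}

#' @rdname readManifest
#' @param manifest A `GRanges` manifest.
#' @export
writeManifest <- function(manifest, path) {
    utils::write.table(
        data.frame(probe_id = names(manifest),
                   chrom = as.character(seqnames(manifest)),
                   pos = start(manifest)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write beta-value matrices
#'
#' Beta TSVs have a `probe_id` first column and one column per sample;
#' values must lie in `[0, 1]` (the first offending row is named).
#'
#' @param path File path.
#' @return `readBetaMatrix()` a probes x samples matrix with probe row
#'   names.
#' @export
readBetaMatrix <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (colnames(df)[1L] != "probe_id")
        stop("first column must be 'probe_id'")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$probe_id
    bad <- which(rowSums(!is.na(m) & (m < 0 | m > 1)) > 0)
    if (length(bad))
        stop(sprintf("beta value outside [0,1] at row %d (probe %s)",
                     bad[1L], rownames(m)[bad[1L]]))
    m
}

#' @rdname readBetaMatrix
#' @param m Probes x samples matrix.
#' @export
writeBetaMatrix <- function(m, path) {
    utils::write.table(
        data.frame(probe_id = rownames(m), m, check.names = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample sheet
#'
#' Columns `sample_id`, `cohort`, `group`; group labels must be `normal` or
#' `tumor`.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
readSampleSheet <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "cohort", "group")
    if (!all(need %in% colnames(df)))
        stop("sample sheet must have columns: ",
             paste(need, collapse = ", "))
    bad <- !df$group %in% c("normal", "tumor")
    if (any(bad))
        stop(sprintf(
            "unknown group label '%s' at line %d; allowed: normal, tumor",
            df$group[which(bad)[1L]], which(bad)[1L] + 1L))
    df
}

#' Read an expression matrix
#'
#' TSV with a `gene` first column and one column per sample.
#'
#' @param path File path.
#' @return Genes x samples matrix with gene row names.
#' @export
readExpression <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (colnames(df)[1L] != "gene")
        stop("first column must be 'gene'")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene
    m
}

#' @rdname readExpression
#' @param m Genes x samples matrix.
#' @export
writeExpression <- function(m, path) {
    utils::write.table(
        data.frame(gene = rownames(m), m, check.names = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold with its default: FDR cut `qThreshold`
#' 0.01, mean-AUC gate `meanAucThreshold` 0.75, DMR gates `minSites` 10 and
#' `minDensityPerKb` 3, merge distance `maxGapBp` 1000, per-group cohort
#' floor `minGroupSize` 30, distal-association `alpha` 0.05, plus the
#' normalization mode, DMS direction mode, fraction-significant rule,
#' simulation sizes and the master `seed`. Round-trips losslessly through
#' YAML via [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `PipelineConfig`.
#' @examples
#' cfg <- pipelineConfig(seed = 7, nCohorts = 2)
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        qThreshold = 0.01, meanAucThreshold = 0.75,
        minSignificantFraction = 1, directionMode = "hyper-only",
        minSites = 10L, minDensityPerKb = 3.0, maxGapBp = 1000L,
        minGroupSize = 30L, alpha = 0.05,
        qnMode = "rank-mean", perCohortNorm = FALSE,
        nProbes = 2000L, chroms = c("chr1", "chr7"),
        meanSpacingBp = 500L, nCohorts = 3L, nNormal = 40L, nTumor = 40L,
        noiseSd = 0.5, cohortSd = 0.02, baselineShape = c(0.85, 0.85),
        rWithinNormal = 0.8, rWithinTumor = 0.2, rBetween = 0.1,
        distalGeneRTumor = 0.35,
        seed = 1L)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    stopifnot(cfg$qThreshold > 0, cfg$qThreshold <= 1,
              cfg$meanAucThreshold > 0, cfg$meanAucThreshold <= 1,
              cfg$minSignificantFraction > 0, cfg$minSignificantFraction <= 1,
              cfg$minSites >= 1, cfg$minDensityPerKb >= 0,
              cfg$maxGapBp >= 0, cfg$minGroupSize >= 1,
              cfg$alpha > 0, cfg$alpha < 1)
    structure(cfg, class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
    do.call(pipelineConfig, yaml::read_yaml(path))
}

#' @rdname pipelineConfig
#' @param config A `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' Run the full synthetic pan-cancer pipeline
#'
#' Simulates two collections ("discovery" and "validation", emulating a
#' TCGA-discovery / GEO-validation design) on one shared manifest with the
#' same planted truth, then per collection: quantile normalization, cohort
#' filtering, per-cohort site statistics, pan-cancer DMS selection, DMR
#' calling and merging; the collections are intersected into the common DMR
#' set. Expression cohorts are generated and summarized with
#' [coexprDisruption()]. All stages derive sub-seeds from `config$seed`, so
#' two runs with the same config are identical.
#'
#' @param config A [pipelineConfig()].
#' @param outDir Output directory (created); per-stage TSV/BED/JSON files
#'   and a `summary.json` are written there.
#' @param planted Planted truth `data.frame` (see [plantedDMR()]), or
#'   `NULL` for a null run.
#' @return Invisibly, a list with the summary, the per-collection DMR
#'   `GRanges`, the common set and the co-expression summary.
#' @export
runAll <- function(config = pipelineConfig(), outDir, planted = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    mf <- generateManifest(config$nProbes, config$chroms,
                           config$meanSpacingBp, seed = config$seed)
    writeManifest(mf, file.path(outDir, "manifest.tsv"))
    if (!is.null(planted))
        jsonlite::write_json(planted, file.path(outDir, "planted.json"),
                             dataframe = "rows", auto_unbox = TRUE)

    collections <- c(discovery = 0L, validation = 101L)
    dmrsByColl <- list()
    summary <- list(config_hash = digestConfig(config))
    for (coll in names(collections)) {
        bcs <- generateBetaCohorts(mf, nCohorts = config$nCohorts,
            nNormal = config$nNormal, nTumor = config$nTumor,
            planted = planted, baselineShape = config$baselineShape,
            noiseSd = config$noiseSd, cohortSd = config$cohortSd,
            seed = config$seed + collections[[coll]])
        bcs <- dropIncompleteProbes(bcs)
        bcs <- filterCohorts(bcs, config$minGroupSize)
        bcs <- quantileNormalize(bcs, mode = config$qnMode,
                                 perCohort = config$perCohortNorm)
        st <- cohortSiteStats(bcs)
        utils::write.table(as.data.frame(st),
            file.path(outDir, paste0(coll, "_site_stats.tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        dms <- panCancerDms(st, mf, qThreshold = config$qThreshold,
            meanAucThreshold = config$meanAucThreshold,
            minSignificantFraction = config$minSignificantFraction,
            directionMode = config$directionMode)
        dmrs <- callDmrs(dms, mf, minSites = config$minSites,
                         minDensityPerKb = config$minDensityPerKb)
        merged <- mergeDmrs(dmrs, maxGapBp = config$maxGapBp)
        utils::write.table(dmrTable(merged),
            file.path(outDir, paste0(coll, "_dmrs.tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        writeDmrBed(merged, file.path(outDir, paste0(coll, "_dmrs.bed")))
        dmrsByColl[[coll]] <- merged
        summary[[coll]] <- list(n_cohorts = length(cohortNames(bcs)),
                                n_dms = length(dms),
                                n_dmrs = length(dmrs),
                                n_dmrs_merged = length(merged))
    }
    common <- intersectCollections(dmrsByColl$discovery,
                                   dmrsByColl$validation)
    utils::write.table(dmrTable(common),
        file.path(outDir, "common_dmrs.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_common_dmrs <- length(common)

    ecs <- generateExpressionCohorts(nCohorts = config$nCohorts,
        nNormal = config$nNormal, nTumor = config$nTumor,
        rWithinNormal = config$rWithinNormal,
        rWithinTumor = config$rWithinTumor, rBetween = config$rBetween,
        distalGeneRTumor = config$distalGeneRTumor, seed = config$seed)
    writeExpression(exprValues(ecs), file.path(outDir, "expression.tsv"))
    co <- coexprDisruption(ecs, alpha = config$alpha)
    utils::write.table(as.data.frame(co),
        file.path(outDir, "coexpr_summary.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    summary$mean_disruption <- mean(co$disruption)

    writePipelineConfig(config, file.path(outDir, "config.yaml"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(summary = summary, dmrs = dmrsByColl, common = common,
                   coexpr = co))
}

# Stable hash of a config for the run log (no external digest dependency:
# serialize deterministically and fold).
digestConfig <- function(config) {
    s <- paste(utils::capture.output(utils::str(unclass(config))),
               collapse = "\n")
    v <- utf8ToInt(s)
    sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}
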