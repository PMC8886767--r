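.paramsFromConfig <- function(config, key, ctor) {
    args <- config[[key]]
    if (is.null(args)) args <- list()
    do.call(ctor, args)
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) and returns every violation at
#' once rather than failing on the first.
#'
#' @param config a named list, or the path to a YAML file holding one. Keys:
#'   \code{outdir}, \code{seed}, \code{simulate} (logical), parameter blocks
#'   \code{dmv}, \code{annotation}, \code{specificity}, \code{overlap}
#'   (passed to the matching parameter constructors), an optional \code{plan}
#'   block (passed to \code{\link{defaultSimulationPlan}}) and, when
#'   \code{simulate} is \code{FALSE}, an \code{inputs} block with paths
#'   \code{cx} (named per tissue), \code{genes} (+ \code{genesDialect}),
#'   \code{expression} and optionally \code{peaks}.
#' @return A character vector of violations; empty when the config is valid.
#' @export
validateConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    v <- character()
    if (is.null(config$outdir)) v <- c(v, "outdir: missing")
    if (is.null(config$seed) || !is.finite(as.numeric(config$seed)))
        v <- c(v, "seed: missing or non-numeric")
    for (blk in c("dmv", "annotation", "specificity", "overlap")) {
        ctor <- switch(blk, dmv = DMVParams, annotation = AnnotationParams,
                       specificity = SpecificityParams, overlap = OverlapParams)
        err <- tryCatch({ .paramsFromConfig(config, blk, ctor); NULL },
                        error = function(e) conditionMessage(e))
        if (!is.null(err)) v <- c(v, paste0(blk, ": ", err))
    }
    simulate <- isTRUE(config$simulate) || is.null(config$inputs)
    if (!simulate) {
        ins <- config$inputs
        if (is.null(ins$cx) || length(ins$cx) < 1L)
            v <- c(v, "inputs$cx: at least one per-tissue cytosine report needed")
        paths <- as.character(c(unlist(ins$cx), ins$genes, ins$expression,
                                unlist(ins$peaks)))
        miss <- paths[!file.exists(paths)]
        if (length(miss))
            v <- c(v, paste0("missing input file: ", miss))
        if (is.null(ins$genes)) v <- c(v, "inputs$genes: missing")
        if (is.null(ins$expression)) v <- c(v, "inputs$expression: missing")
    }
    v
}

.stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
}

#' Run the full valley-analysis pipeline
#'
#' Executes the stages in dependency order -- simulate (optional), per-tissue
#' valley calling, cross-tissue conservation, gene annotation, expression
#' specificity, peak overlap and meta-profiles, then the summary report --
#' writing every intermediate as BED/TSV under \code{outdir}. All randomness
#' derives from the configured seed, so a rerun with the same configuration
#' is byte-identical. In simulation mode every simulated input is first
#' written to disk and read back through the same readers used for real
#' data.
#'
#' @param config see \code{\link{validateConfig}}.
#' @return The run report, invisibly: a nested list of per-stage record
#'   counts, fractions, the parameter echo and the seed (also written to
#'   \code{outdir/report.yaml}).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    violations <- validateConfig(config)
    if (length(violations))
        stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    seed <- as.integer(config$seed)
    dmvPar <- .paramsFromConfig(config, "dmv", DMVParams)
    annPar <- .paramsFromConfig(config, "annotation", AnnotationParams)
    spePar <- .paramsFromConfig(config, "specificity", SpecificityParams)
    ovlPar <- .paramsFromConfig(config, "overlap", OverlapParams)
    simulate <- isTRUE(config$simulate) || is.null(config$inputs)

    if (simulate) {
        planArgs <- config$plan
        if (is.null(planArgs)) planArgs <- list()
        if (!is.null(planArgs$chromLengths))
            planArgs$chromLengths <- unlist(planArgs$chromLengths)
        plan <- .stage("simulate-plan",
                       do.call(defaultSimulationPlan, c(list(seed = seed), planArgs)))
        indir <- file.path(outdir, "inputs")
        dir.create(indir, showWarnings = FALSE)
        cxPaths <- stats::setNames(
            file.path(indir, paste0("methylome_", plan@tissues, ".cx.tsv")),
            plan@tissues)
        .stage("simulate-methylomes", for (tis in plan@tissues)
            writeCytosineReport(simulateMethylome(plan, tis), cxPaths[tis]))
        genesPath <- file.path(indir, "genes.bed")
        writeBed(plan@plantedGenes, genesPath)
        exprPath <- file.path(indir, "expression.tsv")
        .stage("simulate-expression",
               writeExpressionMatrix(simulateExpression(plan), exprPath))
        chromLengths <- plan@chromLengths
        inputs <- list(cx = as.list(cxPaths), genes = genesPath,
                       genesDialect = "bed6", expression = exprPath)
    } else {
        plan <- NULL
        inputs <- config$inputs
        chromLengths <- unlist(config$chromLengths)
    }

    tissues <- names(inputs$cx)
    dmvSets <- list()
    report <- list(software = paste0("dmvscape ",
                                     as.character(utils::packageVersion("dmvscape"))),
                   seed = seed,
                   parameters = list(
                       dmv = list(windowSize = dmvPar@windowSize,
                                  step = dmvPar@step,
                                  minCytosines = dmvPar@minCytosines,
                                  minCoverage = dmvPar@minCoverage,
                                  maxLevel = dmvPar@maxLevel),
                       annotation = list(flankBp = annPar@flankBp,
                                         promoterBp = annPar@promoterBp,
                                         downstreamBp = annPar@downstreamBp,
                                         distalMinBp = annPar@distalMinBp)),
                   stages = list())
    for (tis in tissues) {
        calls <- .stage(paste0("read-cx-", tis),
                        readCytosineReport(inputs$cx[[tis]], "cx_report",
                                           seqlengths = chromLengths))
        st <- .stage(paste0("window-stats-", tis),
                     windowStats(calls, tileWindows(chromLengths, dmvPar), dmvPar))
        st <- callDMVWindows(st, dmvPar)
        dmv <- .stage(paste0("call-dmv-", tis),
                      mergeDMVWindows(st, calls, dmvPar, tissue = tis))
        writeBed(dmv, file.path(outdir, paste0("dmv_", tis, ".bed")))
        dmvSets[[tis]] <- dmv
        report$stages$dmv[[tis]] <- list(
            windows = length(st),
            windowsConsidered = sum(mcols(st)$considered),
            windowsQualifying = sum(mcols(st)$qualifies),
            nDMVs = length(dmv),
            dmvBases = sum(width(dmv)))
    }

    if (length(tissues) >= 2L) {
        cons <- .stage("conserve", conservedDMVs(dmvSets, dmvPar))
        conserved <- cons$conserved
        report$stages$conserved <- list(
            nDMVs = length(conserved),
            genomeFraction = round(genomeDMVCoverage(conserved, chromLengths), 4),
            sharedFraction = as.list(round(cons$sharedFraction, 4)))
    } else {
        conserved <- dmvSets[[1L]]
    }
    writeBed(conserved, file.path(outdir, "dmv_conserved.bed"))

    genes <- .stage("read-genes",
                    readAnnotation(inputs$genes,
                                   if (is.null(inputs$genesDialect)) "gff3"
                                   else inputs$genesDialect))
    ann <- .stage("annotate", classifyDMVs(conserved, genes, annPar))
    utils::write.table(ann, file.path(outdir, "dmv_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    geneCalls <- .stage("dmv-genes", callDMVGenes(genes, conserved, annPar))
    utils::write.table(geneCalls, file.path(outdir, "dmv_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$annotation <- list(
        categories = as.list(table(ann$category)),
        nDMVGenes = sum(geneCalls$is_dmv_gene),
        nPromoterDMVGenes = sum(geneCalls$has_promoter_dmv))

    expr <- .stage("read-expression", readExpressionMatrix(inputs$expression))
    spec <- .stage("specificity", callTissueSpecific(expr, spePar))
    utils::write.table(spec, file.path(outdir, "specificity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    nSpecPerTissue <- table(spec$peak_tissue[spec$is_specific])
    report$stages$specificity <- list(
        nGenes = nrow(spec),
        nExpressed = length(expressedGenes(expr, spePar)),
        nSpecific = sum(spec$is_specific),
        perTissue = as.list(nSpecPerTissue))

    ## TF/valley-style enrichment: specific genes among the annotated
    ## universe vs DMV-gene status
    universe <- geneCalls$gene_id
    specInUniverse <- intersect(spec$gene_id[spec$is_specific], universe)
    dmvGeneIds <- geneCalls$gene_id[geneCalls$is_dmv_gene]
    if (length(specInUniverse) && length(dmvGeneIds) &&
        length(specInUniverse) < length(universe) &&
        length(dmvGeneIds) < length(universe)) {
        enr <- tfDMVEnrichment(specInUniverse, dmvGeneIds, universe)
        report$stages$enrichment <- list(
            chisq = round(enr$statistic, 3),
            p.value = signif(enr$p.value, 3),
            odds.ratio = round(enr$odds.ratio, 3))
    }

    if (simulate) {
        peaks <- .stage("simulate-peaks", simulatePeaks(plan, conserved))
        peaksPath <- file.path(outdir, "inputs", "peaks.bed")
        writeBed(peaks, peaksPath)
        inputs$peaks <- peaksPath
    }
    if (!is.null(inputs$peaks)) {
        peaks <- .stage("read-peaks", readPeaks(inputs$peaks))
        frac <- .stage("overlap", peaksWithinDMVFraction(peaks, conserved, ovlPar))
        prof <- metaProfile(peaks, conserved, ovlPar, mode = "coverage",
                            normalization = "raw", label = "all-marks",
                            regionSet = "conserved-DMVs")
        profDt <- data.frame(bin = seq_along(profileValues(prof)),
                             value = round(profileValues(prof), 6))
        utils::write.table(profDt, file.path(outdir, "metaprofile_dmv.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report$stages$peaks <- list(
            nPeaks = length(peaks),
            withinDMVFraction = as.list(round(frac, 4)))
    }

    reportPath <- file.path(outdir, "report.yaml")
    writeLines(yaml::as.yaml(report), reportPath)
    message("report written to ", reportPath)
    invisible(report)
}
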