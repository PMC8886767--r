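#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
NULL

.CONTEXTS <- c("CG", "CHG", "CHH")

#' Parameters for the sliding-window DMV caller
#'
#' Holds the tunable parameters of the methylation-valley scan: a 1-kb window
#' advanced in 200-bp steps, a per-context site filter (at least five cytosines
#' covered by at least five reads), and the 5\% weighted-methylation ceiling
#' applied strictly (level < \code{maxLevel}) in CG, CHG and CHH alike.
#'
#' @slot windowSize window width in bp.
#' @slot step window increment in bp; must not exceed \code{windowSize}.
#' @slot minCytosines minimum qualifying cytosines per context per window.
#' @slot minCoverage minimum read depth for a cytosine to qualify.
#' @slot maxLevel weighted-methylation ceiling (strict upper bound), in (0,1).
#'
#' @exportClass DMVParams
setClass("DMVParams", representation(
    windowSize = "integer", step = "integer",
    minCytosines = "integer", minCoverage = "integer",
    maxLevel = "numeric"))

setValidity("DMVParams", function(object) {
    msg <- character()
    if (object@windowSize < 1L) msg <- c(msg, "windowSize must be positive")
    if (object@step < 1L) msg <- c(msg, "step must be positive")
    if (object@step > object@windowSize)
        msg <- c(msg, "step must not exceed windowSize")
    if (object@minCytosines < 1L) msg <- c(msg, "minCytosines must be positive")
    if (object@minCoverage < 1L) msg <- c(msg, "minCoverage must be positive")
    if (!is.finite(object@maxLevel) || object@maxLevel <= 0 || object@maxLevel >= 1)
        msg <- c(msg, "maxLevel must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' @param windowSize,step,minCytosines,minCoverage,maxLevel see slot docs.
#' @return A validated \code{DMVParams} object.
#' @examples
#' DMVParams()
#' DMVParams(maxLevel = 0.02)
#' @rdname DMVParams-class
#' @export
DMVParams <- function(windowSize = 1000L, step = 200L, minCytosines = 5L,
                      minCoverage = 5L, maxLevel = 0.05) {
    new("DMVParams", windowSize = as.integer(windowSize), step = as.integer(step),
        minCytosines = as.integer(minCytosines),
        minCoverage = as.integer(minCoverage), maxLevel = as.numeric(maxLevel))
}

#' Parameters for DMV/gene annotation
#'
#' @slot flankBp flank added to each gene side for DMV-gene containment (bp).
#' @slot promoterBp strand-aware upstream window used for the promoter
#'   category and promoter-DMV genes (bp).
#' @slot downstreamBp strand-aware downstream window (bp).
#' @slot distalMinBp minimum gap from the nearest gene body for a valley to be
#'   called distal (bp).
#'
#' @exportClass AnnotationParams
setClass("AnnotationParams", representation(
    flankBp = "integer", promoterBp = "integer",
    downstreamBp = "integer", distalMinBp = "integer"))

setValidity("AnnotationParams", function(object) {
    v <- c(object@flankBp, object@promoterBp, object@downstreamBp, object@distalMinBp)
    if (any(v < 1L)) "all annotation distances must be positive" else TRUE
})

#' @param flankBp,promoterBp,downstreamBp,distalMinBp see slot docs.
#' @return A validated \code{AnnotationParams} object.
#' @rdname AnnotationParams-class
#' @export
AnnotationParams <- function(flankBp = 1000L, promoterBp = 2000L,
                             downstreamBp = 2000L, distalMinBp = 2000L) {
    new("AnnotationParams", flankBp = as.integer(flankBp),
        promoterBp = as.integer(promoterBp),
        downstreamBp = as.integer(downstreamBp),
        distalMinBp = as.integer(distalMinBp))
}

#' Parameters for tissue-specificity scoring
#'
#' @slot expressedMinFpkm a gene counts as expressed when its maximum FPKM
#'   reaches this value in at least one tissue (default 0.5).
#' @slot expCutoff minimum maximum-FPKM for a gene to be tested for
#'   specificity (default 2; lower genes are omitted).
#' @slot zThreshold minimum peak z-score for a specific call.
#' @slot entropyMaxBits maximum Shannon entropy (bits) for a specific call.
#' @slot nClusters number of stage clusters for specific-gene profiles.
#'
#' @exportClass SpecificityParams
setClass("SpecificityParams", representation(
    expressedMinFpkm = "numeric", expCutoff = "numeric", zThreshold = "numeric",
    entropyMaxBits = "numeric", nClusters = "integer"))

setValidity("SpecificityParams", function(object) {
    msg <- character()
    if (object@expressedMinFpkm <= 0) msg <- c(msg, "expressedMinFpkm must be positive")
    if (object@expCutoff <= 0) msg <- c(msg, "expCutoff must be positive")
    if (object@zThreshold <= 0) msg <- c(msg, "zThreshold must be positive")
    if (object@entropyMaxBits <= 0) msg <- c(msg, "entropyMaxBits must be positive")
    if (object@nClusters < 1L) msg <- c(msg, "nClusters must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @param expressedMinFpkm,expCutoff,zThreshold,entropyMaxBits,nClusters see
#'   slot docs.
#' @return A validated \code{SpecificityParams} object.
#' @rdname SpecificityParams-class
#' @export
SpecificityParams <- function(expressedMinFpkm = 0.5, expCutoff = 2,
                              zThreshold = 2, entropyMaxBits = 2,
                              nClusters = 9L) {
    new("SpecificityParams", expressedMinFpkm = as.numeric(expressedMinFpkm),
        expCutoff = as.numeric(expCutoff), zThreshold = as.numeric(zThreshold),
        entropyMaxBits = as.numeric(entropyMaxBits),
        nClusters = as.integer(nClusters))
}

#' Parameters for peak/region overlap statistics and meta-profiles
#'
#' @slot withinRule how a peak counts as lying within the valley union:
#'   \code{"frac_overlap"} (at least \code{minFrac} of its length overlaps) or
#'   \code{"midpoint"} (its midpoint falls inside).
#' @slot minFrac overlap fraction used by the \code{frac_overlap} rule, (0,1].
#' @slot geneFlankBp flank added to gene bodies when asking whether a gene is
#'   marked by a peak (bp).
#' @slot profileFlankBp flank length in the meta-profile (bp; 1000 for DMV
#'   profiles, 2000 for gene-style profiles).
#' @slot nBodyBins number of scaled bins across the region body.
#' @slot nFlankBins number of absolute-bp bins per flank.
#'
#' @exportClass OverlapParams
setClass("OverlapParams", representation(
    withinRule = "character", minFrac = "numeric", geneFlankBp = "integer",
    profileFlankBp = "integer", nBodyBins = "integer", nFlankBins = "integer"))

setValidity("OverlapParams", function(object) {
    msg <- character()
    if (!object@withinRule %in% c("frac_overlap", "midpoint"))
        msg <- c(msg, "withinRule must be 'frac_overlap' or 'midpoint'")
    if (object@minFrac <= 0 || object@minFrac > 1)
        msg <- c(msg, "minFrac must lie in (0, 1]")
    if (object@geneFlankBp < 1L) msg <- c(msg, "geneFlankBp must be positive")
    if (object@profileFlankBp < 1L) msg <- c(msg, "profileFlankBp must be positive")
    if (object@nBodyBins < 1L || object@nFlankBins < 1L)
        msg <- c(msg, "bin counts must be positive")
    if (length(msg)) msg else TRUE
})

#' @param withinRule,minFrac,geneFlankBp,profileFlankBp,nBodyBins,nFlankBins
#'   see slot docs.
#' @return A validated \code{OverlapParams} object.
#' @rdname OverlapParams-class
#' @export
OverlapParams <- function(withinRule = c("frac_overlap", "midpoint"),
                          minFrac = 0.5, geneFlankBp = 1000L,
                          profileFlankBp = 1000L, nBodyBins = 40L,
                          nFlankBins = 20L) {
    new("OverlapParams", withinRule = match.arg(withinRule),
        minFrac = as.numeric(minFrac), geneFlankBp = as.integer(geneFlankBp),
        profileFlankBp = as.integer(profileFlankBp),
        nBodyBins = as.integer(nBodyBins), nFlankBins = as.integer(nFlankBins))
}

#' Per-cytosine methylation calls
#'
#' A \linkS4class{GRanges} of width-1 cytosine positions carrying the context
#' (\code{CG}, \code{CHG} or \code{CHH}) and the methylated / total read
#' counts, the unit record of a whole-genome bisulfite experiment. Strand is
#' kept as reported by the caller; downstream window statistics sum counts
#' from both strands, which for weighted levels is equivalent to pooling.
#'
#' @exportClass CytosineCalls
setClass("CytosineCalls", contains = "GRanges")

setValidity("CytosineCalls", function(object) {
    mc <- mcols(object)
    req <- c("context", "methylated", "total")
    if (!all(req %in% colnames(mc)))
        return(paste("missing metadata columns:",
                     paste(setdiff(req, colnames(mc)), collapse = ", ")))
    msg <- character()
    if (!all(as.character(mc$context) %in% .CONTEXTS))
        msg <- c(msg, "context must be one of CG, CHG, CHH")
    if (any(width(object) != 1L))
        msg <- c(msg, "cytosine positions must have width 1")
    if (any(as.character(strand(object)) == "*"))
        msg <- c(msg, "strand must be '+' or '-'")
    m <- mc$methylated; t <- mc$total
    if (any(m < 0L) || any(t < 0L) || any(m > t))
        msg <- c(msg, "counts must satisfy 0 <= methylated <= total")
    if (length(msg)) msg else TRUE
})

#' @param chrom chromosome names (or a \code{GRanges} already carrying the
#'   metadata columns, in which case the remaining arguments are ignored).
#' @param position 1-based cytosine coordinates.
#' @param strand \code{"+"} or \code{"-"} per cytosine.
#' @param context \code{"CG"}, \code{"CHG"} or \code{"CHH"} per cytosine.
#' @param methylated,total read counts with \code{0 <= methylated <= total}.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A validated \code{CytosineCalls} object, sorted by position.
#' @examples
#' CytosineCalls("sc1", c(101L, 135L), c("+", "-"), c("CG", "CHH"),
#'               methylated = c(3L, 0L), total = c(10L, 8L))
#' @rdname CytosineCalls-class
#' @export
CytosineCalls <- function(chrom, position = NULL, strand = NULL, context = NULL,
                          methylated = NULL, total = NULL, seqlengths = NULL) {
    if (is(chrom, "GRanges")) {
        gr <- chrom
    } else {
        gr <- GRanges(chrom, IRanges(position, width = 1L), strand = strand,
                      context = factor(context, levels = .CONTEXTS),
                      methylated = as.integer(methylated),
                      total = as.integer(total))
    }
    if (!is.factor(mcols(gr)$context))
        mcols(gr)$context <- factor(mcols(gr)$context, levels = .CONTEXTS)
    if (!is.null(seqlengths))
        seqlengths(gr) <- seqlengths[seqlevels(gr)]
    new("CytosineCalls", sort(gr, ignore.strand = TRUE))
}

#' A set of DNA methylation valleys
#'
#' A \linkS4class{GRanges} of merged hypomethylated intervals from one tissue
#' (or the cross-tissue conserved set), carrying per-context weighted
#' methylation levels (\code{mCG}, \code{mCHG}, \code{mCHH}) recomputed over
#' the merged region, the number of qualifying windows merged
#' (\code{nWindows}) and the tissue of origin. Ranges are sorted and pairwise
#' non-overlapping.
#'
#' @exportClass DMVSet
setClass("DMVSet", contains = "GRanges")

setValidity("DMVSet", function(object) {
    mc <- mcols(object)
    req <- c("tissue", "nWindows", "mCG", "mCHG", "mCHH")
    if (!all(req %in% colnames(mc)))
        return(paste("missing metadata columns:",
                     paste(setdiff(req, colnames(mc)), collapse = ", ")))
    msg <- character()
    lv <- as.matrix(mc[, c("mCG", "mCHG", "mCHH")])
    if (any(lv < 0 | lv > 1, na.rm = TRUE))
        msg <- c(msg, "methylation levels must lie in [0, 1]")
    if (length(object) > 1L) {
        s <- sort(object, ignore.strand = TRUE)
        if (!identical(granges(s, use.mcols = FALSE), granges(object, use.mcols = FALSE)))
            msg <- c(msg, "DMVs must be sorted by position")
        if (!isDisjoint(object))
            msg <- c(msg, "DMVs within a set must be pairwise non-overlapping")
    }
    if (length(msg)) msg else TRUE
})

#' @param ranges a \code{GRanges} of merged valley intervals.
#' @param tissue tissue label (recycled).
#' @param nWindows qualifying windows merged per valley.
#' @param mCG,mCHG,mCHH per-context weighted methylation level over the merged
#'   region (NA when the context had no covered cytosines).
#' @return A validated \code{DMVSet}.
#' @rdname DMVSet-class
#' @export
DMVSet <- function(ranges, tissue = "NA", nWindows = NA_integer_,
                   mCG = NA_real_, mCHG = NA_real_, mCHH = NA_real_) {
    gr <- granges(ranges, use.mcols = FALSE)
    n <- length(gr)
    mcols(gr) <- DataFrame(tissue = rep_len(tissue, n),
                           nWindows = rep_len(as.integer(nWindows), n),
                           mCG = rep_len(as.numeric(mCG), n),
                           mCHG = rep_len(as.numeric(mCHG), n),
                           mCHH = rep_len(as.numeric(mCHH), n))
    new("DMVSet", sort(gr, ignore.strand = TRUE))
}

#' Binned average signal over a region set
#'
#' The meta-region (metagene) summary: each region's body is rescaled to
#' \code{nBodyBins} bins and flanked by \code{nFlankBins} absolute-bp bins on
#' either side; the profile is the across-region mean of per-bin signal
#' (peak-coverage fraction, score density, or weighted methylation level).
#' Under \code{max1} normalization the maximum equals exactly 1.
#'
#' @slot label what the profile summarizes (e.g. a histone mark).
#' @slot regionSet label of the region set profiled.
#' @slot values numeric vector of length \code{nFlankBins + nBodyBins +
#'   nFlankBins}, flank / body / flank order, 5' to 3'.
#' @slot nBodyBins,nFlankBins bin layout.
#' @slot normalization \code{"max1"} or \code{"raw"}.
#'
#' @exportClass MetaProfile
setClass("MetaProfile", representation(
    label = "character", regionSet = "character", values = "numeric",
    nBodyBins = "integer", nFlankBins = "integer", normalization = "character"))

setValidity("MetaProfile", function(object) {
    msg <- character()
    if (length(object@values) != object@nBodyBins + 2L * object@nFlankBins)
        msg <- c(msg, "values length must equal nBodyBins + 2 * nFlankBins")
    if (!object@normalization %in% c("max1", "raw"))
        msg <- c(msg, "normalization must be 'max1' or 'raw'")
    if (object@normalization == "max1") {
        v <- object@values[!is.na(object@values)]
        if (length(v) && (abs(max(v) - 1) > 1e-12 || any(v < 0) || any(v > 1)))
            msg <- c(msg, "max1 profiles must have maximum 1 and values in [0,1]")
    }
    if (length(msg)) msg else TRUE
})

#' Plan for a seeded synthetic methylome / expression / peak simulation
#'
#' Describes the genome, the per-context cytosine densities and background
#' methylation means, the planted near-zero-methylation valleys (identical
#' across tissues, emulating the developmental conservation of valleys), the
#' gene models placed inside and outside valleys, the expression atlas with
#' planted single-tissue-specific genes, and the peak plan coupling histone
#' peaks to valleys with probability \code{pInDMV}. A single integer seed
#' makes every output deterministic; per-tissue sub-streams are derived from
#' the seed and the tissue index.
#'
#' @slot seed integer RNG seed.
#' @slot chromLengths named integer vector of chromosome lengths (bp).
#' @slot cytosineDensity named numeric: expected cytosines per bp per context.
#' @slot coverageLambda mean Poisson read depth.
#' @slot backgroundMethylation named numeric: mean level per context.
#' @slot methylationDispersion beta concentration for per-cytosine true levels.
#' @slot plantedDMVs \code{GRanges} with a \code{level} metadata column
#'   (each level < 0.05).
#' @slot plantedGenes \code{GRanges} gene models with \code{gene_id} and
#'   \code{placement} (\code{inside_dmv} / \code{outside_dmv}) columns.
#' @slot tissues methylome tissue labels.
#' @slot exprTissues expression-atlas tissue labels.
#' @slot nBackgroundGenes count of non-specific genes in the atlas.
#' @slot specificGenePlan data.frame (geneId, tissue, onFpkm, offFpkm).
#' @slot exprNoiseSd multiplicative log-normal noise sd (log scale).
#' @slot peakPlan data.frame (mark, n, minLen, maxLen, pInDMV).
#'
#' @exportClass SimulationPlan
setClass("SimulationPlan", representation(
    seed = "integer", chromLengths = "integer", cytosineDensity = "numeric",
    coverageLambda = "numeric", backgroundMethylation = "numeric",
    methylationDispersion = "numeric", plantedDMVs = "GRanges",
    plantedGenes = "GRanges", tissues = "character", exprTissues = "character",
    nBackgroundGenes = "integer", specificGenePlan = "data.frame",
    exprNoiseSd = "numeric", peakPlan = "data.frame"))

setValidity("SimulationPlan", function(object) {
    msg <- character()
    if (is.null(names(object@chromLengths)) || any(object@chromLengths < 1L))
        msg <- c(msg, "chromLengths must be a named vector of positive lengths")
    if (!all(.CONTEXTS %in% names(object@cytosineDensity)))
        msg <- c(msg, "cytosineDensity must name CG, CHG and CHH")
    if (!all(.CONTEXTS %in% names(object@backgroundMethylation)))
        msg <- c(msg, "backgroundMethylation must name CG, CHG and CHH")
    bg <- object@backgroundMethylation[.CONTEXTS]
    if (any(bg < 0 | bg > 1)) msg <- c(msg, "background levels must lie in [0,1]")
    if (object@coverageLambda < 0) msg <- c(msg, "coverageLambda must be >= 0")
    if (object@methylationDispersion <= 0)
        msg <- c(msg, "methylationDispersion must be positive")
    pd <- object@plantedDMVs
    if (length(pd)) {
        if (is.null(pd$level)) msg <- c(msg, "plantedDMVs need a 'level' column")
        else if (any(pd$level < 0 | pd$level >= 0.05))
            msg <- c(msg, "planted valley levels must lie in [0, 0.05)")
        if (!isDisjoint(pd)) msg <- c(msg, "planted valleys must not overlap")
        bad <- !as.character(seqnames(pd)) %in% names(object@chromLengths) |
            end(pd) > object@chromLengths[as.character(seqnames(pd))] | start(pd) < 1L
        if (any(bad)) msg <- c(msg, "planted valleys must lie within chromosome bounds")
    }
    if (nrow(object@specificGenePlan)) {
        sgp <- object@specificGenePlan
        if (!all(c("geneId", "tissue", "onFpkm", "offFpkm") %in% names(sgp)))
            msg <- c(msg, "specificGenePlan needs geneId, tissue, onFpkm, offFpkm")
        else if (!all(sgp$tissue %in% object@exprTissues))
            msg <- c(msg, "specificGenePlan target tissues must be atlas tissues")
    }
    if (nrow(object@peakPlan)) {
        pp <- object@peakPlan
        if (!all(c("mark", "n", "minLen", "maxLen", "pInDMV") %in% names(pp)))
            msg <- c(msg, "peakPlan needs mark, n, minLen, maxLen, pInDMV")
        else if (any(pp$pInDMV < 0 | pp$pInDMV > 1))
            msg <- c(msg, "pInDMV must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "DMVParams", function(object) {
    cat(sprintf(
        "DMVParams: %d-bp windows, %d-bp step; >=%d cytosines at >=%dx per context; level < %.3f\n",
        object@windowSize, object@step, object@minCytosines, object@minCoverage,
        object@maxLevel))
})

setMethod("show", "SimulationPlan", function(object) {
    cat(sprintf(
        "SimulationPlan: seed %d; %d chrom (%.2f Mb); %d planted valleys; %d methylome tissues; %d atlas tissues\n",
        object@seed, length(object@chromLengths),
        sum(as.numeric(object@chromLengths)) / 1e6, length(object@plantedDMVs),
        length(object@tissues), length(object@exprTissues)))
})

setMethod("show", "CytosineCalls", function(object) {
    cat(sprintf("CytosineCalls with %d positions (%s)\n", length(object),
                paste(sprintf("%s: %d", .CONTEXTS,
                              as.vector(table(mcols(object)$context)[.CONTEXTS])),
                      collapse = ", ")))
    callNextMethod()
})

setMethod("show", "DMVSet", function(object) {
    tis <- unique(as.character(mcols(object)$tissue))
    cat(sprintf("DMVSet with %d valleys spanning %.0f kb (tissue: %s)\n",
                length(object), sum(width(object)) / 1e3,
                paste(tis, collapse = ", ")))
    callNextMethod()
})

setMethod("show", "MetaProfile", function(object) {
    cat(sprintf(
        "MetaProfile '%s' over '%s': %d+%d+%d bins, %s normalization\n",
        object@label, object@regionSet, object@nFlankBins, object@nBodyBins,
        object@nFlankBins, object@normalization))
})

#' @describeIn MetaProfile-class the per-bin profile values.
#' @param object a \code{MetaProfile}.
#' @export
profileValues <- function(object) object@values
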