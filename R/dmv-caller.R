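#' Tile a chromosome with sliding windows
#'
#' Windows of \code{windowSize} bp advanced by \code{step} bp from the
#' chromosome start; the final window is truncated at the chromosome end, so
#' the window count is \code{ceil(max(L - windowSize, 0) / step) + 1}.
#'
#' @param chromLengths named vector of chromosome lengths (bp).
#' @param params a \linkS4class{DMVParams}.
#' @return A \code{GRanges} of windows, sorted by (chrom, start).
#' @examples
#' tileWindows(c(sc1 = 1400), DMVParams())
#' @export
tileWindows <- function(chromLengths, params = DMVParams()) {
    validObject(params)
    if (is.null(names(chromLengths)))
        stop("chromLengths must be a named vector")
    if (any(chromLengths < 1)) stop("chromosome lengths must be positive")
    si <- Seqinfo(names(chromLengths), seqlengths = as.integer(chromLengths))
    out <- vector("list", length(chromLengths))
    for (i in seq_along(chromLengths)) {
        L <- as.integer(chromLengths[i])
        n <- ceiling(max(L - params@windowSize, 0L) / params@step) + 1L
        st <- (seq_len(n) - 1L) * params@step + 1L
        en <- pmin(st + params@windowSize - 1L, L)
        out[[i]] <- GRanges(factor(rep(names(chromLengths)[i], n),
                                   levels = names(chromLengths)),
                            IRanges(st, en), seqinfo = si)
    }
    do.call(c, out)
}

#' Per-window methylation statistics
#'
#' For each window and each context, counts the qualifying cytosines (read
#' depth at least \code{minCoverage}) and their summed methylated / total
#' counts; the weighted level is the ratio of the sums. A window is
#' \emph{considered} only when every context has at least \code{minCytosines}
#' qualifying cytosines (the site filter is applied per context, since a
#' context level estimated from fewer sites is unstable and the valley
#' threshold must hold in all three contexts). Counts from both strands are
#' summed, which is equivalent to strand pooling for weighted levels.
#'
#' @param calls a \linkS4class{CytosineCalls} object (any order; overlap
#'   assignment does not require sorted input).
#' @param windows windows from \code{\link{tileWindows}}, or a named
#'   chromosome-length vector to tile internally.
#' @param params a \linkS4class{DMVParams}.
#' @return A \code{GRanges} of windows with metadata columns
#'   \code{nSites_<ctx>}, \code{meth_<ctx>}, \code{total_<ctx>},
#'   \code{level_<ctx>} for each context, and \code{considered}.
#' @export
windowStats <- function(calls, windows, params = DMVParams()) {
    validObject(params)
    if (!is(windows, "GRanges")) windows <- tileWindows(windows, params)
    keep <- mcols(calls)$total >= params@minCoverage
    q <- calls[keep]
    hits <- findOverlaps(q, windows, ignore.strand = TRUE)
    dt <- data.table::data.table(
        win = subjectHits(hits),
        ctx = as.integer(mcols(q)$context[queryHits(hits)]),
        meth = mcols(q)$methylated[queryHits(hits)],
        total = mcols(q)$total[queryHits(hits)])
    agg <- dt[, list(nSites = .N, meth = sum(meth), total = sum(total)),
              by = c("win", "ctx")]
    nw <- length(windows)
    mc <- DataFrame(row.names = seq_len(nw))
    considered <- rep(TRUE, nw)
    for (k in seq_along(.CONTEXTS)) {
        ctxName <- .CONTEXTS[k]
        sub <- agg[agg$ctx == k, ]
        nSites <- meth <- total <- integer(nw)
        nSites[sub$win] <- sub$nSites
        meth[sub$win] <- sub$meth
        total[sub$win] <- sub$total
        level <- ifelse(total > 0L, meth / total, NA_real_)
        mc[[paste0("nSites_", ctxName)]] <- nSites
        mc[[paste0("meth_", ctxName)]] <- meth
        mc[[paste0("total_", ctxName)]] <- total
        mc[[paste0("level_", ctxName)]] <- level
        considered <- considered & nSites >= params@minCytosines & total > 0L
    }
    mc$considered <- considered
    out <- granges(windows, use.mcols = FALSE)
    mcols(out) <- mc
    out
}

#' Select windows that qualify as valley windows
#'
#' A window qualifies when it is considered and its weighted level is
#' strictly below \code{maxLevel} in all three contexts (a window at exactly
#' the threshold in any context is rejected).
#'
#' @param stats window statistics from \code{\link{windowStats}}.
#' @param params a \linkS4class{DMVParams}.
#' @return The input with an added logical \code{qualifies} column.
#' @export
callDMVWindows <- function(stats, params = DMVParams()) {
    validObject(params)
    mc <- mcols(stats)
    ok <- mc$considered
    for (ctxName in .CONTEXTS) {
        lv <- mc[[paste0("level_", ctxName)]]
        ok <- ok & !is.na(lv) & lv < params@maxLevel
    }
    mcols(stats)$qualifies <- ok
    stats
}

#' Merge qualifying valley windows into contiguous valleys
#'
#' Overlapping or book-ended qualifying windows are merged into maximal
#' intervals, and the per-context weighted levels are recomputed over each
#' merged region's qualifying cytosines.
#'
#' @param qualifying window statistics (only rows with
#'   \code{qualifies == TRUE} are used, so the full output of
#'   \code{\link{callDMVWindows}} can be passed).
#' @param calls the \linkS4class{CytosineCalls} the windows were scored from.
#' @param params a \linkS4class{DMVParams}.
#' @param tissue tissue label stamped on the valleys.
#' @return A \linkS4class{DMVSet}.
#' @export
mergeDMVWindows <- function(qualifying, calls, params = DMVParams(),
                            tissue = "NA") {
    if (!is.null(mcols(qualifying)$qualifies))
        qualifying <- qualifying[mcols(qualifying)$qualifies]
    if (length(qualifying) == 0L)
        return(DMVSet(GRanges(), tissue = character()))
    merged <- GenomicRanges::reduce(granges(qualifying, use.mcols = FALSE),
                                    ignore.strand = TRUE)
    nWin <- countOverlaps(merged, qualifying, ignore.strand = TRUE)
    q <- calls[mcols(calls)$total >= params@minCoverage]
    hits <- findOverlaps(q, merged, ignore.strand = TRUE)
    dt <- data.table::data.table(
        reg = subjectHits(hits),
        ctx = as.integer(mcols(q)$context[queryHits(hits)]),
        meth = mcols(q)$methylated[queryHits(hits)],
        total = mcols(q)$total[queryHits(hits)])
    agg <- dt[, list(meth = sum(meth), total = sum(total)), by = c("reg", "ctx")]
    lv <- matrix(NA_real_, nrow = length(merged), ncol = 3L)
    lv[cbind(agg$reg, agg$ctx)] <- agg$meth / agg$total
    DMVSet(merged, tissue = tissue, nWindows = nWin,
           mCG = lv[, 1L], mCHG = lv[, 2L], mCHH = lv[, 3L])
}

#' Call DNA methylation valleys for one tissue
#'
#' Convenience wrapper running the full per-tissue scan: tile, score, apply
#' the strict sub-threshold rule in all three contexts, and merge.
#'
#' @param calls a \linkS4class{CytosineCalls} object.
#' @param chromLengths named chromosome lengths; taken from
#'   \code{seqlengths(calls)} when omitted.
#' @param params a \linkS4class{DMVParams}.
#' @param tissue tissue label.
#' @return A \linkS4class{DMVSet}.
#' @examples
#' plan <- defaultSimulationPlan(seed = 1, chromLengths = c(sc1 = 200000L),
#'                               nPlantedDMVs = 2)
#' calls <- simulateMethylome(plan, "leaf")
#' callDMVs(calls, tissue = "leaf")
#' @export
callDMVs <- function(calls, chromLengths = NULL, params = DMVParams(),
                     tissue = "NA") {
    if (is.null(chromLengths)) {
        chromLengths <- seqlengths(calls)
        if (any(is.na(chromLengths)))
            stop("chromLengths not given and seqlengths(calls) incomplete")
    }
    st <- windowStats(calls, tileWindows(chromLengths, params), params)
    st <- callDMVWindows(st, params)
    mergeDMVWindows(st, calls, params, tissue = tissue)
}

#' Valleys conserved across all tissues
#'
#' The conserved set is the per-base intersection of the per-tissue valley
#' sets (a base is conserved when every tissue's valley set covers it), with
#' runs shorter than \code{windowSize} discarded. The per-tissue shared
#' fraction is the fraction of a tissue's valleys that overlap (by at least
#' 1 bp) a valley of at least one other tissue.
#'
#' @param perTissue named list of \linkS4class{DMVSet} (or \code{GRanges}),
#'   one per tissue; at least two tissues.
#' @param params a \linkS4class{DMVParams} (provides the minimum run length).
#' @return A list with elements \code{conserved} (a \linkS4class{DMVSet} with
#'   tissue \code{"conserved"}) and \code{sharedFraction} (named numeric per
#'   tissue).
#' @export
conservedDMVs <- function(perTissue, params = DMVParams()) {
    if (length(perTissue) < 2L) stop("need valley sets from >= 2 tissues")
    if (is.null(names(perTissue)))
        names(perTissue) <- paste0("tissue", seq_along(perTissue))
    sets <- lapply(perTissue, function(x)
        GenomicRanges::reduce(granges(x, use.mcols = FALSE), ignore.strand = TRUE))
    cons <- Reduce(function(a, b)
        GenomicRanges::intersect(a, b, ignore.strand = TRUE), sets)
    cons <- cons[width(cons) >= params@windowSize]
    shared <- vapply(seq_along(sets), function(i) {
        others <- GenomicRanges::reduce(
            do.call(c, unname(sets[-i])), ignore.strand = TRUE)
        if (length(sets[[i]]) == 0L) return(NA_real_)
        mean(countOverlaps(sets[[i]], others, ignore.strand = TRUE) > 0L)
    }, numeric(1))
    names(shared) <- names(perTissue)
    list(conserved = DMVSet(cons, tissue = "conserved"),
         sharedFraction = shared)
}

#' Fraction of the genome covered by valleys
#'
#' @param dmvs a non-overlapping valley set.
#' @param chromLengths named chromosome lengths.
#' @return Total valley bases divided by total genome bases, in [0, 1].
#' @examples
#' genomeDMVCoverage(GRanges("sc1", IRanges(1, 1000)), c(sc1 = 10000))
#' @export
genomeDMVCoverage <- function(dmvs, chromLengths) {
    gr <- granges(dmvs, use.mcols = FALSE)
    if (!isDisjoint(gr)) stop("valleys must be non-overlapping")
    sum(as.numeric(width(gr))) / sum(as.numeric(chromLengths))
}
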