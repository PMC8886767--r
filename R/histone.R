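## overlap of each peak with the valley union, in bases
.overlapBp <- function(peaks, dmvUnion) {
    ov <- rep(0L, length(peaks))
    hits <- findOverlaps(peaks, dmvUnion, ignore.strand = TRUE)
    if (length(hits)) {
        w <- width(pintersect(peaks[queryHits(hits)],
                              dmvUnion[subjectHits(hits)], ignore.strand = TRUE))
        agg <- rowsum(w, queryHits(hits))
        ov[as.integer(rownames(agg))] <- agg[, 1L]
    }
    ov
}

.peakWithin <- function(peaks, dmvUnion, params) {
    if (params@withinRule == "midpoint") {
        mid <- GRanges(seqnames(peaks),
                       IRanges(start(peaks) + (width(peaks) - 1L) %/% 2L,
                               width = 1L))
        countOverlaps(mid, dmvUnion, ignore.strand = TRUE) > 0L
    } else {
        .overlapBp(peaks, dmvUnion) >= params@minFrac * width(peaks)
    }
}

#' Fraction of peaks lying within the valley union
#'
#' A peak counts as within the valleys when at least \code{minFrac} of its
#' length overlaps the valley union (default rule), or when its midpoint
#' falls inside (\code{withinRule = "midpoint"}).
#'
#' @param peaks a \code{GRanges} of peaks with a \code{mark} column (peaks
#'   without one are pooled under \code{"all"}).
#' @param dmvs a non-overlapping valley set.
#' @param params an \linkS4class{OverlapParams}.
#' @return A named numeric vector of within fractions, one per mark;
#'   \code{NA} for marks with no peaks.
#' @export
peaksWithinDMVFraction <- function(peaks, dmvs, params = OverlapParams()) {
    validObject(params)
    if (length(peaks) == 0L) {
        warning("empty peak set: fraction undefined")
        return(stats::setNames(numeric(0), character(0)))
    }
    dmvUnion <- GenomicRanges::reduce(granges(dmvs, use.mcols = FALSE),
                                      ignore.strand = TRUE)
    within <- .peakWithin(peaks, dmvUnion, params)
    mark <- mcols(peaks)$mark
    if (is.null(mark)) mark <- rep("all", length(peaks))
    tapply(within, mark, mean)[unique(mark)]
}

#' Fraction of genes marked by peaks
#'
#' A gene is marked by a histone mark when any peak of that mark overlaps
#' the gene body extended by \code{geneFlankBp} on both sides by at least
#' 1 bp.
#'
#' @param genes gene models (\code{GRanges} with \code{gene_id}).
#' @param peaks a \code{GRanges} of peaks with a \code{mark} column.
#' @param params an \linkS4class{OverlapParams}.
#' @return A list with \code{perMark} (named fraction per mark),
#'   \code{anyMark} (fraction with >= 1 mark) and \code{markedBy} (logical
#'   genes x marks matrix).
#' @export
markedGeneFraction <- function(genes, peaks, params = OverlapParams()) {
    validObject(params)
    ext <- trim(restrict(genes + params@geneFlankBp, start = 1L))
    marks <- unique(mcols(peaks)$mark)
    markedBy <- vapply(marks, function(mk)
        countOverlaps(ext, peaks[mcols(peaks)$mark == mk],
                      ignore.strand = TRUE) > 0L,
        logical(length(genes)))
    markedBy <- matrix(markedBy, nrow = length(genes),
                       dimnames = list(mcols(genes)$gene_id, marks))
    list(perMark = colMeans(markedBy),
         anyMark = mean(rowSums(markedBy) > 0L),
         markedBy = markedBy)
}

## per-base values of an RleList over [a, b] on one chromosome, zero-padded
## outside the covered range
.baseValues <- function(rle, chrom, a, b) {
    n <- b - a + 1L
    v <- numeric(n)
    if (!chrom %in% names(rle)) return(v)
    r <- rle[[chrom]]
    lo <- max(a, 1L); hi <- min(b, length(r))
    if (lo > hi) return(v)
    v[(lo - a + 1L):(hi - a + 1L)] <- as.numeric(S4Vectors::window(r, lo, hi))
    v
}

## integral of the per-base step function at fractional offsets x in [0, n]
.stepIntegral <- function(vals, x) {
    cum <- c(0, cumsum(vals))
    i <- pmin(floor(x), length(vals))
    cum[i + 1L] + (x - i) * c(vals, 0)[i + 1L]
}

## per-bin means/sums over [a, b] split into nbins equal (fractional) bins
.binValues <- function(vals, nbins, statistic = "mean") {
    n <- length(vals)
    edges <- seq(0, n, length.out = nbins + 1L)
    s <- diff(.stepIntegral(vals, edges))
    if (statistic == "mean") s / (n / nbins) else s
}

.profileBins <- function(vals, flankBp, nFlank, nBody, statistic) {
    n <- length(vals)
    body <- vals[(flankBp + 1L):(n - flankBp)]
    c(.binValues(vals[seq_len(flankBp)], nFlank, statistic),
      .binValues(body, nBody, statistic),
      .binValues(vals[(n - flankBp + 1L):n], nFlank, statistic))
}

#' Meta-region signal profile
#'
#' Averages signal over a region set after rescaling each region body to
#' \code{nBodyBins} bins with \code{profileFlankBp}-bp flanks split into
#' \code{nFlankBins} absolute bins. Three signal modes:
#' \describe{
#'   \item{\code{coverage}}{fraction of each bin covered by the peak union
#'     (0/1 per base).}
#'   \item{\code{score}}{score-weighted peak coverage density.}
#'   \item{\code{methylation}}{weighted methylation level per bin (summed
#'     methylated / total counts of the cytosines in the bin), from a
#'     \linkS4class{CytosineCalls} signal, optionally restricted to one
#'     context via \code{context}.}
#' }
#' Minus-strand regions are flipped so bin 1 is always the 5' flank. With
#' \code{normalization = "max1"} the profile is divided by its maximum
#' (matching the convention of scaling each mark's peak enrichment to 1);
#' an all-zero profile cannot be max-normalized and raises an error
#' suggesting \code{"raw"}.
#'
#' @param signal peak \code{GRanges} (coverage/score modes) or
#'   \linkS4class{CytosineCalls} (methylation mode).
#' @param regions region set (\code{GRanges}/\linkS4class{DMVSet}); strand
#'   honoured.
#' @param params an \linkS4class{OverlapParams}.
#' @param mode signal mode, see Details.
#' @param normalization \code{"max1"} or \code{"raw"}.
#' @param label,regionSet labels stored on the profile.
#' @param context optional single context for methylation mode.
#' @return A \linkS4class{MetaProfile}.
#' @export
metaProfile <- function(signal, regions, params = OverlapParams(),
                        mode = c("coverage", "score", "methylation"),
                        normalization = c("max1", "raw"),
                        label = "signal", regionSet = "regions",
                        context = NULL) {
    mode <- match.arg(mode)
    normalization <- match.arg(normalization)
    validObject(params)
    if (length(regions) == 0L) stop("region set must be non-empty")
    F <- params@profileFlankBp; nf <- params@nFlankBins; nb <- params@nBodyBins
    if (mode == "methylation") {
        if (!is.null(context))
            signal <- signal[as.character(mcols(signal)$context) %in% context]
        methRle <- coverage(signal, weight = as.numeric(mcols(signal)$methylated))
        totRle <- coverage(signal, weight = as.numeric(mcols(signal)$total))
    } else if (mode == "coverage") {
        covRle <- coverage(GenomicRanges::reduce(granges(signal, use.mcols = FALSE),
                                                 ignore.strand = TRUE))
    } else {
        sc <- mcols(signal)$score
        if (is.null(sc) || any(is.na(sc))) stop("score mode needs peak scores")
        covRle <- coverage(signal, weight = as.numeric(sc))
    }
    nbins <- nb + 2L * nf
    acc <- matrix(NA_real_, nrow = length(regions), ncol = nbins)
    for (i in seq_along(regions)) {
        chrom <- as.character(seqnames(regions))[i]
        a <- start(regions)[i] - F; b <- end(regions)[i] + F
        if (mode == "methylation") {
            mv <- .profileBins(.baseValues(methRle, chrom, a, b), F, nf, nb, "sum")
            tv <- .profileBins(.baseValues(totRle, chrom, a, b), F, nf, nb, "sum")
            bins <- ifelse(tv > 0, mv / tv, NA_real_)
        } else {
            bins <- .profileBins(.baseValues(covRle, chrom, a, b), F, nf, nb,
                                 "mean")
        }
        if (as.character(strand(regions))[i] == "-") bins <- rev(bins)
        acc[i, ] <- bins
    }
    values <- colMeans(acc, na.rm = TRUE)
    values[is.nan(values)] <- NA_real_
    if (normalization == "max1") {
        mx <- suppressWarnings(max(values, na.rm = TRUE))
        if (!is.finite(mx) || mx <= 0)
            stop("profile has no signal; use normalization = 'raw'")
        values <- values / mx
    }
    new("MetaProfile", label = label, regionSet = regionSet, values = values,
        nBodyBins = nb, nFlankBins = nf, normalization = normalization)
}

#' Length-matched random control regions
#'
#' Draws one random interval per valley with identical length, placed
#' uniformly in valley-free genome space; used as the background for
#' valley-enrichment profiles.
#'
#' @param dmvs valley set to match.
#' @param chromLengths named chromosome lengths.
#' @param seed integer seed.
#' @param maxTries placement retries per region before failing.
#' @return A \code{GRanges} with the same multiset of widths as \code{dmvs},
#'   none overlapping any valley.
#' @export
randomControlRegions <- function(dmvs, chromLengths, seed, maxTries = 1000L) {
    gr <- GenomicRanges::reduce(granges(dmvs, use.mcols = FALSE),
                                ignore.strand = TRUE)
    genome <- GRanges(names(chromLengths), IRanges(1L, as.integer(chromLengths)))
    free <- suppressWarnings(
        GenomicRanges::setdiff(genome, gr, ignore.strand = TRUE))
    set.seed(as.integer(seed) %% .Machine$integer.max)
    lens <- width(dmvs)
    st <- integer(length(lens)); chr <- character(length(lens))
    for (i in seq_along(lens)) {
        fit <- which(width(free) >= lens[i])
        if (!length(fit))
            stop("no valley-free region can hold a control of length ", lens[i])
        placed <- FALSE
        for (try in seq_len(maxTries)) {
            j <- fit[sample.int(length(fit), 1L, prob = width(free)[fit])]
            s <- start(free)[j] +
                as.integer(stats::runif(1, 0, width(free)[j] - lens[i] + 1L))
            cand <- GRanges(seqnames(free)[j], IRanges(s, width = lens[i]))
            if (countOverlaps(cand, gr, ignore.strand = TRUE) == 0L) {
                st[i] <- s; chr[i] <- as.character(seqnames(free))[j]
                placed <- TRUE; break
            }
        }
        if (!placed) stop("control placement failed after ", maxTries, " tries")
    }
    GRanges(chr, IRanges(st, width = width(dmvs)))
}

#' Fraction of differential peaks within valleys
#'
#' Applies the same within rule as \code{\link{peaksWithinDMVFraction}} to an
#' externally computed differential-peak set (e.g. MAnorm output read
#' through \code{\link{readPeaks}}), pooled and per mark.
#'
#' @param diffPeaks differential peaks (\code{GRanges} with \code{mark}).
#' @param dmvs a valley set.
#' @param params an \linkS4class{OverlapParams}.
#' @return A list with \code{overall} (pooled fraction) and \code{perMark}.
#' @export
differentialPeaksInDMV <- function(diffPeaks, dmvs, params = OverlapParams()) {
    dmvUnion <- GenomicRanges::reduce(granges(dmvs, use.mcols = FALSE),
                                      ignore.strand = TRUE)
    within <- .peakWithin(diffPeaks, dmvUnion, params)
    mark <- mcols(diffPeaks)$mark
    if (is.null(mark)) mark <- rep("all", length(diffPeaks))
    list(overall = mean(within),
         perMark = tapply(within, mark, mean)[unique(mark)])
}

#' Differential-peak coverage of gene sets
#'
#' For each named gene set, counts the genes whose body plus
#' \code{geneFlankBp} flanks overlaps at least one differential peak, per
#' mark and pooled across marks.
#'
#' @param geneSets named list of gene \code{GRanges} (each with
#'   \code{gene_id}).
#' @param diffPeaks differential peaks with a \code{mark} column.
#' @param params an \linkS4class{OverlapParams}.
#' @return A data.frame with columns \code{set}, \code{mark} (including
#'   \code{"any"}), \code{n_genes}, \code{n_marked}, \code{fraction}.
#' @export
geneSetMarkingMatrix <- function(geneSets, diffPeaks,
                                 params = OverlapParams()) {
    if (is.null(names(geneSets))) stop("geneSets must be named")
    rows <- lapply(names(geneSets), function(nm) {
        genes <- geneSets[[nm]]
        if (length(genes) == 0L)
            return(data.frame(set = nm, mark = "any", n_genes = 0L,
                              n_marked = 0L, fraction = NA_real_))
        mk <- markedGeneFraction(genes, diffPeaks, params)
        data.frame(set = nm,
                   mark = c(colnames(mk$markedBy), "any"),
                   n_genes = length(genes),
                   n_marked = c(colSums(mk$markedBy),
                                sum(rowSums(mk$markedBy) > 0L)),
                   fraction = c(colMeans(mk$markedBy), mk$anyMark),
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, rows)
}
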