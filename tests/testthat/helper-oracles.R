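## Independent brute-force oracles, written against plain data frames so they
## share no code path with the package implementation.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

## calls as a plain data.frame
callsToFrame <- function(calls) {
    data.frame(chrom = as.character(seqnames(calls)), pos = start(calls),
               context = as.character(calls$context),
               meth = calls$methylated, total = calls$total,
               stringsAsFactors = FALSE)
}

## Brute-force valley caller on ONE chromosome: enumerate every window
## independently, apply the per-context site filter and the strict <5% rule,
## mark covered bases, and extract maximal runs.
bruteForceDMVs <- function(df, chromLength, windowSize = 1000, step = 200,
                           minCytosines = 5, minCoverage = 5, maxLevel = 0.05) {
    stopifnot(length(unique(df$chrom)) <= 1L)
    nWin <- ceiling(max(chromLength - windowSize, 0) / step) + 1
    covered <- logical(chromLength)
    q <- df[df$total >= minCoverage, ]
    q <- q[order(q$pos), ]
    for (w in seq_len(nWin)) {
        a <- (w - 1) * step + 1
        b <- min(a + windowSize - 1, chromLength)
        lo <- findInterval(a - 1, q$pos) + 1
        hi <- findInterval(b, q$pos)
        inWin <- if (lo > hi) q[0, ] else q[lo:hi, ]
        ok <- TRUE
        for (ctx in c("CG", "CHG", "CHH")) {
            sub <- inWin[inWin$context == ctx, ]
            if (nrow(sub) < minCytosines || sum(sub$total) == 0) { ok <- FALSE; break }
            if (sum(sub$meth) / sum(sub$total) >= maxLevel) { ok <- FALSE; break }
        }
        if (ok) covered[a:b] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    data.frame(start = starts[r$values], end = ends[r$values])
}

## interval-containment oracle for DMV genes: the gene +/- flank must lie
## entirely inside a single valley interval
containmentOracle <- function(geneStart, geneEnd, dmvStart, dmvEnd, flank = 1000) {
    a <- max(geneStart - flank, 1)
    b <- geneEnd + flank
    any(dmvStart <= a & b <= dmvEnd)
}

## textbook Pearson chi-squared statistic on a 2x2 table
chisqOracle <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
}

## per-base coverage fraction of a set of peaks over [a, b], binned with
## integer-aligned bins (used only on cases where bins divide evenly)
coverageBinsOracle <- function(peaks, a, b, nbins) {
    bases <- a:b
    cov <- vapply(bases, function(x)
        any(start(peaks) <= x & end(peaks) >= x), logical(1))
    w <- length(bases) / nbins
    vapply(seq_len(nbins), function(k)
        mean(cov[((k - 1) * w + 1):(k * w)]), numeric(1))
}

## small deterministic cytosine table builder for window-level unit tests:
## nSites per context evenly spaced in [a, b], given per-context summed
## methylated counts spread over the sites
windowCalls <- function(chrom = "sc1", a = 1, b = 1000, nCG = 5, nCHG = 5,
                        nCHH = 5, totalEach = 20, methCG = 0, methCHG = 0,
                        methCHH = 0) {
    mk <- function(n, ctx, methTotal) {
        if (n == 0) return(NULL)
        pos <- round(seq(a, b, length.out = n + 2))[2:(n + 1)]
        meth <- rep(0L, n)
        i <- 1
        while (methTotal > 0) {  # spread counts without exceeding totalEach
            add <- min(methTotal, totalEach)
            meth[i] <- add; methTotal <- methTotal - add; i <- i + 1
        }
        data.frame(pos = pos, ctx = ctx, meth = meth, total = totalEach)
    }
    df <- rbind(mk(nCG, "CG", methCG), mk(nCHG, "CHG", methCHG),
                mk(nCHH, "CHH", methCHH))
    CytosineCalls(chrom, df$pos, "+", df$ctx, df$meth, df$total)
}

## binomial 99% interval around rate p at sample size n
binom99 <- function(p, n) {
    z <- qnorm(0.995)
    c(p - z * sqrt(p * (1 - p) / n), p + z * sqrt(p * (1 - p) / n))
}

jaccardBp <- function(a, b) {
    a <- reduce(granges(a), ignore.strand = TRUE)
    b <- reduce(granges(b), ignore.strand = TRUE)
    i <- sum(width(GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
    u <- sum(width(GenomicRanges::union(a, b, ignore.strand = TRUE)))
    i / u
}
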