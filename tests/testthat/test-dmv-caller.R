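test_that("window tiling matches the closed-form count and truncates the tail", {
    p <- DMVParams()
    w <- tileWindows(c(sc1 = 1000), p)
    expect_equal(length(w), 1L)
    expect_equal(c(start(w), end(w)), c(1L, 1000L))

    w <- tileWindows(c(sc1 = 1400), p)
    expect_equal(start(w), c(1L, 201L, 401L))
    expect_equal(end(w), c(1000L, 1200L, 1400L))

    w <- tileWindows(c(sc1 = 1500), p)
    expect_equal(length(w), 4L)  # starts 0,200,400,600; last truncated
    expect_equal(end(w)[4], 1500L)
    expect_equal(start(w)[4], 601L)

    for (L in c(999, 1001, 5000, 12345)) {
        w <- tileWindows(c(sc1 = L), p)
        expect_equal(length(w), ceiling(max(L - 1000, 0) / 200) + 1)
        expect_true(all(end(w) <= L))
    }
})

test_that("window statistics apply the per-context site and coverage filters", {
    ## 5 CG sites at >=5x, all unmethylated; CHG/CHH also qualifying
    calls <- windowCalls(totalEach = 10, methCG = 0)
    st <- windowStats(calls, c(sc1 = 1000))
    expect_true(mcols(st)$considered)
    expect_equal(mcols(st)$level_CG, 0)

    ## 4 qualifying CHH sites: never considered regardless of levels
    calls <- windowCalls(nCHH = 4)
    st <- windowStats(calls, c(sc1 = 1000))
    expect_false(mcols(st)$considered)

    ## sites below the coverage floor do not count as qualifying
    calls <- windowCalls(totalEach = 4)
    st <- windowStats(calls, c(sc1 = 1000))
    expect_false(mcols(st)$considered)
    expect_equal(mcols(st)$nSites_CG, 0L)

    ## weighted level is the ratio of summed counts: (3+1)/(10+10+3*10)
    calls <- CytosineCalls("sc1", c(10, 20, 30, 40, 50, 101:105, 201:205),
                           "+", rep(c("CG", "CHG", "CHH"), each = 5),
                           c(3L, 1L, 0L, 0L, 0L, rep(0L, 10)), rep(10L, 15))
    st <- windowStats(calls, c(sc1 = 1000))
    expect_equal(mcols(st)$level_CG, 4 / 50)
})

test_that("the valley threshold is strict and required in all three contexts", {
    p <- DMVParams()
    mkStats <- function(cg, chg, chh, considered = TRUE) {
        gr <- GRanges("sc1", IRanges(1, 1000))
        mcols(gr) <- S4Vectors::DataFrame(
            nSites_CG = 5L, meth_CG = 0L, total_CG = 100L, level_CG = cg,
            nSites_CHG = 5L, meth_CHG = 0L, total_CHG = 100L, level_CHG = chg,
            nSites_CHH = 5L, meth_CHH = 0L, total_CHH = 100L, level_CHH = chh,
            considered = considered)
        gr
    }
    expect_true(mcols(callDMVWindows(mkStats(0.04, 0.04, 0.04), p))$qualifies)
    expect_false(mcols(callDMVWindows(mkStats(0.06, 0.01, 0.01), p))$qualifies)
    expect_false(mcols(callDMVWindows(mkStats(0.05, 0.00, 0.00), p))$qualifies)
    expect_false(mcols(callDMVWindows(mkStats(0.01, 0.01, 0.01, FALSE), p))$qualifies)
})

test_that("merging unions overlapping and book-ended windows, recomputing levels", {
    calls <- CytosineCalls("sc1", seq(1, 1200, by = 40), "+",
                           rep(c("CG", "CHG", "CHH"), 10),
                           rep(0L, 30), rep(10L, 30))
    qual <- GRanges("sc1", IRanges(c(1, 201), width = 1000), qualifies = TRUE)
    dmv <- mergeDMVWindows(qual, calls)
    expect_equal(c(start(dmv), end(dmv)), c(1L, 1200L))
    expect_equal(dmv$nWindows, 2L)
    expect_equal(dmv$mCG, 0)

    qual <- GRanges("sc1", IRanges(c(1, 2001), width = 1000), qualifies = TRUE)
    dmv <- mergeDMVWindows(qual, calls)
    expect_equal(length(dmv), 2L)

    ## book-ended truncated windows merge too
    qual <- GRanges("sc1", IRanges(c(1, 1001), width = c(1000, 200)),
                    qualifies = TRUE)
    dmv <- mergeDMVWindows(qual, calls)
    expect_equal(length(dmv), 1L)
    expect_equal(end(dmv), 1200L)
})

test_that("caller equals the brute-force per-window union oracle on random genomes", {
    for (seed in 1:3) {
        plan <- defaultSimulationPlan(seed = seed,
                                      chromLengths = c(sc1 = 100000L),
                                      nPlantedDMVs = 3)
        calls <- simulateMethylome(plan, "leaf")
        got <- callDMVs(calls, tissue = "leaf")
        exp <- bruteForceDMVs(callsToFrame(calls), 100000)
        expect_equal(start(got), exp$start)
        expect_equal(end(got), exp$end)
    }
})

test_that("lower thresholds and stricter coverage shrink the call set monotonically", {
    plan <- defaultSimulationPlan(seed = 5, chromLengths = c(sc1 = 150000L),
                                  nPlantedDMVs = 3)
    calls <- simulateMethylome(plan, "root")
    base <- callDMVs(calls, params = DMVParams(maxLevel = 0.05), tissue = "t")
    tight <- callDMVs(calls, params = DMVParams(maxLevel = 0.02), tissue = "t")
    expect_lte(sum(width(tight)), sum(width(base)))

    stLoose <- windowStats(calls, c(sc1 = 150000L), DMVParams(minCoverage = 5))
    stStrict <- windowStats(calls, c(sc1 = 150000L), DMVParams(minCoverage = 15))
    expect_lte(sum(mcols(stStrict)$considered), sum(mcols(stLoose)$considered))
})

test_that("conserved set is the cross-tissue intersection with min run length", {
    mk <- function(...) DMVSet(GRanges("sc1", IRanges(...)), tissue = "x")
    ## identical valleys: conserved identical, shared fraction 1
    res <- conservedDMVs(list(a = mk(1, 1200), b = mk(1, 1200)))
    expect_equal(c(start(res$conserved), end(res$conserved)), c(1L, 1200L))
    expect_equal(unname(res$sharedFraction), c(1, 1))

    ## disjoint: empty conserved set, shared fractions 0
    res <- conservedDMVs(list(a = mk(1, 1200), b = mk(3001, 4000)))
    expect_equal(length(res$conserved), 0L)
    expect_equal(unname(res$sharedFraction), c(0, 0))

    ## partial overlap: per-base intersection kept when >= windowSize
    res <- conservedDMVs(list(a = mk(1, 2000), b = mk(501, 2500)))
    expect_equal(c(start(res$conserved), end(res$conserved)), c(501L, 2000L))

    ## intersections shorter than one window are discarded
    res <- conservedDMVs(list(a = mk(1, 2000), b = mk(1500, 2500)))
    expect_equal(length(res$conserved), 0L)

    expect_error(conservedDMVs(list(a = mk(1, 1200))), ">= 2 tissues")
})

test_that("genome coverage fraction is total valley bases over genome size", {
    expect_equal(genomeDMVCoverage(GRanges("sc1", IRanges(1, 1000)),
                                   c(sc1 = 10000)), 0.1)
    expect_equal(genomeDMVCoverage(GRanges(), c(sc1 = 10000)), 0)
    ## precomputed genome totals reproduce the headline fraction
    expect_equal(round(genomeDMVCoverage(GRanges("g", IRanges(1, 115e6)),
                                         c(g = 350e6)), 4), 0.3286)
    expect_error(genomeDMVCoverage(GRanges("sc1", IRanges(c(1, 500), width = 600)),
                                   c(sc1 = 10000)), "non-overlapping")
})
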