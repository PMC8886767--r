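test_that("within-valley rule counts majority overlap, configurable to midpoint", {
    dmvs <- GRanges("sc1", IRanges(1001, 3000))
    peaks <- GRanges("sc1", IRanges(c(1500, 2901, 901, 5000), width = 1000),
                     mark = "H3K4me3")
    ## overlaps: full, 100/1000 = 10%, 2000/1000? no: [901,1900] -> 900/1000
    frac <- peaksWithinDMVFraction(peaks, dmvs)
    expect_equal(unname(frac["H3K4me3"]), 2 / 4)  # full + 90%, not 10% or 0%
    midRule <- OverlapParams(withinRule = "midpoint")
    fracMid <- peaksWithinDMVFraction(peaks, dmvs, midRule)
    expect_equal(unname(fracMid["H3K4me3"]), 2 / 4)
    expect_warning(peaksWithinDMVFraction(GRanges(), dmvs), "empty")
})

test_that("within fraction is monotone non-increasing in the overlap threshold", {
    set.seed(22)
    dmvs <- reduce(GRanges("sc1", IRanges(sort(sample.int(200000, 20)),
                                          width = 3000)))
    peaks <- GRanges("sc1", IRanges(sample.int(200000, 300), width = 800),
                     mark = "m")
    fr <- vapply(c(0.1, 0.3, 0.5, 0.8, 1),
                 function(f) unname(peaksWithinDMVFraction(
                     peaks, dmvs, OverlapParams(minFrac = f))["m"]),
                 numeric(1))
    expect_true(all(diff(fr) <= 0))
    expect_true(all(fr >= 0 & fr <= 1))
})

test_that("marked-gene calls use flanked bodies and any-overlap", {
    genes <- GRanges("sc1", IRanges(5001, 7000), strand = "+", gene_id = "g1")
    peakNear <- GRanges("sc1", IRanges(4300, 4600), mark = "H3K4me3")
    peakFar <- GRanges("sc1", IRanges(3300, 3600), mark = "H3K27me3")
    res <- markedGeneFraction(genes, c(peakNear, peakFar))
    expect_equal(unname(res$perMark["H3K4me3"]), 1)  # 500 bp into the flank
    expect_equal(unname(res$perMark["H3K27me3"]), 0) # 1400 bp upstream of flank
    expect_equal(res$anyMark, 1)
})

test_that("marked-gene fractions match the all-pairs overlap oracle", {
    set.seed(23)
    genes <- GRanges("sc1", IRanges(sort(sample.int(100000, 50)), width = 2000),
                     strand = "+", gene_id = sprintf("g%02d", 1:50))
    peaks <- GRanges("sc1", IRanges(sample.int(100000, 80), width = 500),
                     mark = sample(c("A", "B"), 80, TRUE))
    res <- markedGeneFraction(genes, peaks)
    for (mk in c("A", "B")) {
        pk <- peaks[peaks$mark == mk]
        want <- vapply(seq_along(genes), function(i) {
            a <- max(start(genes)[i] - 1000, 1); b <- end(genes)[i] + 1000
            any(start(pk) <= b & end(pk) >= a)
        }, logical(1))
        expect_identical(unname(res$markedBy[, mk]), want)
    }
})

test_that("meta-profiles bin signal with scaled bodies and absolute flanks", {
    params <- OverlapParams(profileFlankBp = 1000, nBodyBins = 40, nFlankBins = 20)
    regions <- GRanges("sc1", IRanges(c(10001, 50001), width = 4000))
    ## peaks covering exactly each body, nothing in flanks
    peaks <- GRanges("sc1", IRanges(c(10001, 50001), width = 4000), mark = "m")
    prof <- metaProfile(peaks, regions, params, normalization = "max1")
    v <- profileValues(prof)
    expect_equal(v[21:60], rep(1, 40))
    expect_equal(v[c(1:20, 61:80)], rep(0, 40))

    ## single region, peak over its left half
    r1 <- GRanges("sc1", IRanges(10001, 14000))
    pLeft <- GRanges("sc1", IRanges(10001, 12000), mark = "m")
    v <- profileValues(metaProfile(pLeft, r1, params, normalization = "max1"))
    expect_equal(v[21:40], rep(1, 20))
    expect_equal(v[41:60], rep(0, 20))
    ## agreement with the per-base binning oracle on the body
    expect_equal(v[21:60], coverageBinsOracle(pLeft, 10001, 14000, 40))

    ## empty signal cannot be max-normalized
    expect_error(metaProfile(GRanges("sc1", IRanges(1, 10), mark = "m"),
                             GRanges("sc2", IRanges(1, 4000)),
                             params, normalization = "max1"), "raw")
})

test_that("minus-strand regions are flipped to 5'->3'", {
    params <- OverlapParams(nBodyBins = 10, nFlankBins = 5)
    rMinus <- GRanges("sc1", IRanges(10001, 12000), strand = "-")
    ## peak at the RIGHT end of the region = the 5' end on the minus strand
    pk <- GRanges("sc1", IRanges(11801, 12000), mark = "m")
    v <- profileValues(metaProfile(pk, rMinus, params, normalization = "max1"))
    expect_equal(v[6], 1)   # first body bin
    expect_equal(v[15], 0)  # last body bin
})

test_that("methylation-mode profiles recover planted valley shape", {
    plan <- defaultSimulationPlan(seed = 24, chromLengths = c(sc1 = 300000L),
                                  nPlantedDMVs = 4)
    calls <- simulateMethylome(plan, "leaf")
    params <- OverlapParams(profileFlankBp = 2000)
    prof <- metaProfile(calls, plan@plantedDMVs, params, mode = "methylation",
                        normalization = "raw", context = "CG")
    v <- profileValues(prof)
    body <- v[21:60]; flank <- v[c(1:10, 71:80)]  # outer flank halves
    expect_lt(max(body, na.rm = TRUE), 0.05)
    expect_gt(min(flank, na.rm = TRUE), 0.5)
})

test_that("random controls preserve lengths and avoid valleys", {
    set.seed(25)
    dmvs <- reduce(GRanges("sc1", IRanges(sort(sample.int(400000, 10)),
                                          width = sample(2000:6000, 10, TRUE))))
    ctrl <- randomControlRegions(dmvs, c(sc1 = 500000), seed = 7)
    expect_equal(sort(width(ctrl)), sort(width(dmvs)))
    expect_equal(sum(countOverlaps(ctrl, dmvs, ignore.strand = TRUE)), 0L)
    ## deterministic given the seed
    ctrl2 <- randomControlRegions(dmvs, c(sc1 = 500000), seed = 7)
    expect_identical(start(sort(ctrl)), start(sort(ctrl2)))
})

test_that("valley-coupled peaks enrich valley profiles over matched controls", {
    plan <- defaultSimulationPlan(seed = 26, chromLengths = c(sc1 = 1000000L),
                                  nPlantedDMVs = 10)
    plan@peakPlan <- data.frame(mark = "H3K27ac", n = 500L, minLen = 500L,
                                maxLen = 1500L, pInDMV = 0.9)
    dmvs <- plan@plantedDMVs
    peaks <- simulatePeaks(plan, dmvs)
    overD <- mean(profileValues(metaProfile(peaks, dmvs, normalization = "raw")))
    ctrl <- randomControlRegions(dmvs, plan@chromLengths, seed = 3)
    overC <- mean(profileValues(metaProfile(peaks, ctrl, normalization = "raw")))
    expect_gt(overD, overC)
})

test_that("differential-peak fractions and gene-set marking are exact on planted layouts", {
    dmvs <- GRanges("sc1", IRanges(c(10001, 30001), width = 5000))
    inside <- GRanges("sc1", IRanges(c(11001, 31001), width = 1000),
                      mark = c("H3K27ac", "H3K27me3"))
    outside <- GRanges("sc1", IRanges(50001, width = 1000), mark = "H3K27ac")
    expect_equal(differentialPeaksInDMV(inside, dmvs)$overall, 1)
    expect_equal(differentialPeaksInDMV(outside, dmvs)$overall, 0)

    sets <- list(
        seedSpecific = GRanges("sc1", IRanges(c(11001, 31001), width = 500),
                               strand = "+", gene_id = c("s1", "s2")),
        constitutive = GRanges("sc1", IRanges(70001, width = 500),
                               strand = "+", gene_id = "c1"))
    tab <- geneSetMarkingMatrix(sets, inside)
    seedAny <- tab[tab$set == "seedSpecific" & tab$mark == "any", ]
    expect_equal(seedAny$fraction, 1)
    constAny <- tab[tab$set == "constitutive" & tab$mark == "any", ]
    expect_equal(constAny$n_marked, 0L)
})
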