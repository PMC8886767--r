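genesFixture <- function() {
    GRanges("sc1", IRanges(c(2001, 20001, 40001), width = c(2000, 3000, 2000)),
            strand = c("+", "-", "+"),
            gene_id = c("gA", "gB", "gC"))
}

test_that("valley categories follow the genic > promoter > downstream > distal precedence", {
    genes <- genesFixture()
    dmvs <- GRanges("sc1", IRanges(
        c(2101, 501, 4201, 30001, 19001),
        width = c(800, 1000, 900, 2000, 800)))
    ann <- classifyDMVs(dmvs, genes)
    byStart <- ann[order(ann$start), ]
    ## [501,1500] overlaps gA's upstream 2k window -> promoter
    ## [2101,2900] inside gA -> genic; [4201,5100] downstream of + gA
    ## [19001,19800] downstream of - gB (upstream is to the right)
    ## [30001,32000] gap to gB end (23000) is 7000 -> distal
    expect_equal(byStart$category,
                 c("promoter", "genic", "downstream", "downstream", "distal"))
    expect_equal(byStart$distance_bp[byStart$category == "distal"], 7000)
    expect_equal(byStart$nearest_gene[byStart$category == "distal"], "gB")
    ## partition: every valley exactly one category
    expect_equal(nrow(ann), length(dmvs))
    expect_equal(sum(table(ann$category)), length(dmvs))
})

test_that("promoter windows are strand-aware", {
    ## - strand gene: upstream lies to the right of the gene
    genes <- GRanges("sc1", IRanges(10001, 12000), strand = "-", gene_id = "gM")
    dmv <- GRanges("sc1", IRanges(12101, 12500))
    ann <- classifyDMVs(dmv, genes)
    expect_equal(ann$category, "promoter")
    expect_true("gM" %in% promoterDMVGenes(genes, dmv))
    dmvLeft <- GRanges("sc1", IRanges(9001, 9500))
    expect_equal(classifyDMVs(dmvLeft, genes)$category, "downstream")
})

test_that("gaps shorter than the distal cutoff land in the residual bin", {
    genes <- GRanges("sc1", IRanges(50001, 52000), strand = "+", gene_id = "gX")
    near <- GRanges("sc1", IRanges(45500, 46000))  # gap 4000 -> distal
    expect_equal(classifyDMVs(near, genes)$category, "distal")
    mid <- GRanges("sc1", IRanges(46500, 47500))   # gap 2500, promoter window stops at 48001
    expect_equal(classifyDMVs(mid, genes)$category, "distal")
    ## with a distal cutoff beyond the window reach, in-between gaps fall in
    ## the residual bin
    close <- GRanges("sc1", IRanges(55000, 55400)) # gap 2999
    wideParams <- AnnotationParams(distalMinBp = 3000)
    expect_message(ann <- classifyDMVs(close, genes, wideParams), "proximal")
    expect_equal(ann$category, "proximal_unclassified")
})

test_that("DMV genes require full containment of the flanked gene body", {
    genes <- GRanges("sc1", IRanges(5001, 7000), strand = "+", gene_id = "g1")
    res <- callDMVGenes(genes, GRanges("sc1", IRanges(3901, 8100)))
    expect_true(res$is_dmv_gene)
    expect_equal(res$covering_dmv, "DMV_1")
    ## a valley exactly the gene body leaves the flanks uncovered
    res <- callDMVGenes(genes, GRanges("sc1", IRanges(5001, 7000)))
    expect_false(res$is_dmv_gene)
    ## flanks clipped at the chromosome start still count as contained
    gStart <- GRanges("sc1", IRanges(500, 1500), strand = "+", gene_id = "g2")
    res <- callDMVGenes(gStart, GRanges("sc1", IRanges(1, 2600)))
    expect_true(res$is_dmv_gene)
})

test_that("DMV-gene calls match the interval-containment oracle on random layouts", {
    set.seed(21)
    for (rep in 1:3) {
        nG <- 160
        gs <- sort(sample.int(400000, nG))
        genes <- GRanges("sc1", IRanges(gs, width = sample(500:4000, nG, TRUE)),
                         strand = sample(c("+", "-"), nG, TRUE),
                         gene_id = sprintf("g%03d", seq_len(nG)))
        ds <- sort(sample.int(400000, 40))
        dmvs <- reduce(GRanges("sc1", IRanges(ds, width = sample(1000:8000, 40, TRUE))))
        got <- callDMVGenes(genes, dmvs)$is_dmv_gene
        want <- vapply(seq_len(nG), function(i)
            containmentOracle(start(genes)[i], end(genes)[i],
                              start(dmvs), end(dmvs)), logical(1))
        expect_identical(got, want)
        ## containment implies body overlap (weaker necessary condition)
        expect_true(all(countOverlaps(genes[got], dmvs,
                                      ignore.strand = TRUE) > 0))
    }
})

test_that("promoter-DMV genes exclude DMV genes and honour strand", {
    genes <- GRanges("sc1", IRanges(c(10001, 30001), width = 2000),
                     strand = c("+", "-"), gene_id = c("gP", "gQ"))
    dmvs <- GRanges("sc1", IRanges(c(8501, 32101, 29001), width = c(1000, 500, 4200)))
    ## gQ (- strand): upstream window 32001-34000 overlapped AND gQ +-1k inside
    ## [29001,33200]? gQ ext = 29001..33000, valley 29001-33200 contains it ->
    ## gQ is a DMV gene, so only gP qualifies as promoter-DMV gene
    dmvs <- reduce(dmvs)
    prom <- promoterDMVGenes(genes, dmvs)
    calls <- callDMVGenes(genes, dmvs)
    expect_true(calls$is_dmv_gene[calls$gene_id == "gQ"])
    expect_equal(prom, "gP")
    expect_length(intersect(prom, calls$gene_id[calls$is_dmv_gene]), 0)
})

test_that("distal pairs use the deterministic nearest-gene tie rule", {
    genes <- GRanges("sc1", IRanges(c(1, 20001), width = 2000),
                     strand = "+", gene_id = c("gLeft", "gRight"))
    ## valley midway: gaps both 6999 bp
    dmv <- GRanges("sc1", IRanges(9000, 13001))
    pairs <- distalDMVGenePairs(dmv, genes)
    expect_equal(pairs$nearest_gene, "gLeft")  # smaller start wins the tie
    expect_equal(pairs$distance_bp, 6999)

    ## no gene on the valley's chromosome: dropped with a message
    dmv2 <- GRanges("sc9", IRanges(1000, 3000))
    expect_message(p2 <- distalDMVGenePairs(dmv2, genes), "dropped")
    expect_equal(nrow(p2), 0L)
})

test_that("distal valleys never approach a gene closer than the cutoff", {
    set.seed(31)
    gs <- sort(sample.int(300000, 60))
    genes <- GRanges("sc1", IRanges(gs, width = 1500), strand = "+",
                     gene_id = sprintf("g%02d", 1:60))
    ds <- sort(sample.int(300000, 50))
    dmvs <- reduce(GRanges("sc1", IRanges(ds, width = 1200)))
    ann <- classifyDMVs(dmvs, genes)
    distal <- ann[ann$category == "distal", ]
    if (nrow(distal)) {
        expect_true(all(distal$distance_bp >= 2000))
        ## exhaustive all-pairs check of the reported nearest distance
        for (i in seq_len(nrow(distal))) {
            ## bases strictly between valley edge and gene-body edge
            gaps <- pmax(pmax(start(genes) - distal$end[i] - 1,
                              distal$start[i] - end(genes) - 1), 0)
            expect_equal(distal$distance_bp[i], min(gaps))
        }
    }
    expect_equal(sum(table(ann$category)), length(dmvs))
})
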