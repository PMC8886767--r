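#' Default simulation plan
#'
#' Builds the study-shaped synthetic setting: a 2-Mb genome in two scaffolds
#' with plant-like cytosine densities (CG 0.04, CHG 0.04, CHH 0.12 per bp),
#' high-background methylation differing by context (mCG 0.80 >> mCHG 0.40 >>
#' mCHH 0.10), 20 planted near-zero valleys of 2-10 kb shared across five
#' tissues (leaf, root, embryo and two endosperm stages, matching a typical
#' WGBS design), Poisson coverage with mean 20, a 16-tissue FPKM atlas of
#' 2000 genes with 200 planted single-tissue-specific genes (on-FPKM 50,
#' off-FPKM 0.1, log-normal noise sd 0.2), gene models placed inside and
#' outside the valleys, and five histone-mark peak sets coupled to valleys
#' with per-mark probabilities in the 0.87-0.97 range.
#'
#' Planted-valley positions, gene placements and specific-gene targets are
#' drawn deterministically from \code{seed}, so two calls with the same seed
#' return identical plans.
#'
#' @param seed integer seed driving the whole simulation.
#' @param nPlantedDMVs number of planted valleys.
#' @param chromLengths named integer vector of chromosome lengths.
#' @param coverageLambda mean read depth.
#' @param tissues methylome tissue labels.
#' @return A validated \linkS4class{SimulationPlan}.
#' @examples
#' plan <- defaultSimulationPlan(seed = 1)
#' plan
#' @export
defaultSimulationPlan <- function(seed = 1L, nPlantedDMVs = 20L,
                                  chromLengths = c(sc1 = 1000000L, sc2 = 1000000L),
                                  coverageLambda = 20,
                                  tissues = c("leaf", "root", "embryo",
                                              "endosperm35", "endosperm20")) {
    seed <- as.integer(seed)
    set.seed(seed)
    chromLengths <- stats::setNames(as.integer(chromLengths), names(chromLengths))
    ## planted valleys: lengths 2-10 kb, laid out on a jittered grid so they
    ## never overlap and keep >= 10 kb of background between them
    nchr <- length(chromLengths)
    si <- Seqinfo(names(chromLengths), seqlengths = unname(chromLengths))
    perChrom <- diff(round(seq(0, nPlantedDMVs, length.out = nchr + 1L)))
    pd <- GRanges(seqinfo = si)
    for (i in seq_len(nchr)) {
        n <- perChrom[i]
        if (n == 0L) next
        L <- chromLengths[i]
        slot <- L %/% (n + 1L)
        len <- as.integer(round(stats::runif(n, 2000, 10000)))
        maxoff <- pmax(1L, slot - len - 10000L)
        off <- as.integer(stats::runif(n, 0, maxoff))
        st <- as.integer(seq_len(n) - 1L) * slot + off + 5000L
        pd <- c(pd, GRanges(factor(rep(names(chromLengths)[i], n),
                                   levels = names(chromLengths)),
                            IRanges(st, width = len), level = 0.01,
                            seqinfo = si))
    }
    ## gene models: one gene inside each valley wide enough to hold a gene
    ## plus its 1-kb flanks, and background genes in valley-free space
    genes <- NULL
    wide <- pd[width(pd) >= 4000L]
    if (length(wide)) {
        gst <- start(wide) + 1500L
        gen <- pmin(end(wide) - 1500L, gst + 4000L)
        genes <- GRanges(seqnames(wide), IRanges(gst, gen),
                         strand = sample(c("+", "-"), length(wide), TRUE),
                         gene_id = sprintf("dmvg%03d", seq_along(wide)),
                         placement = "inside_dmv", seqinfo = si)
    }
    avoid <- GenomicRanges::reduce(trim(suppressWarnings(pd + 4000L)))
    genome <- GRanges(names(chromLengths), IRanges(1L, chromLengths),
                      seqinfo = si)
    free <- GenomicRanges::setdiff(genome, avoid, ignore.strand = TRUE)
    free <- free[width(free) >= 6000L]
    nbg <- 80L
    pick <- sample(seq_along(free), nbg, replace = TRUE, prob = width(free))
    bst <- start(free)[pick] +
        as.integer(stats::runif(nbg, 1000, width(free)[pick] - 3000))
    bg <- GRanges(seqnames(free)[pick], IRanges(bst, width = 2000L),
                  strand = sample(c("+", "-"), nbg, TRUE),
                  gene_id = sprintf("bgg%03d", seq_len(nbg)),
                  placement = "outside_dmv", seqinfo = si)
    genes <- sort(if (is.null(genes)) bg else c(genes, bg),
                  ignore.strand = TRUE)

    exprTissues <- c("leaf", "root", "stem", "inflorescence", "flower",
                     "capsule", "pollen", "ovule", "germinating_seed",
                     "embryo", "endosperm", "seed1", "seed2", "seed3",
                     "seed4", "seed5")
    nSpecific <- 200L
    sgp <- data.frame(
        geneId = sprintf("tsg%04d", seq_len(nSpecific)),
        tissue = exprTissues[(seq_len(nSpecific) - 1L) %% length(exprTissues) + 1L],
        onFpkm = 50, offFpkm = 0.1, stringsAsFactors = FALSE)
    peakPlan <- data.frame(
        mark = c("H3K4me3", "H3K27ac", "H3K9ac", "H3K36me3", "H3K27me3"),
        n = 400L, minLen = 500L, maxLen = 1500L,
        pInDMV = c(0.97, 0.95, 0.90, 0.87, 0.89), stringsAsFactors = FALSE)

    new("SimulationPlan", seed = seed, chromLengths = chromLengths,
        cytosineDensity = c(CG = 0.04, CHG = 0.04, CHH = 0.12),
        coverageLambda = as.numeric(coverageLambda),
        backgroundMethylation = c(CG = 0.80, CHG = 0.40, CHH = 0.10),
        methylationDispersion = 50, plantedDMVs = pd, plantedGenes = genes,
        tissues = tissues, exprTissues = exprTissues,
        nBackgroundGenes = 1800L, specificGenePlan = sgp,
        exprNoiseSd = 0.2, peakPlan = peakPlan)
}

## cytosine positions are a property of the genome, not the tissue: drawn
## once from the plan seed so all tissues share them exactly
.simulatePositions <- function(plan) {
    set.seed(plan@seed)
    chroms <- names(plan@chromLengths)
    si <- Seqinfo(chroms, seqlengths = unname(plan@chromLengths))
    out <- vector("list", length(chroms))
    for (i in seq_along(chroms)) {
        L <- plan@chromLengths[i]
        dens <- plan@cytosineDensity[.CONTEXTS]
        nTot <- as.integer(round(L * sum(dens)))
        pos <- sort(sample.int(L, nTot))
        cnt <- floor(nTot * dens / sum(dens))
        cnt[3L] <- cnt[3L] + (nTot - sum(cnt))
        ctx <- sample(rep(factor(.CONTEXTS, levels = .CONTEXTS), times = cnt))
        str <- sample(c("+", "-"), nTot, TRUE)
        out[[i]] <- GRanges(factor(rep(chroms[i], nTot), levels = chroms),
                            IRanges(pos, width = 1L), strand = str,
                            context = ctx, seqinfo = si)
    }
    do.call(c, out)
}

.rbetaMean <- function(n, mu, conc) {
    p <- numeric(n)
    pos <- mu > 0 & mu < 1
    p[pos] <- stats::rbeta(sum(pos), mu[pos] * conc, (1 - mu[pos]) * conc)
    p[mu >= 1] <- 1
    p  # mu == 0 stays exactly 0
}

#' Simulate a per-tissue bisulfite methylome
#'
#' Cytosine positions are drawn once per plan and shared across tissues.
#' Each cytosine's true methylation level comes from a beta distribution
#' centred on the regional mean -- the per-context background, or the planted
#' level inside a planted valley -- with concentration
#' \code{methylationDispersion}; read coverage is Poisson with mean
#' \code{coverageLambda} and the methylated count is binomial. Per-tissue
#' randomness uses a sub-stream derived from the plan seed and the tissue
#' index, so each tissue is reproducible in isolation while planted valleys
#' stay identical across tissues.
#'
#' @param plan a \linkS4class{SimulationPlan}.
#' @param tissue one of \code{plan@tissues}.
#' @return A \linkS4class{CytosineCalls} object with seqlengths set.
#' @export
simulateMethylome <- function(plan, tissue) {
    validObject(plan)
    idx <- match(tissue, plan@tissues)
    if (is.na(idx)) stop("unknown tissue: ", tissue)
    pos <- .simulatePositions(plan)
    n <- length(pos)
    mu <- plan@backgroundMethylation[as.character(pos$context)]
    hit <- findOverlaps(pos, plan@plantedDMVs, ignore.strand = TRUE)
    mu[queryHits(hit)] <- plan@plantedDMVs$level[subjectHits(hit)]
    set.seed((plan@seed + 1009L * idx) %% .Machine$integer.max)
    p <- .rbetaMean(n, mu, plan@methylationDispersion)
    cov <- stats::rpois(n, plan@coverageLambda)
    meth <- stats::rbinom(n, cov, p)
    gr <- granges(pos, use.mcols = FALSE)
    mcols(gr) <- DataFrame(context = pos$context, methylated = as.integer(meth),
                           total = as.integer(cov))
    new("CytosineCalls", gr)
}

#' Simulate a gene-by-tissue FPKM atlas
#'
#' Non-specific genes receive i.i.d. log-normal FPKM across tissues; each
#' planted specific gene receives its on-FPKM in the target tissue and its
#' off-FPKM elsewhere, both under multiplicative log-normal noise
#' (\code{exprNoiseSd} on the log scale). When \code{includeAnnotated} is
#' \code{TRUE} the planted gene models also receive atlas rows: genes placed
#' inside valleys are seed/embryo/endosperm-specific (emulating the coupling
#' between valleys and tissue-specific expression), genes outside valleys get
#' background expression.
#'
#' @param plan a \linkS4class{SimulationPlan}.
#' @param includeAnnotated add rows for \code{plan@plantedGenes}.
#' @return A \code{SummarizedExperiment} with an \code{fpkm} assay and a
#'   logical \code{plantedSpecific} (plus \code{plantedTissue}) rowData.
#' @export
simulateExpression <- function(plan, includeAnnotated = TRUE) {
    validObject(plan)
    set.seed((plan@seed + 104729L) %% .Machine$integer.max)
    tissues <- plan@exprTissues
    nt <- length(tissues)
    sgp <- plan@specificGenePlan
    if (includeAnnotated && length(plan@plantedGenes)) {
        pg <- plan@plantedGenes
        inDMV <- mcols(pg)$placement == "inside_dmv"
        seedTis <- intersect(c("seed1", "seed2", "seed3", "seed4", "seed5",
                               "embryo", "endosperm"), tissues)
        nIn <- sum(inDMV)
        extra <- data.frame(
            geneId = mcols(pg)$gene_id[inDMV],
            tissue = seedTis[(seq_len(nIn) - 1L) %% length(seedTis) + 1L],
            onFpkm = rep(50, nIn), offFpkm = rep(0.1, nIn),
            stringsAsFactors = FALSE)
        sgp <- rbind(sgp, extra)
        bgIds <- c(sprintf("cg%05d", seq_len(plan@nBackgroundGenes)),
                   mcols(pg)$gene_id[!inDMV])
    } else {
        bgIds <- sprintf("cg%05d", seq_len(plan@nBackgroundGenes))
    }
    ns <- nrow(sgp); nb <- length(bgIds)
    noise <- function(n) exp(stats::rnorm(n, 0, plan@exprNoiseSd))
    spec <- matrix(rep(sgp$offFpkm, nt), nrow = ns)
    spec[cbind(seq_len(ns), match(sgp$tissue, tissues))] <- sgp$onFpkm
    spec <- spec * noise(ns * nt)
    ## background genes: a gene-specific baseline (log-normal across genes)
    ## with milder multiplicative tissue noise, so across-gene spread is wide
    ## but no constitutive gene swings by orders of magnitude across tissues
    base <- stats::rlnorm(nb, meanlog = 1, sdlog = 1.5)
    bg <- base * matrix(stats::rlnorm(nb * nt, meanlog = 0, sdlog = 0.6),
                        nrow = nb)
    m <- rbind(spec, bg)
    rownames(m) <- c(sgp$geneId, bgIds)
    colnames(m) <- tissues
    SummarizedExperiment::SummarizedExperiment(
        assays = list(fpkm = m),
        rowData = DataFrame(
            plantedSpecific = c(rep(TRUE, ns), rep(FALSE, nb)),
            plantedTissue = c(sgp$tissue, rep(NA_character_, nb))))
}

#' Simulate valley-coupled histone peak sets
#'
#' Each peak is placed entirely inside a uniformly chosen valley with the
#' mark's coupling probability \code{pInDMV}, and otherwise uniformly in
#' valley-free genome space, so the realized within-valley fraction is
#' binomial around \code{pInDMV}.
#'
#' @param plan a \linkS4class{SimulationPlan}.
#' @param dmvs valley intervals (\code{GRanges} or \linkS4class{DMVSet});
#'   required whenever any \code{pInDMV > 0}.
#' @param tissue tissue label stamped on the peaks.
#' @return A \code{GRanges} with \code{mark}, \code{tissue} and \code{score}
#'   columns.
#' @export
simulatePeaks <- function(plan, dmvs, tissue = "endosperm") {
    validObject(plan)
    pp <- plan@peakPlan
    if (nrow(pp) == 0L) return(GRanges())
    dmvs <- GenomicRanges::reduce(granges(dmvs, use.mcols = FALSE),
                                  ignore.strand = TRUE)
    if (any(pp$pInDMV > 0) && length(dmvs) == 0L)
        stop("pInDMV > 0 requires a non-empty valley set")
    genome <- GRanges(names(plan@chromLengths), IRanges(1L, plan@chromLengths))
    free <- GenomicRanges::setdiff(genome, dmvs, ignore.strand = TRUE)
    set.seed((plan@seed + 224737L) %% .Machine$integer.max)
    out <- vector("list", nrow(pp))
    for (k in seq_len(nrow(pp))) {
        n <- pp$n[k]
        len <- as.integer(round(stats::runif(n, pp$minLen[k], pp$maxLen[k])))
        inDMV <- stats::runif(n) < pp$pInDMV[k]
        st <- integer(n); chr <- character(n)
        for (i in seq_len(n)) {
            pool <- if (inDMV[i]) dmvs else free
            fit <- which(width(pool) >= len[i])
            if (!length(fit))
                stop("no ", if (inDMV[i]) "valley" else "valley-free region",
                     " can hold a peak of length ", len[i])
            j <- fit[sample.int(length(fit), 1L, prob = width(pool)[fit])]
            st[i] <- start(pool)[j] +
                as.integer(stats::runif(1, 0, width(pool)[j] - len[i] + 1L))
            chr[i] <- as.character(seqnames(pool))[j]
        }
        out[[k]] <- GRanges(chr, IRanges(st, width = len), mark = pp$mark[k],
                            tissue = tissue,
                            score = round(stats::runif(n, 1, 100), 2))
    }
    sort(do.call(c, out), ignore.strand = TRUE)
}
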