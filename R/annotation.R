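## gap in bases between two ranges on the same chromosome (0 when touching
## or overlapping), computed edge-to-edge and strand-ignorant
.gapBp <- function(aStart, aEnd, bStart, bEnd) {
    pmax(pmax(bStart - aEnd, aStart - bEnd), 0L)
}

## nearest gene per query with the deterministic tie rule: minimal gap, then
## smaller gene start, then lexicographic gene_id
.nearestGene <- function(query, genes) {
    n <- length(query)
    out <- data.frame(gene_id = rep(NA_character_, n), distance = rep(Inf, n),
                      stringsAsFactors = FALSE)
    if (length(genes) == 0L || n == 0L) return(out)
    gChrom <- as.character(seqnames(genes))
    gStart <- start(genes); gEnd <- end(genes)
    gid <- mcols(genes)$gene_id
    qChrom <- as.character(seqnames(query))
    for (i in seq_len(n)) {
        same <- which(gChrom == qChrom[i])
        if (!length(same)) next
        ## gap counts bases strictly between the edges (0 when overlapping
        ## or book-ended); widening the query by 1 bp per side turns the
        ## edge difference into that convention
        gaps <- .gapBp(start(query)[i] - 1L, end(query)[i] + 1L,
                       gStart[same], gEnd[same])
        best <- same[order(gaps, gStart[same], gid[same])[1L]]
        out$gene_id[i] <- gid[best]
        out$distance[i] <- min(gaps)
    }
    out
}

#' Classify valleys by genomic context
#'
#' Assigns each valley one category with precedence genic > promoter >
#' downstream > distal: genic when it overlaps any gene body; else promoter
#' when it overlaps any gene's strand-aware upstream window; else downstream
#' for the strand-aware downstream window; else distal when the gap to the
#' nearest gene body is at least \code{distalMinBp}. Valleys closer than
#' that but outside all windows fall into a residual
#' \code{proximal_unclassified} bin (counted in a message). Each valley also
#' receives its nearest gene (minimal gap; ties broken by smaller gene start,
#' then gene id) and the gap in bp (0 when overlapping).
#'
#' @param dmvs a \linkS4class{DMVSet} or \code{GRanges}.
#' @param genes gene models with a \code{gene_id} column.
#' @param params an \linkS4class{AnnotationParams}.
#' @return A data.frame with columns \code{dmv_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{category}, \code{nearest_gene},
#'   \code{distance_bp}.
#' @export
classifyDMVs <- function(dmvs, genes, params = AnnotationParams()) {
    validObject(params)
    if (length(genes) == 0L) stop("annotation must be non-empty")
    gr <- granges(dmvs, use.mcols = FALSE)
    upstream <- flank(genes, params@promoterBp, start = TRUE)
    downstream <- flank(genes, params@downstreamBp, start = FALSE)
    upstream <- trim(restrict(upstream, start = 1L))
    downstream <- trim(restrict(downstream, start = 1L))
    ## suppressWarnings: valleys on gene-free chromosomes trigger a benign
    ## Seqinfo-merge notice
    genic <- suppressWarnings(countOverlaps(gr, genes, ignore.strand = TRUE) > 0L)
    inProm <- suppressWarnings(countOverlaps(gr, upstream, ignore.strand = TRUE) > 0L)
    inDown <- suppressWarnings(countOverlaps(gr, downstream, ignore.strand = TRUE) > 0L)
    nn <- .nearestGene(gr, genes)
    category <- ifelse(genic, "genic",
                ifelse(inProm, "promoter",
                ifelse(inDown, "downstream",
                ifelse(nn$distance >= params@distalMinBp, "distal",
                       "proximal_unclassified"))))
    nUncl <- sum(category == "proximal_unclassified")
    if (nUncl > 0L)
        message(nUncl, " valley(s) proximal to a gene but outside all windows")
    data.frame(dmv_id = sprintf("DMV_%d", seq_along(gr)),
               chrom = as.character(seqnames(gr)), start = start(gr),
               end = end(gr), category = category,
               nearest_gene = nn$gene_id,
               distance_bp = ifelse(genic, 0, nn$distance),
               stringsAsFactors = FALSE)
}

#' Call DMV genes
#'
#' A gene is a DMV gene when its body extended by \code{flankBp} on both
#' sides (clipped to chromosome bounds when seqlengths are known) lies
#' entirely within a single merged valley.
#'
#' @param genes gene models with a \code{gene_id} column.
#' @param dmvs a non-overlapping valley set.
#' @param params an \linkS4class{AnnotationParams}.
#' @return A data.frame with columns \code{gene_id}, \code{is_dmv_gene},
#'   \code{covering_dmv} (valley id or NA) and \code{has_promoter_dmv}.
#' @examples
#' genes <- GRanges("sc1", IRanges(5001, 7000), strand = "+", gene_id = "g1")
#' dmvs <- GRanges("sc1", IRanges(3901, 8100))
#' callDMVGenes(genes, dmvs)
#' @export
callDMVGenes <- function(genes, dmvs, params = AnnotationParams()) {
    validObject(params)
    gr <- granges(dmvs, use.mcols = FALSE)
    if (!isDisjoint(gr)) stop("valleys must be non-overlapping")
    ext <- genes + params@flankBp
    ext <- trim(restrict(ext, start = 1L))
    if (!any(is.na(seqlengths(ext)))) ext <- trim(ext)
    hits <- findOverlaps(ext, gr, type = "within", ignore.strand = TRUE)
    isDMVGene <- rep(FALSE, length(genes))
    covering <- rep(NA_character_, length(genes))
    isDMVGene[queryHits(hits)] <- TRUE
    covering[queryHits(hits)] <- sprintf("DMV_%d", subjectHits(hits))
    promSet <- promoterDMVGenes(genes, dmvs, params)
    data.frame(gene_id = mcols(genes)$gene_id, is_dmv_gene = isDMVGene,
               covering_dmv = covering,
               has_promoter_dmv = mcols(genes)$gene_id %in% promSet,
               stringsAsFactors = FALSE)
}

#' Genes with a valley over their promoter
#'
#' Genes that are not DMV genes but whose strand-aware upstream
#' \code{promoterBp} window overlaps at least one valley; disjoint from the
#' DMV-gene set by construction.
#'
#' @inheritParams callDMVGenes
#' @return A character vector of gene ids.
#' @export
promoterDMVGenes <- function(genes, dmvs, params = AnnotationParams()) {
    validObject(params)
    gr <- granges(dmvs, use.mcols = FALSE)
    ext <- trim(restrict(genes + params@flankBp, start = 1L))
    isDMVGene <- countOverlaps(ext, gr, type = "within",
                               ignore.strand = TRUE) > 0L
    prom <- trim(restrict(flank(genes, params@promoterBp, start = TRUE),
                          start = 1L))
    hasProm <- countOverlaps(prom, gr, ignore.strand = TRUE) > 0L
    mcols(genes)$gene_id[hasProm & !isDMVGene]
}

#' Nearest-gene assignment for distal valleys
#'
#' Restricts to valleys classified distal and reports each one's nearest
#' gene under the deterministic tie rule (minimal gap, then smaller gene
#' start, then gene id). Valleys on gene-free chromosomes are dropped with a
#' message.
#'
#' @inheritParams classifyDMVs
#' @return A data.frame with columns \code{dmv_id}, \code{nearest_gene},
#'   \code{distance_bp}.
#' @export
distalDMVGenePairs <- function(dmvs, genes, params = AnnotationParams()) {
    ann <- classifyDMVs(dmvs, genes, params)
    distal <- ann[ann$category == "distal", , drop = FALSE]
    noGene <- !is.finite(distal$distance_bp)
    if (any(noGene))
        message(sum(noGene), " distal valley(s) without a gene on their ",
                "chromosome dropped")
    distal <- distal[!noGene, , drop = FALSE]
    data.frame(dmv_id = distal$dmv_id, nearest_gene = distal$nearest_gene,
               distance_bp = distal$distance_bp, stringsAsFactors = FALSE,
               row.names = NULL)
}
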