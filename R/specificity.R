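#' Expressed genes
#'
#' Genes reaching at least \code{expressedMinFpkm} (default 0.5 FPKM) in at
#' least one tissue.
#'
#' @param expr a \code{SummarizedExperiment} with an \code{fpkm} assay, or an
#'   FPKM matrix (genes x tissues).
#' @param params a \linkS4class{SpecificityParams}.
#' @return A character vector of gene ids.
#' @export
expressedGenes <- function(expr, params = SpecificityParams()) {
    m <- .fpkmMatrix(expr)
    rownames(m)[apply(m, 1L, max) >= params@expressedMinFpkm]
}

#' Expression-level bins per tissue
#'
#' Counts expressed genes per tissue in the bins low [0.5, 5), medium
#' [5, 10), high [10, 100) and very high [100, Inf) FPKM; values below the
#' expressed threshold are not counted.
#'
#' @inheritParams expressedGenes
#' @return An integer matrix, tissues x bins.
#' @export
expressionBins <- function(expr, params = SpecificityParams()) {
    m <- .fpkmMatrix(expr)
    breaks <- c(params@expressedMinFpkm, 5, 10, 100, Inf)
    labs <- c("low", "medium", "high", "very_high")
    out <- t(apply(m, 2L, function(v)
        table(cut(v[v >= params@expressedMinFpkm], breaks = breaks,
                  labels = labs, right = FALSE))))
    storage.mode(out) <- "integer"
    out
}

#' Per-gene z-score normalization across tissues
#'
#' Standardizes each gene's FPKM vector to \code{(x - mean) / sd} with the
#' sample (n-1) standard deviation; genes constant across tissues map to an
#' all-zero vector.
#'
#' @inheritParams expressedGenes
#' @return A numeric matrix of the same shape as the input.
#' @examples
#' zscoreNormalize(matrix(1:3, 1, dimnames = list("g", c("a", "b", "c"))))
#' @export
zscoreNormalize <- function(expr) {
    m <- .fpkmMatrix(expr)
    if (ncol(m) < 2L) stop("z-scores need >= 2 tissues")
    mu <- rowMeans(m)
    sd <- apply(m, 1L, stats::sd)
    z <- (m - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    z
}

#' Shannon entropy of a relative-expression distribution
#'
#' \code{H = -sum(P_i * log2(P_i))} over \code{P_i = X_i / sum(X)}, with
#' \code{0 * log(0)} taken as 0. Zero bits means expression confined to one
#' tissue; \code{log2(n)} bits means perfectly uniform expression. All-zero
#' vectors are undefined and return \code{NA} with a warning.
#'
#' @param x a non-negative FPKM vector, or a genes x tissues matrix (one
#'   entropy per row).
#' @return Entropy in bits (vector input), or a named numeric vector.
#' @examples
#' shannonEntropy(rep(1, 16))  # 4 bits
#' shannonEntropy(c(8, 8, 0))  # 1 bit
#' @export
shannonEntropy <- function(x) {
    if (is.matrix(x)) return(apply(x, 1L, shannonEntropy))
    if (any(x < 0)) stop("FPKM values must be non-negative")
    s <- sum(x)
    if (s == 0) {
        warning("all-zero expression vector: entropy undefined")
        return(NA_real_)
    }
    p <- x[x > 0] / s
    -sum(p * log2(p))
}

#' Call tissue-specific genes
#'
#' Genes with maximum FPKM below \code{expCutoff} (default 2) are omitted
#' from testing. A candidate is called specific when its Shannon entropy is
#' at most \code{entropyMaxBits} (default 2 bits) and its peak z-score is at
#' least \code{zThreshold} (default 2); the peak tissue is the FPKM argmax
#' (ties broken by tissue order).
#'
#' @inheritParams expressedGenes
#' @return A data.frame with columns \code{gene_id}, \code{max_fpkm},
#'   \code{entropy_bits}, \code{peak_tissue}, \code{z_max},
#'   \code{is_candidate}, \code{is_specific}.
#' @export
callTissueSpecific <- function(expr, params = SpecificityParams()) {
    m <- .fpkmMatrix(expr)
    maxF <- apply(m, 1L, max)
    H <- suppressWarnings(shannonEntropy(m))
    z <- zscoreNormalize(m)
    zMax <- apply(z, 1L, max)
    peak <- colnames(m)[apply(m, 1L, which.max)]
    cand <- maxF >= params@expCutoff
    specific <- cand & !is.na(H) & H <= params@entropyMaxBits &
        zMax >= params@zThreshold
    data.frame(gene_id = rownames(m), max_fpkm = maxF, entropy_bits = H,
               peak_tissue = peak, z_max = zMax, is_candidate = cand,
               is_specific = specific, stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Cluster stage profiles of specific genes
#'
#' Agglomerative hierarchical clustering (Euclidean distance, complete
#' linkage) of z-score profiles, cut at \code{nClusters}; cluster labels are
#' reordered by the stage at which each cluster's mean profile peaks, so
#' cluster 1 peaks earliest.
#'
#' @param z a genes x stages matrix of z-scores (e.g. rows of
#'   \code{\link{zscoreNormalize}} restricted to specific genes).
#' @param params a \linkS4class{SpecificityParams} (supplies
#'   \code{nClusters}), or an integer cluster count.
#' @return A list with \code{cluster} (named integer vector) and
#'   \code{profiles} (nClusters x stages matrix of mean z-profiles).
#' @export
clusterStageProfiles <- function(z, params = SpecificityParams()) {
    k <- if (is(params, "SpecificityParams")) params@nClusters
         else as.integer(params)
    if (nrow(z) < k)
        stop("need at least ", k, " genes to form ", k, " clusters")
    hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "complete")
    raw <- stats::cutree(hc, k = k)
    prof <- do.call(rbind, lapply(seq_len(k), function(i)
        colMeans(z[raw == i, , drop = FALSE])))
    ord <- order(apply(prof, 1L, which.max), seq_len(k))
    relabel <- match(seq_len(k), ord)
    cl <- relabel[raw]
    names(cl) <- rownames(z)
    prof <- prof[ord, , drop = FALSE]
    rownames(prof) <- paste0("cluster", seq_len(k))
    list(cluster = cl, profiles = prof)
}

#' Chi-squared enrichment of a gene set within DMV genes
#'
#' Builds the 2x2 table of membership in a gene set (e.g. tissue-specific
#' TFs) against DMV-gene status over a common gene universe and applies the
#' Pearson chi-squared test with 1 df and no continuity correction.
#'
#' @param setGenes gene ids in the focal set.
#' @param dmvGenes gene ids called DMV genes.
#' @param universe all gene ids under consideration.
#' @return A list with \code{table} (2x2 counts), \code{statistic},
#'   \code{p.value} and \code{odds.ratio}.
#' @export
tfDMVEnrichment <- function(setGenes, dmvGenes, universe) {
    universe <- unique(universe)
    if (!all(setGenes %in% universe) || !all(dmvGenes %in% universe))
        stop("setGenes and dmvGenes must be drawn from the universe")
    inSet <- factor(universe %in% setGenes, levels = c(TRUE, FALSE))
    inDMV <- factor(universe %in% dmvGenes, levels = c(TRUE, FALSE))
    tab <- table(set = inSet, dmv = inDMV)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
        stop("chi-squared test undefined: a marginal total is zero")
    ht <- stats::chisq.test(tab, correct = FALSE)
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    list(table = tab, statistic = unname(ht$statistic),
         p.value = ht$p.value, odds.ratio = unname(or))
}
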