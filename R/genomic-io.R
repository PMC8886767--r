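#' Read per-cytosine methylation calls
#'
#' Parses a per-cytosine methylation table into a
#' \linkS4class{CytosineCalls} object. Two dialects are supported:
#' \describe{
#'   \item{\code{cx_report}}{Bismark-style cytosine report: chrom, 1-based
#'     position, strand, methylated count, unmethylated count, context
#'     (total = methylated + unmethylated).}
#'   \item{\code{bedgraph_counts}}{bedGraph-like counts: chrom, 0-based start,
#'     end, methylated count, total count, context, strand.}
#' }
#' Coordinates are normalized to the 1-based convention of
#' \linkS4class{GRanges} at the parse boundary. Records with a context other
#' than CG/CHG/CHH (e.g. CN) are dropped with a message.
#'
#' @param path path to a (possibly gzipped) TSV file.
#' @param dialect input dialect, see Details.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A \linkS4class{CytosineCalls} object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("sc1\t101\t+\t3\t7\tCG", tf)
#' readCytosineReport(tf, "cx_report")
#' @export
readCytosineReport <- function(path, dialect = c("cx_report", "bedgraph_counts"),
                               seqlengths = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    ncol <- if (dialect == "cx_report") 6L else 7L
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            fill = TRUE, colClasses = list(character = 1))
    if (nrow(dt) == 0L)
        return(CytosineCalls(GRanges(context = factor(levels = .CONTEXTS),
                                     methylated = integer(), total = integer())))
    if (ncol(dt) < ncol)
        stop(sprintf("expected %d columns for dialect '%s', found %d",
                     ncol, dialect, ncol(dt)))
    int <- function(x) suppressWarnings(as.integer(x))
    if (dialect == "cx_report") {
        chrom <- dt[[1L]]; pos <- int(dt[[2L]]); str <- dt[[3L]]
        meth <- int(dt[[4L]]); unmeth <- int(dt[[5L]])
        ctx <- dt[[6L]]; total <- meth + unmeth
    } else {
        chrom <- dt[[1L]]; pos <- int(dt[[2L]]) + 1L
        meth <- int(dt[[4L]]); total <- int(dt[[5L]])
        ctx <- dt[[6L]]; str <- dt[[7L]]
    }
    if (any(bad <- (is.na(pos) | is.na(meth) | is.na(total) | is.na(ctx) |
                    is.na(str))))
        stop(sprintf("malformed line %d in %s", which(bad)[1L], path))
    if (dialect == "bedgraph_counts" && any(int(dt[[3L]]) != pos))
        stop("bedgraph_counts records must span a single base (end = start + 1)")
    if (any(bad <- !str %in% c("+", "-")))
        stop(sprintf("malformed line %d: strand '%s'", which(bad)[1L], str[which(bad)[1L]]))
    if (any(bad <- (meth < 0L | total < 0L | meth > total)))
        stop(sprintf("invalid counts at line %d: methylated > total", which(bad)[1L]))
    keep <- ctx %in% .CONTEXTS
    if (!all(keep)) {
        message(sum(!keep), " record(s) with unknown context dropped")
        chrom <- chrom[keep]; pos <- pos[keep]; str <- str[keep]
        ctx <- ctx[keep]; meth <- meth[keep]; total <- total[keep]
    }
    CytosineCalls(chrom, pos, str, ctx, meth, total, seqlengths = seqlengths)
}

#' Write per-cytosine methylation calls
#'
#' Inverse of \code{\link{readCytosineReport}}; round-trips exactly.
#'
#' @param calls a \linkS4class{CytosineCalls} object.
#' @param path output path.
#' @param dialect output dialect (see \code{\link{readCytosineReport}}).
#' @return \code{path}, invisibly.
#' @export
writeCytosineReport <- function(calls, path,
                                dialect = c("cx_report", "bedgraph_counts")) {
    dialect <- match.arg(dialect)
    mc <- mcols(calls)
    if (dialect == "cx_report") {
        dt <- data.table::data.table(
            chrom = as.character(seqnames(calls)), pos = start(calls),
            strand = as.character(strand(calls)), meth = mc$methylated,
            unmeth = mc$total - mc$methylated, context = as.character(mc$context))
    } else {
        dt <- data.table::data.table(
            chrom = as.character(seqnames(calls)), start = start(calls) - 1L,
            end = start(calls), meth = mc$methylated, total = mc$total,
            context = as.character(mc$context),
            strand = as.character(strand(calls)))
    }
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
    invisible(path)
}

.validateBedFrame <- function(dt, path) {
    if (ncol(dt) < 3L) stop("BED file needs at least 3 columns: ", path)
    start0 <- as.integer(dt[[2L]]); end0 <- as.integer(dt[[3L]])
    if (any(is.na(start0)) || any(is.na(end0)))
        stop(sprintf("malformed line %d in %s",
                     which(is.na(start0) | is.na(end0))[1L], path))
    if (any(bad <- (start0 >= end0)))
        stop(sprintf("empty or inverted interval at line %d (start >= end)",
                     which(bad)[1L]))
    if (any(start0 < 0L)) stop("negative coordinates in ", path)
    list(chrom = as.character(dt[[1L]]), start = start0 + 1L, end = end0)
}

#' Read a BED3+ file of intervals
#'
#' Accepts BED3 and upward (0-based half-open coordinates converted to the
#' 1-based \linkS4class{GRanges} convention). Column 4 becomes \code{name},
#' column 5 \code{score}, column 6 the strand; any further columns are kept as
#' numbered metadata columns. Input record order is preserved.
#'
#' @param path path to a BED file.
#' @return A \code{GRanges}.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1))
    if (nrow(dt) == 0L) return(GRanges())
    core <- .validateBedFrame(dt, path)
    str <- if (ncol(dt) >= 6L && all(dt[[6L]] %in% c("+", "-", "."))) {
        ifelse(dt[[6L]] == ".", "*", dt[[6L]])
    } else "*"
    gr <- GRanges(core$chrom, IRanges(core$start, core$end), strand = str)
    if (ncol(dt) >= 4L) mcols(gr)$name <- as.character(dt[[4L]])
    if (ncol(dt) >= 5L) mcols(gr)$score <- suppressWarnings(as.numeric(dt[[5L]]))
    if (ncol(dt) >= 7L)
        for (j in 7:ncol(dt)) mcols(gr)[[paste0("V", j)]] <- dt[[j]]
    gr
}

#' Read ChIP-seq peaks from BED
#'
#' BED6+ where the name column holds the histone-mark label.
#'
#' @param path path to a BED file.
#' @param mark histone-mark label; defaults to the BED name column.
#' @param tissue tissue label attached to every peak.
#' @return A \code{GRanges} with \code{mark}, \code{tissue} and \code{score}
#'   metadata columns.
#' @export
readPeaks <- function(path, mark = NULL, tissue = "NA") {
    gr <- readBed(path)
    mcols(gr)$mark <- if (is.null(mark)) {
        if (is.null(mcols(gr)$name)) stop("no name column and no 'mark' given")
        mcols(gr)$name
    } else rep_len(mark, length(gr))
    if (any(!nzchar(mcols(gr)$mark))) stop("empty mark label")
    mcols(gr)$tissue <- rep_len(tissue, length(gr))
    if (is.null(mcols(gr)$score)) mcols(gr)$score <- NA_real_
    gr
}

#' Read gene models from GFF3 or BED6
#'
#' GFF3 rows of type \code{gene} (1-based inclusive, converted by
#' \code{rtracklayer}) or BED6 rows with the gene id in the name column.
#' Duplicate gene ids are a validation error.
#'
#' @param path annotation file.
#' @param dialect \code{"gff3"} or \code{"bed6"}.
#' @return A \code{GRanges} with a \code{gene_id} metadata column.
#' @export
readAnnotation <- function(path, dialect = c("gff3", "bed6")) {
    dialect <- match.arg(dialect)
    if (dialect == "gff3") {
        gff <- rtracklayer::import(path, format = "gff3")
        genes <- gff[tolower(as.character(gff$type)) == "gene"]
        if (length(genes) == 0L) stop("no 'gene' rows in ", path)
        ids <- as.character(genes$ID)
        if (any(is.na(ids) | !nzchar(ids)))
            stop("gene rows without an ID attribute in ", path)
    } else {
        genes <- readBed(path)
        ids <- mcols(genes)$name
        if (is.null(ids)) stop("bed6 annotation needs a name column")
    }
    if (anyDuplicated(ids))
        stop("duplicate gene ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    out <- granges(genes, use.mcols = FALSE)
    mcols(out)$gene_id <- ids
    out
}

#' Read a gene-by-tissue FPKM matrix
#'
#' TSV with a header of tissue labels and gene ids in the first column.
#' Missing cells, negative values, and duplicated gene or tissue labels are
#' validation errors.
#'
#' @param path TSV path.
#' @return A \linkS4class{SummarizedExperiment} with an \code{fpkm} assay.
#' @export
readExpressionMatrix <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    dt <- data.table::fread(path, header = TRUE, sep = "\t",
                            colClasses = list(character = 1))
    if (ncol(dt) < 2L) stop("expression matrix needs >= 1 tissue column")
    genes <- dt[[1L]]
    if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
    tissues <- colnames(dt)[-1L]
    if (anyDuplicated(tissues)) stop("duplicate tissue labels in ", path)
    m <- as.matrix(dt[, -1L, with = FALSE])
    storage.mode(m) <- "double"
    if (any(is.na(m))) stop("missing or non-numeric FPKM cell in ", path)
    if (any(m < 0)) stop("negative FPKM value in ", path)
    rownames(m) <- genes
    SummarizedExperiment::SummarizedExperiment(assays = list(fpkm = m))
}

#' Write an FPKM matrix as TSV
#'
#' @param se a \code{SummarizedExperiment} with an \code{fpkm} assay, or a
#'   numeric matrix with gene rownames and tissue colnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(se, path) {
    m <- .fpkmMatrix(se)
    dt <- data.table::data.table(gene_id = rownames(m))
    for (j in colnames(m)) dt[[j]] <- m[, j]
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
    invisible(path)
}

.fpkmMatrix <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "fpkm")
    if (!is.matrix(x)) stop("expected a matrix or SummarizedExperiment")
    if (is.null(rownames(x)) || is.null(colnames(x)))
        stop("expression matrix needs gene rownames and tissue colnames")
    x
}

#' Write intervals, peaks or valleys as BED
#'
#' Output is sorted by (chrom, start) and uses 0-based half-open coordinates.
#' A \linkS4class{DMVSet} gains the columns id, nWindows, strand, mCG, mCHG
#' and mCHH (levels formatted to 4 decimals); a plain \code{GRanges} writes
#' BED3/BED6 depending on available \code{name}/\code{score} columns. Files
#' written here round-trip through \code{\link{readBed}} /
#' \code{\link{readDMVBed}}.
#'
#' @param x a \code{GRanges} or \linkS4class{DMVSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(x, path) {
    x <- sort(x, ignore.strand = TRUE)
    if (is(x, "DMVSet")) {
        mc <- mcols(x)
        dt <- data.table::data.table(
            chrom = as.character(seqnames(x)), start = start(x) - 1L,
            end = end(x), id = sprintf("DMV_%d", seq_along(x)),
            nWindows = mc$nWindows, strand = ".",
            mCG = sprintf("%.4f", mc$mCG), mCHG = sprintf("%.4f", mc$mCHG),
            mCHH = sprintf("%.4f", mc$mCHH), tissue = as.character(mc$tissue))
    } else {
        dt <- data.table::data.table(
            chrom = as.character(seqnames(x)), start = start(x) - 1L,
            end = end(x))
        mc <- mcols(x)
        hasName <- !is.null(mc$name) || !is.null(mc$mark) || !is.null(mc$gene_id)
        if (hasName) {
            nm <- if (!is.null(mc$name)) mc$name
                  else if (!is.null(mc$gene_id)) mc$gene_id else mc$mark
            dt$name <- as.character(nm)
            dt$score <- if (!is.null(mc$score)) {
                ifelse(is.na(mc$score), 0, mc$score)
            } else 0
            s <- as.character(strand(x))
            dt$strand <- ifelse(s == "*", ".", s)
        }
    }
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a DMV BED written by \code{\link{writeBed}}
#'
#' @param path path to a valley BED file.
#' @return A \linkS4class{DMVSet}.
#' @export
readDMVBed <- function(path) {
    gr <- readBed(path)
    mc <- mcols(gr)
    if (ncol(mc) < 6L) stop("not a DMV BED (expected 10 columns): ", path)
    DMVSet(granges(gr, use.mcols = FALSE),
           tissue = as.character(mc$V10), nWindows = as.integer(mc$score),
           mCG = as.numeric(mc$V7), mCHG = as.numeric(mc$V8),
           mCHH = as.numeric(mc$V9))
}
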