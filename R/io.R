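# On-disk conventions: every interval file (bedGraph, BED) is 0-based
# half-open, tab-separated, LF-terminated. In memory all coordinates live in
# GRanges (1-based closed, the Bioconductor invariant); the readers and
# writers below do the +/-1 shift so a write-then-read round trip is the
# identity.

.readLinesData <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
    list(lines = lines[keep], lineno = which(keep))
}

.sortByChromPos <- function(gr) {
    gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
    gr
}

#' Read a MethylDackel-style per-CpG methylation bedGraph
#'
#' Expects six tab-separated columns: chrom, start (0-based position of the
#' C), end, percent methylation, methylated read count, unmethylated read
#' count. A leading \code{track} header line is tolerated. The percentage
#' column is ignored; methylation fractions are always recomputed from the
#' two count columns so no rounding from the caller leaks in.
#'
#' CpGs are keyed by position on one strand only: strand merging of the
#' symmetric CpG (the MethylDackel default) is assumed to have happened
#' upstream.
#'
#' @param path path to the bedGraph file
#' @param sampleId sample identifier stored in the \code{sample_id} metadata
#'   column
#' @return a width-1 \code{GRanges}, sorted by (chrom, pos), with integer
#'   metadata columns \code{meth} and \code{unmeth} and a \code{sample_id}
#'   column; zero-coverage records are kept (their fraction is undefined and
#'   they fall to the coverage filter downstream)
#' @seealso \code{\link{writeMethylBedGraph}}, \code{\link{buildMethylMatrix}}
#' @export
readMethylBedGraph <- function(path, sampleId) {
    stopifnot(is.character(sampleId), length(sampleId) == 1L)
    dat <- .readLinesData(path)
    if (!length(dat$lines))
        return(GRanges(meth = integer(), unmeth = integer(),
                       sample_id = character()))
    fields <- strsplit(dat$lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 6L))
        stop("malformed methylation bedGraph line ", dat$lineno[which(nf != 6L)[1L]],
             ": expected 6 tab-separated fields, got ", nf[nf != 6L][1L],
             call. = FALSE)
    m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
    start0 <- suppressWarnings(as.integer(m[, 2L]))
    meth <- suppressWarnings(as.integer(m[, 5L]))
    unmeth <- suppressWarnings(as.integer(m[, 6L]))
    bad <- which(is.na(start0) | is.na(meth) | is.na(unmeth))
    if (length(bad))
        stop("malformed methylation bedGraph line ", dat$lineno[bad[1L]],
             ": non-numeric coordinate or count", call. = FALSE)
    if (any(meth < 0L) || any(unmeth < 0L))
        stop("negative read count on line ",
             dat$lineno[which(meth < 0L | unmeth < 0L)[1L]], call. = FALSE)
    gr <- GRanges(m[, 1L], IRanges(start0 + 1L, width = 1L),
                  meth = meth, unmeth = unmeth, sample_id = sampleId)
    .sortByChromPos(gr)
}

#' @rdname readMethylBedGraph
#' @param x a width-1 \code{GRanges} with \code{meth} and \code{unmeth}
#'   metadata columns
#' @export
writeMethylBedGraph <- function(x, path) {
    stopifnot(is(x, "GRanges"), all(c("meth", "unmeth") %in% names(mcols(x))))
    cov <- mcols(x)$meth + mcols(x)$unmeth
    pct <- ifelse(cov > 0, 100 * mcols(x)$meth / cov, 0)
    writeLines(paste(as.character(seqnames(x)), start(x) - 1L, start(x),
                     format(pct, trim = TRUE, digits = 8L),
                     mcols(x)$meth, mcols(x)$unmeth, sep = "\t"), path)
    invisible(path)
}

#' Per-CpG coverage and methylation fraction
#'
#' @param x a CpG \code{GRanges} as returned by
#'   \code{\link{readMethylBedGraph}}
#' @return \code{cpgCoverage}: integer read totals; \code{cpgFraction}:
#'   methylated fraction, \code{NA} where coverage is zero.
#' @export
cpgCoverage <- function(x) mcols(x)$meth + mcols(x)$unmeth

#' @rdname cpgCoverage
#' @export
cpgFraction <- function(x) {
    cov <- cpgCoverage(x)
    ifelse(cov > 0, mcols(x)$meth / cov, NA_real_)
}

#' Read and write BED interval files
#'
#' BED3/BED6, 0-based half-open on disk. Strand is taken from column 6 when
#' present, else \code{*}; a \code{.} strand maps to \code{*}. Intervals with
#' \code{end <= start} are rejected.
#'
#' @param path file path
#' @return \code{readBedFile}: a \code{GRanges} (with \code{name} and
#'   \code{score} metadata columns when the file has 6 columns)
#' @export
readBedFile <- function(path) {
    dat <- .readLinesData(path)
    if (!length(dat$lines)) return(GRanges())
    fields <- strsplit(dat$lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("malformed BED line ", dat$lineno[which(nf < 3L)[1L]],
             ": fewer than 3 columns", call. = FALSE)
    chrom <- vapply(fields, `[`, "", 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (anyNA(start0) || anyNA(end0))
        stop("malformed BED line ", dat$lineno[which(is.na(start0) | is.na(end0))[1L]],
             ": non-numeric coordinates", call. = FALSE)
    if (any(end0 <= start0))
        stop("invalid BED interval on line ",
             dat$lineno[which(end0 <= start0)[1L]], ": end <= start",
             call. = FALSE)
    std <- rep("*", length(chrom))
    has6 <- nf >= 6L
    std[has6] <- vapply(fields[has6], `[`, "", 6L)
    std[std == "."] <- "*"
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = std)
    if (any(nf >= 4L)) {
        nm <- rep(".", length(chrom))
        nm[nf >= 4L] <- vapply(fields[nf >= 4L], `[`, "", 4L)
        sc <- rep(0, length(chrom))
        sc[nf >= 5L] <- suppressWarnings(
            as.numeric(vapply(fields[nf >= 5L], `[`, "", 5L)))
        mcols(gr)$name <- nm
        mcols(gr)$score <- sc
    }
    gr
}

#' @rdname readBedFile
#' @param x a \code{GRanges}
#' @param extraCols optional data.frame of additional columns appended after
#'   the six BED fields
#' @export
writeBedFile <- function(x, path, extraCols = NULL) {
    stopifnot(is(x, "GRanges"))
    validateIntervals(x)
    nm <- if ("name" %in% names(mcols(x))) mcols(x)$name else rep(".", length(x))
    sc <- if ("score" %in% names(mcols(x))) mcols(x)$score else rep(0, length(x))
    std <- as.character(strand(x))
    std[std == "*"] <- "."
    out <- paste(as.character(seqnames(x)), start(x) - 1L, end(x),
                 nm, sc, std, sep = "\t")
    if (!is.null(extraCols))
        out <- paste(out, do.call(paste, c(unname(as.list(extraCols)),
                                           sep = "\t")), sep = "\t")
    writeLines(out, path)
    invisible(path)
}

#' Validate the shared genomic-interval contract
#'
#' Asserts that every range has positive width (i.e. a non-empty half-open
#' interval on disk), a non-negative 0-based start, and a non-empty
#' chromosome name. All interval-producing code paths funnel through this.
#'
#' @param x a \code{GRanges}
#' @return \code{x}, invisibly; stops on violation
#' @export
validateIntervals <- function(x) {
    stopifnot(is(x, "GRanges"))
    if (length(x) == 0L) return(invisible(x))
    if (any(width(x) < 1L))
        stop("interval contract violated: empty interval (end <= start)",
             call. = FALSE)
    if (any(start(x) < 1L))
        stop("interval contract violated: negative start", call. = FALSE)
    if (any(!nzchar(as.character(seqnames(x)))))
        stop("interval contract violated: empty chromosome name", call. = FALSE)
    invisible(x)
}

.readTsvTable <- function(path, required, what) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    miss <- setdiff(required, colnames(df))
    if (length(miss))
        stop(what, " is missing required column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    df
}

#' Read a differential-expression table
#'
#' Tab-separated with a header naming at least \code{gene_id},
#' \code{fold_change} (tumor vs control, linear scale), \code{p_value} and
#' \code{control_fpkm}. Duplicated gene ids are an error.
#'
#' @param path file path
#' @return a data.frame, one row per gene
#' @export
readExpressionTable <- function(path) {
    df <- .readTsvTable(path, c("gene_id", "fold_change", "p_value",
                                "control_fpkm"), "expression table")
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene_id in expression table: ",
             df$gene_id[anyDuplicated(df$gene_id)], call. = FALSE)
    if (any(df$fold_change <= 0))
        stop("fold_change must be positive (linear scale)", call. = FALSE)
    if (any(df$p_value < 0 | df$p_value > 1))
        stop("p_value outside [0, 1]", call. = FALSE)
    if (any(df$control_fpkm < 0))
        stop("control_fpkm must be non-negative", call. = FALSE)
    df
}

#' @rdname readExpressionTable
#' @param x a data.frame with the expression-table columns
#' @export
writeExpressionTable <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header \code{gene_id}, \code{chrom}, \code{tss}
#' (0-based position of the TSS base) and \code{strand} (\code{+}/\code{-}).
#'
#' @param path file path
#' @return a data.frame, one row per gene
#' @export
readGeneTable <- function(path) {
    df <- .readTsvTable(path, c("gene_id", "chrom", "tss", "strand"),
                        "gene table")
    if (!all(df$strand %in% c("+", "-")))
        stop("gene strand must be '+' or '-'", call. = FALSE)
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene_id in gene table", call. = FALSE)
    df
}

#' @rdname readGeneTable
#' @param x a data.frame with the gene-table columns
#' @export
writeGeneTable <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a 4-column signal bedGraph into per-chromosome run-length vectors
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open)
#' @return an \code{RleList}, one numeric per-base vector per chromosome
#' @export
readSignalBedGraph <- function(path) {
    dat <- .readLinesData(path)
    if (!length(dat$lines)) return(RleList(compress = FALSE))
    fields <- strsplit(dat$lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4L))
        stop("malformed bedGraph line ",
             dat$lineno[which(lengths(fields) < 4L)[1L]], call. = FALSE)
    chrom <- vapply(fields, `[`, "", 1L)
    start0 <- as.numeric(vapply(fields, `[`, "", 2L))
    end0 <- as.numeric(vapply(fields, `[`, "", 3L))
    val <- as.numeric(vapply(fields, `[`, "", 4L))
    if (any(end0 <= start0)) stop("bedGraph interval with end <= start",
                                  call. = FALSE)
    out <- lapply(split(seq_along(chrom), chrom), function(i) {
        len <- max(end0[i])
        v <- numeric(len)
        for (k in i) v[(start0[k] + 1):end0[k]] <- val[k]
        Rle(v)
    })
    methods::as(out, "RleList")
}

#' @rdname readSignalBedGraph
#' @param x an \code{RleList} of per-base signal
#' @export
writeSignalBedGraph <- function(x, path) {
    lines <- character()
    for (chrom in names(x)) {
        r <- x[[chrom]]
        ends <- cumsum(S4Vectors::runLength(r))
        starts0 <- c(0, ends[-length(ends)])
        v <- S4Vectors::runValue(r)
        lines <- c(lines, paste(chrom, starts0, ends,
                                format(v, trim = TRUE, digits = 10L),
                                sep = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}
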