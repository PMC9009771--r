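# Delimiter by extension: ".csv" means comma, anything else tab.
.delimFor <- function(file) if (grepl("\\.csv$", file)) "," else "\t"

.readDelim <- function(file, ...) {
    if (!file.exists(file))
        stop("no such file: ", file)
    utils::read.table(file, header = TRUE, sep = .delimFor(file), ...)
}

# Atomic write: serialize to a temp file in the destination directory,
# then rename, so failed runs never leave partial outputs behind.
.atomically <- function(file, writer) {
    tmp <- tempfile(tmpdir = dirname(file), fileext = ".tmp")
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, file))
        stop("could not move temporary file onto ", file)
    invisible(file)
}

#' Read a delimited counts table
#'
#' Expects a header row of sample IDs and gene IDs in the first column;
#' tab-delimited unless the file name ends in `.csv`.
#'
#' @param file path to the counts file.
#' @return Integer matrix (genes x samples) with dimnames.
#' @export
readCountsTable <- function(file) {
    df <- .readDelim(file, row.names = 1L, check.names = FALSE)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    if (any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers")
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene IDs in counts table")
    if (ncol(m) < 2L)
        stop("at least 2 samples are required")
    m
}

#' Read a gene annotation table
#'
#' Delimited text with columns `gene_id`, `length_bp` and optionally
#' `biotype`.
#'
#' @param file path to the annotation file.
#' @return A data.frame with one row per gene.
#' @export
readGeneAnnotation <- function(file) {
    df <- .readDelim(file, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("gene_id", "length_bp")
    if (!all(need %in% colnames(df)))
        stop("annotation must contain columns: ",
             paste(need, collapse = ", "))
    if (any(df$length_bp < 1))
        stop("gene lengths must be >= 1 bp")
    df
}

#' Read a per-gene covariate file
#'
#' Two delimited columns: `gene_id` and `value` (mean log-expression).
#'
#' @param file path to the covariate file.
#' @return Named numeric vector.
#' @export
readCovariate <- function(file) {
    df <- .readDelim(file, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("covariate file needs columns gene_id and value")
    stats::setNames(as.numeric(df[[2L]]), df[[1L]])
}

#' Read / write a correlation matrix as delimited text
#'
#' The matrix is stored dense with gene IDs as header and first column,
#' in sorted (covariate-ascending) gene order; `writeCorrelationMatrix()`
#' also writes a sidecar `<file>.genes` table recording the gene order
#' and the sort covariate, which `readCorrelationMatrix()` uses when no
#' explicit covariate is supplied. Writes are atomic.
#'
#' @param file path to the matrix file.
#' @param covariate named per-gene covariate vector; if `NULL`, read from
#'   the sidecar file.
#' @return `readCorrelationMatrix()` returns a
#'   [CorrelationMatrix-class]; `writeCorrelationMatrix()` the path,
#'   invisibly.
#' @export
readCorrelationMatrix <- function(file, covariate = NULL) {
    df <- .readDelim(file, row.names = 1L, check.names = FALSE)
    m <- as.matrix(df)
    if (is.null(covariate)) {
        sidecar <- paste0(file, ".genes")
        if (!file.exists(sidecar))
            stop("no covariate supplied and no sidecar file ", sidecar)
        covariate <- readCovariate(sidecar)
    }
    CorrelationMatrix(m, covariate = covariate)
}

#' @param corr a [CorrelationMatrix-class] to write.
#' @rdname readCorrelationMatrix
#' @export
writeCorrelationMatrix <- function(corr, file) {
    stopifnot(is(corr, "CorrelationMatrix"))
    sep <- .delimFor(file)
    .atomically(file, function(tmp)
        utils::write.table(corValues(corr), tmp, sep = sep,
                           quote = FALSE, col.names = NA))
    .atomically(paste0(file, ".genes"), function(tmp)
        utils::write.table(
            data.frame(gene_id = geneIDs(corr), value = covariate(corr)),
            tmp, sep = sep, quote = FALSE, row.names = FALSE))
    invisible(file)
}

#' Write a synthetic dataset to a directory
#'
#' Writes the counts (`counts.tsv`), annotation (`annotation.tsv`),
#' ground-truth edges (`true_edges.tsv`), batch factors
#' (`batch_factors.tsv`) and the generator configuration (`config.json`)
#' of a [generateDataset()] result in the formats the preprocessing
#' readers accept. The realized latent correlation matrix is written only
#' when `withTrueCorr = TRUE` (it is quadratic in the number of genes).
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment-class] from
#'   [generateDataset()].
#' @param dir output directory (created if missing).
#' @param withTrueCorr also write `true_corr.tsv`.
#' @return The directory path, invisibly.
#' @export
writeDataset <- function(se, dir, withTrueCorr = FALSE) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    counts <- SummarizedExperiment::assay(se, "counts")
    .atomically(file.path(dir, "counts.tsv"), function(tmp)
        utils::write.table(counts, tmp, sep = "\t", quote = FALSE,
                           col.names = NA))
    rd <- SummarizedExperiment::rowData(se)
    .atomically(file.path(dir, "annotation.tsv"), function(tmp)
        utils::write.table(
            data.frame(gene_id = rownames(se),
                       length_bp = rd$length_bp,
                       biotype = rd$biotype),
            tmp, sep = "\t", quote = FALSE, row.names = FALSE))
    md <- S4Vectors::metadata(se)
    if (!is.null(md$trueEdges))
        .atomically(file.path(dir, "true_edges.tsv"), function(tmp)
            utils::write.table(
                data.frame(gene1 = md$trueEdges[, 1L],
                           gene2 = md$trueEdges[, 2L]),
                tmp, sep = "\t", quote = FALSE, row.names = FALSE))
    if (!is.null(md$batchFactor))
        .atomically(file.path(dir, "batch_factors.tsv"), function(tmp)
            utils::write.table(md$batchFactor, tmp, sep = "\t",
                               quote = FALSE, col.names = NA))
    if (!is.null(md$config))
        .atomically(file.path(dir, "config.json"), function(tmp)
            jsonlite::write_json(unclass(md$config), tmp,
                                 auto_unbox = TRUE, digits = NA))
    if (withTrueCorr && !is.null(md$trueCorr))
        writeCorrelationMatrix(md$trueCorr, file.path(dir, "true_corr.tsv"))
    invisible(dir)
}
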