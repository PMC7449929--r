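# Plain-text interchange: TSV expression, CSV sample sheets and cohorts,
# MTX single-cell matrices.

#' Write / read a bulk cohort directory
#'
#' A bulk cohort is stored as plain text: \code{expression.tsv}
#' (log-normalized genes x samples, first column \code{gene_id}),
#' \code{samples.csv} (sample sheet with \code{tlr_max},
#' \code{cluster_truth} and \code{immune_fraction_truth} when present) and
#' \code{signatures.gmt} (the signature collection, if attached to
#' \code{metadata()}).
#'
#' @param se A \code{SummarizedExperiment} as produced by
#'   [generateBulkCohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, \code{dir}.
#' @export
writeBulkCohort <- function(se, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- SummarizedExperiment::assay(se)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  cd <- cbind(sample_id = rownames(cd), cd)
  utils::write.csv(cd, file.path(dir, "samples.csv"), row.names = FALSE)
  sigs <- S4Vectors::metadata(se)$signatures
  if (!is.null(sigs)) writeGMT(sigs, file.path(dir, "signatures.gmt"))
  invisible(dir)
}

#' @rdname writeBulkCohort
#' @return For \code{readBulkCohort}, a \code{SummarizedExperiment} with
#'   assay \code{logexpr}, the sample sheet as \code{colData} and the
#'   signatures (if present) in \code{metadata()}.
#' @export
readBulkCohort <- function(dir) {
  df <- utils::read.delim(file.path(dir, "expression.tsv"),
                          check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  cd <- utils::read.csv(file.path(dir, "samples.csv"),
                        stringsAsFactors = FALSE)
  rownames(cd) <- cd$sample_id
  cd$sample_id <- NULL
  if ("cluster_truth" %in% names(cd))
    cd$cluster_truth <- factor(cd$cluster_truth,
                               levels = c("immune-poor", "immune-rich"))
  meta <- list()
  gmt <- file.path(dir, "signatures.gmt")
  if (file.exists(gmt)) meta$signatures <- readGMT(gmt)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(logexpr = mat),
    colData = S4Vectors::DataFrame(cd[colnames(mat), , drop = FALSE]),
    metadata = meta)
}

#' Write / read a response cohort CSV
#'
#' Long-format CSV with one row per (patient, timepoint):
#' \code{patient_id}, \code{timepoint}, \code{glut1}, \code{glut3},
#' \code{response}, \code{pfs_time}, \code{event}.
#'
#' @param cohort Data frame from [generateResponseCohort()] (or of the same
#'   shape).
#' @param path CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeResponseCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResponseCohort
#' @return For \code{readResponseCohort}, the cohort \code{data.frame} with
#'   \code{timepoint} and \code{response} restored as factors.
#' @export
readResponseCohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timepoint <- factor(df$timepoint, levels = c("pre", "on"))
  df$response <- factor(df$response, levels = c("PD", "SD", "PR_CR"))
  df$event <- as.logical(df$event)
  df
}

#' Write / read a single-cell cohort as MTX plus label files
#'
#' Writes \code{counts.mtx} (MatrixMarket sparse counts, genes x cells),
#' \code{genes.tsv} (gene id and group) and \code{cells.tsv} (cell id and
#' type).
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay
#'   (e.g. from [generateScCohort()]).
#' @param dir Output directory (created if missing).
#' @return Invisibly, \code{dir}.
#' @export
writeCellMatrix <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "counts.mtx"))
  rd <- as.data.frame(SummarizedExperiment::rowData(sce))
  genes <- data.frame(gene_id = rownames(counts))
  if ("group" %in% names(rd)) genes$group <- rd$group
  utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cells <- data.frame(cell_id = colnames(counts))
  if ("cell_type" %in% names(cd)) cells$cell_type <- cd$cell_type
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCellMatrix
#' @return For \code{readCellMatrix}, a \code{SingleCellExperiment} with
#'   sparse \code{counts}, gene groups in \code{rowData} and cell types in
#'   \code{colData}.
#' @export
readCellMatrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"))
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  rd <- S4Vectors::DataFrame(row.names = genes$gene_id)
  if ("group" %in% names(genes)) rd$group <- genes$group
  cd <- S4Vectors::DataFrame(row.names = cells$cell_id)
  if ("cell_type" %in% names(cells)) cd$cell_type <- cells$cell_type
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
}

#' Write an enrichment table as CSV
#'
#' One row per sample: \code{sample_id}, one column per signature score,
#' and the \code{ImmuneScore}.
#'
#' @param et An [EnrichmentTable-class].
#' @param path CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeEnrichmentTable <- function(et, path) {
  stopifnot(is(et, "EnrichmentTable"))
  df <- data.frame(sample_id = colnames(et@scores),
                   t(et@scores),
                   ImmuneScore = et@immuneScore,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
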