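# Single-cell normalization, GLUT1/GLUT3 four-class gating, and per-cell
# gene-set scores.

#' Library-size log-normalization of single-cell counts
#'
#' Each count is divided by its cell's total, multiplied by \code{scale}
#' (10,000 by default) and natural-log transformed with a pseudocount of 1:
#' \code{ln(1 + scale * count / total)}. Zeros stay exactly zero and the
#' result is invariant to rescaling all counts of a cell.
#'
#' @param counts Genes-by-cells count matrix (dense or sparse), or a
#'   \code{SingleCellExperiment} with a \code{counts} assay (e.g. from
#'   [generateScCohort()]).
#' @param scale Scaling factor (default 1e4).
#' @return Normalized matrix of the same shape (sparse in, sparse out); for
#'   a \code{SingleCellExperiment} input, the object with a
#'   \code{logcounts} assay added.
#' @export
logNormalizeCells <- function(counts, scale = 1e4) {
  .assertNumber(scale, "scale", 0, strict = TRUE)
  sce <- NULL
  if (is(counts, "SingleCellExperiment")) {
    sce <- counts
    counts <- SummarizedExperiment::assay(sce, "counts")
  }
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    .stopf("zeroTotalCell", "cell(s) with zero total count: %s",
           paste(head(bad, 5L), collapse = ", "))
  }
  if (is(counts, "sparseMatrix")) {
    norm <- methods::as(counts %*% Matrix::Diagonal(x = scale / totals),
                        "CsparseMatrix")
    norm@x <- log1p(norm@x)  # sparse: transform nonzeros only, zeros stay 0
    dimnames(norm) <- dimnames(counts)
  } else {
    norm <- log1p(sweep(counts, 2L, scale / totals, `*`))
  }
  if (!is.null(sce)) {
    SummarizedExperiment::assay(sce, "logcounts") <- norm
    return(sce)
  }
  norm
}

#' Gate single cells on GLUT1 and GLUT3 positivity
#'
#' A cell is positive for a transporter when its normalized expression is
#' strictly above the cutoff, yielding the exhaustive four-class partition
#' GLUT1+GLUT3-, GLUT1-GLUT3+, double-positive and double-negative (the
#' single-cell scatter-gate with one cutoff for both genes).
#'
#' @param norm Normalized genes-by-cells matrix (e.g. from
#'   [logNormalizeCells()]), or a \code{SingleCellExperiment} with a
#'   \code{logcounts} assay.
#' @param glut1Gene,glut3Gene Row identifiers of the two transporters
#'   (defaults \code{SLC2A1}, \code{SLC2A3}).
#' @param cutoff Positivity cutoff on the normalized scale (default 0.5).
#' @param cellTypes Optional per-cell type labels; when given (or present
#'   in the \code{SingleCellExperiment}'s \code{colData$cell_type}), a
#'   class-by-type composition table is included.
#' @return List with \code{class} (named factor over the four classes),
#'   \code{fractions} (named numeric summing to 1), \code{cutoff}, and
#'   optionally \code{composition} (class x cell-type counts).
#' @export
gateGlut <- function(norm, glut1Gene = "SLC2A1", glut3Gene = "SLC2A3",
                     cutoff = 0.5, cellTypes = NULL) {
  .assertNumber(cutoff, "cutoff", 0, strict = TRUE)
  if (is(norm, "SingleCellExperiment")) {
    if (is.null(cellTypes) &&
        "cell_type" %in% names(SummarizedExperiment::colData(norm)))
      cellTypes <- SummarizedExperiment::colData(norm)$cell_type
    norm <- SummarizedExperiment::assay(norm, "logcounts")
  }
  missing <- setdiff(c(glut1Gene, glut3Gene), rownames(norm))
  if (length(missing))
    .stopf("missingGene", "gene(s) not in the matrix: %s",
           paste(missing, collapse = ", "))
  g1 <- as.numeric(norm[glut1Gene, ]) > cutoff
  g3 <- as.numeric(norm[glut3Gene, ]) > cutoff
  cls <- factor(ifelse(g1 & g3, "double_pos",
                ifelse(g1, "G1pos_G3neg",
                ifelse(g3, "G1neg_G3pos", "double_neg"))),
                levels = c("G1pos_G3neg", "G1neg_G3pos",
                           "double_pos", "double_neg"))
  names(cls) <- colnames(norm)
  out <- list(class = cls,
              fractions = table(cls) / length(cls),
              cutoff = cutoff)
  out$fractions <- setNames(as.numeric(out$fractions),
                            names(out$fractions))
  if (!is.null(cellTypes))
    out$composition <- table(class = cls, cell_type = cellTypes)
  out
}

#' Per-cell gene-set score
#'
#' The mean normalized expression of the set's genes in each cell — the
#' single-cell analogue of the bulk enrichment score (a rank-based running
#' sum is unstable in sparse cells, so a signature mean is used instead).
#' Set genes absent from the matrix are dropped; no overlap is an error.
#'
#' @param norm Normalized genes-by-cells matrix or a
#'   \code{SingleCellExperiment} with \code{logcounts}.
#' @param geneSet Character vector of gene identifiers.
#' @return Named numeric vector of per-cell scores.
#' @export
perCellScore <- function(norm, geneSet) {
  if (is(norm, "SingleCellExperiment"))
    norm <- SummarizedExperiment::assay(norm, "logcounts")
  genes <- intersect(geneSet, rownames(norm))
  if (!length(genes))
    .stopf("emptyOverlap", "gene set has no overlap with the matrix")
  Matrix::colMeans(norm[genes, , drop = FALSE])
}
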