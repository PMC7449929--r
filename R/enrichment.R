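# Single-sample gene-set enrichment (ssGSEA) and the ImmuneScore summation.

#' Single-sample gene-set enrichment score
#'
#' Ranks the sample's genes by descending expression (ties broken by gene
#' identifier for determinism) and accumulates the weighted running-sum
#' statistic: at each position i,
#' \deqn{P_{in}(i) = \sum_{j \le i,\, j \in S} w_j / \sum_{j \in S} w_j,
#'       \quad w_j = (\mathrm{rank\ from\ bottom}_j)^\alpha,}
#' \deqn{P_{out}(i) = \#\{\mathrm{non-set\ genes} \le i\} / \#\mathrm{non-set\ genes},}
#' and the score is \eqn{\sum_i (P_{in}(i) - P_{out}(i))}. The statistic
#' depends only on the ranking, so it is invariant under strictly monotone
#' transforms of expression.
#'
#' @param expr Named numeric vector of one sample's expression over genes.
#' @param geneSet Character vector of gene identifiers.
#' @param alpha Non-negative rank-weighting exponent; 0 gives the unweighted
#'   Kolmogorov-Smirnov-like running sum, 0.25 (default) the conventional
#'   single-sample GSEA weighting.
#' @return A single numeric enrichment score.
#' @examples
#' expr <- c(A = 3, B = 2, C = 1)
#' ssgseaScore(expr, "A", alpha = 0)   #  1.5
#' ssgseaScore(expr, "C", alpha = 0)   # -1.5
#' @export
ssgseaScore <- function(expr, geneSet, alpha = 0.25) {
  if (!is.numeric(expr) || is.null(names(expr)) || anyDuplicated(names(expr)))
    .stopf("invalidParameter",
           "'expr' must be a numeric vector with unique gene names")
  .assertNumber(alpha, "alpha", 0)
  inSet <- names(expr) %in% geneSet
  if (!any(inSet))
    .stopf("emptyOverlap", "gene set has no overlap with the expressed genes")
  if (all(inSet))
    .stopf("degenerateSet", "gene set covers all genes; score is degenerate")
  ord <- order(-expr, names(expr), method = "radix")
  inSet <- inSet[ord]
  n <- length(expr)
  w <- (n - seq_len(n) + 1)^alpha
  pIn <- cumsum(ifelse(inSet, w, 0)) / sum(w[inSet])
  pOut <- cumsum(!inSet) / sum(!inSet)
  sum(pIn - pOut)
}

#' Score a cohort against a signature collection
#'
#' Applies [ssgseaScore()] to every sample for every signature and fills the
#' per-sample ImmuneScore as the sum of the immune-summand signature scores
#' (the ten immune cell types in the default collection). Signature genes
#' absent from the matrix are silently dropped with a message reporting the
#' count; a signature with no overlap at all is an error naming it.
#'
#' @param expr Genes-by-samples numeric matrix of log-normalized expression,
#'   or a \code{SummarizedExperiment} whose first assay is one (e.g. from
#'   [generateBulkCohort()]).
#' @param sigs A [SignatureCollection-class].
#' @param alpha Rank-weighting exponent passed to [ssgseaScore()].
#' @param normalize If \code{TRUE}, min-max rescale each signature's scores
#'   across the cohort to \[0, 1\] (off by default; the raw running-sum
#'   statistic is reported).
#' @return An [EnrichmentTable-class].
#' @examples
#' se <- generateBulkCohort(bulkSimParams(n_samples = 8, seed = 1))
#' et <- scoreCohort(se, S4Vectors::metadata(se)$signatures)
#' immuneScore(et)[1:3]
#' @export
scoreCohort <- function(expr, sigs, alpha = 0.25, normalize = FALSE) {
  if (is(expr, "SummarizedExperiment"))
    expr <- SummarizedExperiment::assay(expr)
  if (!is.matrix(expr) || is.null(rownames(expr)) || is.null(colnames(expr)))
    .stopf("invalidParameter",
           "'expr' must be a genes x samples matrix with dimnames")
  stopifnot(is(sigs, "SignatureCollection"))

  sets <- geneSets(sigs)
  present <- lapply(sets, function(gs) gs[gs %in% rownames(expr)])
  nDropped <- sum(lengths(sets) - lengths(present))
  if (nDropped > 0)
    message(sprintf("scoreCohort: dropped %d signature gene(s) absent from the matrix",
                    nDropped))
  empty <- names(present)[lengths(present) == 0L]
  if (length(empty))
    .stopf("emptyOverlap",
           "signature(s) with zero overlap in the expression matrix: %s",
           paste(empty, collapse = ", "))

  scores <- vapply(seq_len(ncol(expr)), function(j) {
    v <- expr[, j]
    vapply(present, function(gs) ssgseaScore(v, gs, alpha), numeric(1))
  }, numeric(length(present)))
  scores <- matrix(scores, nrow = length(present),
                   dimnames = list(names(present), colnames(expr)))
  if (normalize) {
    rng <- apply(scores, 1L, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    scores <- (scores - rng[1, ]) / span
  }
  imm <- sigs@immune
  new("EnrichmentTable", scores = scores, immune = imm,
      immuneScore = colSums(scores[imm, , drop = FALSE]))
}
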