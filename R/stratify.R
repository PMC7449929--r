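# KDE-based immune-rich/poor stratification and the correlation analyses.

#' Gaussian kernel density estimate of a score distribution
#'
#' Thin wrapper around \code{stats::density} with the settings used for
#' ImmuneScore histograms: Gaussian kernel, 512 regular grid points spanning
#' \[min - 3 bw, max + 3 bw\], and Silverman's rule-of-thumb bandwidth by
#' default (the \code{density} default \code{bw.nrd0}).
#'
#' @param values Numeric vector, n >= 4, finite, not all identical.
#' @param bandwidth_rule \code{"silverman"} (default) or \code{"fixed"}.
#' @param bandwidth Positive bandwidth, required when
#'   \code{bandwidth_rule = "fixed"}.
#' @return A [DensityCurve-class].
#' @seealso [findSplitThreshold()]
#' @export
kdeDensity <- function(values, bandwidth_rule = c("silverman", "fixed"),
                       bandwidth = NULL) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (length(values) < 4L || any(!is.finite(values)))
    .stopf("invalidParameter", "'values' must be >= 4 finite numbers")
  if (max(values) == min(values))
    .stopf("degenerateDistribution",
           "all values identical; density estimate is degenerate")
  bw <- if (bandwidth_rule == "fixed") {
    if (is.null(bandwidth))
      .stopf("invalidParameter", "fixed rule requires a 'bandwidth'")
    .assertNumber(bandwidth, "bandwidth", 0, strict = TRUE)
  } else stats::bw.nrd0(values)
  d <- density(values, bw = bw, kernel = "gaussian", n = 512L, cut = 3)
  new("DensityCurve", grid = d$x, density = d$y, bandwidth = d$bw)
}

#' Valley threshold between the two dominant modes of a density
#'
#' Locates the local maxima of the curve, takes the two with the highest
#' density, and returns the grid point of minimum density strictly between
#' them (the valley). When several interior minima exist, the one with the
#' lowest density wins; exact density ties resolve to the smaller grid
#' value. A unimodal curve raises a \code{noValley} error so the caller can
#' fall back to a fixed threshold.
#'
#' @param curve A [DensityCurve-class].
#' @return The threshold (numeric scalar, at grid resolution).
#' @examples
#' set.seed(1)
#' x <- c(rnorm(500, 0.2, 0.05), rnorm(500, 0.8, 0.05))
#' findSplitThreshold(kdeDensity(x))  # near 0.5
#' @export
findSplitThreshold <- function(curve) {
  stopifnot(is(curve, "DensityCurve"))
  d <- curve@density
  n <- length(d)
  isMax <- which(vapply(seq(2L, n - 1L), function(i)
    d[i] > d[i - 1L] && d[i] >= d[i + 1L], TRUE)) + 1L
  if (length(isMax) < 2L)
    .stopf("noValley",
           "density has fewer than two local maxima; no valley threshold")
  top2 <- sort(isMax[order(d[isMax], decreasing = TRUE)[1:2]])
  inner <- seq(top2[1] + 1L, top2[2] - 1L)
  valley <- inner[which.min(d[inner])]  # which.min takes the first = smaller grid
  curve@grid[valley]
}

#' Assign immune-poor / immune-rich cluster labels
#'
#' A sample is immune-rich iff its score is strictly greater than the
#' threshold (scores exactly at the threshold are immune-poor).
#'
#' @param scores Named numeric vector of per-sample scores (e.g.
#'   [immuneScore()] output).
#' @param threshold Numeric split point, typically from
#'   [findSplitThreshold()].
#' @return A [ClusterAssignment-class].
#' @export
assignClusters <- function(scores, threshold) {
  if (any(!is.finite(scores)))
    .stopf("invalidParameter", "'scores' must be finite")
  .assertNumber(threshold, "threshold")
  labels <- factor(ifelse(scores > threshold, "immune-rich", "immune-poor"),
                   levels = c("immune-poor", "immune-rich"))
  names(labels) <- names(scores)
  new("ClusterAssignment", threshold = threshold, labels = labels)
}

#' Pearson correlation with a t-distributed p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from the
#' t distribution with n - 2 degrees of freedom (via
#' \code{stats::cor.test}).
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both with nonzero
#'   variance.
#' @return A list with elements \code{r}, \code{p} and \code{n}.
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    .stopf("invalidParameter", "'x' and 'y' must be equal length, n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    .stopf("invalidParameter", "inputs must be finite")
  if (var(x) == 0 || var(y) == 0)
    .stopf("undefinedCorrelation",
           "correlation undefined: an input has zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cross-correlation of enrichment scores with metabolic features
#'
#' Correlates every signature score (plus the ImmuneScore) with every
#' feature column, producing the long table behind a correlation heatmap of
#' immune cell types against glucose-metabolic profiles (GLUT1, GLUT3,
#' glycolysis, TLRmax).
#'
#' @param scores An [EnrichmentTable-class].
#' @param features Numeric matrix or data.frame, samples x features, with
#'   rownames matching the score table's sample names.
#' @return A \code{data.frame} with columns \code{signature},
#'   \code{feature}, \code{r}, \code{p}, \code{n}.
#' @export
correlationPanel <- function(scores, features) {
  stopifnot(is(scores, "EnrichmentTable"))
  features <- as.matrix(features)
  shared <- intersect(colnames(scores@scores), rownames(features))
  if (length(shared) < 3L)
    .stopf("invalidParameter", "fewer than 3 shared samples")
  mat <- rbind(scores@scores[, shared, drop = FALSE],
               ImmuneScore = scores@immuneScore[shared])
  features <- features[shared, , drop = FALSE]
  out <- expand.grid(signature = rownames(mat),
                     feature = colnames(features),
                     stringsAsFactors = FALSE)
  res <- mapply(function(s, f) {
    pc <- pearsonCorr(mat[s, ], features[, f])
    c(pc$r, pc$p)
  }, out$signature, out$feature)
  out$r <- res[1, ]
  out$p <- res[2, ]
  out$n <- length(shared)
  out
}

#' Cluster-conditional correlations of TLRmax with metabolic features
#'
#' Within each immune cluster separately, correlates the PET uptake readout
#' (TLRmax) with each feature (typically ImmuneScore, GLUT1 and GLUT3) —
#' the analysis showing that uptake tracks cancer GLUT1 in immune-poor
#' tumors and immune GLUT3 in immune-rich tumors. Clusters with fewer than
#' 3 samples are skipped with a warning.
#'
#' @param tlr Named numeric vector of per-sample TLRmax.
#' @param features Samples x features matrix or data.frame (rownames are
#'   sample ids).
#' @param clusters A [ClusterAssignment-class] over the same samples.
#' @return A \code{data.frame} with columns \code{cluster}, \code{feature},
#'   \code{r}, \code{p}, \code{n}.
#' @export
conditionalCorrelations <- function(tlr, features, clusters) {
  stopifnot(is(clusters, "ClusterAssignment"))
  features <- as.matrix(features)
  labels <- clusterLabels(clusters)
  shared <- Reduce(intersect, list(names(tlr), rownames(features),
                                   names(labels)))
  if (length(shared) < 3L)
    .stopf("invalidParameter", "fewer than 3 shared samples")
  tlr <- tlr[shared]; features <- features[shared, , drop = FALSE]
  labels <- labels[shared]
  out <- NULL
  for (cl in levels(droplevels(labels))) {
    idx <- labels == cl
    if (sum(idx) < 3L) {
      warning(sprintf("cluster '%s' has %d sample(s); skipped", cl, sum(idx)))
      next
    }
    for (f in colnames(features)) {
      pc <- pearsonCorr(tlr[idx], features[idx, f])
      out <- rbind(out, data.frame(cluster = cl, feature = f,
                                   r = pc$r, p = pc$p, n = pc$n,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
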