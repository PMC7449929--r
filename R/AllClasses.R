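#' @import methods
#' @importFrom stats cor.test density pchisq pnorm qnorm quantile rbeta rbinom
#'   rexp rlnorm rnbinom rnorm rpois runif sd setNames var kruskal.test
#' @importFrom utils combn head
NULL

#' Named gene-set collection with immune-summand flags
#'
#' Holds named gene sets (immune cell types, glycolysis, ...) together with a
#' logical flag marking the sets whose enrichment scores are summed into the
#' per-sample ImmuneScore.
#'
#' @slot sets Named list of character vectors (gene identifiers).
#' @slot immune Logical vector, one per set; \code{TRUE} for the immune
#'   cell-type sets that enter the ImmuneScore summation.
#'
#' @seealso [SignatureCollection()], [defaultSignatureCollection()],
#'   [readGMT()]
#' @exportClass SignatureCollection
setClass("SignatureCollection",
  representation(sets = "list", immune = "logical"))

setValidity("SignatureCollection", function(object) {
  s <- object@sets
  if (length(s) == 0L) return("collection must contain at least one set")
  if (is.null(names(s)) || anyDuplicated(names(s)) || any(!nzchar(names(s))))
    return("set names must be unique and non-empty")
  if (!all(vapply(s, function(g) is.character(g) && length(g) > 0L, TRUE)))
    return("every gene set must be a non-empty character vector")
  if (length(object@immune) != length(s))
    return("'immune' flag must have one entry per set")
  TRUE
})

#' Per-sample, per-signature enrichment scores
#'
#' Stores the signature-by-sample matrix of single-sample enrichment scores
#' plus the derived ImmuneScore (the sum of the immune-summand signature
#' scores for each sample).
#'
#' @slot scores Numeric matrix, signatures (rows) by samples (columns).
#' @slot immune Logical per-row flag; \code{TRUE} rows are summed into the
#'   ImmuneScore.
#' @slot immuneScore Named numeric vector of per-sample ImmuneScores.
#'
#' @seealso [scoreCohort()], [immuneScore()], [enrichmentScores()]
#' @exportClass EnrichmentTable
setClass("EnrichmentTable",
  representation(scores = "matrix", immune = "logical",
                 immuneScore = "numeric"))

setValidity("EnrichmentTable", function(object) {
  sc <- object@scores
  if (!is.numeric(sc) || is.null(rownames(sc)) || is.null(colnames(sc)))
    return("scores must be a numeric matrix with signature and sample names")
  if (length(object@immune) != nrow(sc))
    return("'immune' flag must have one entry per signature row")
  if (length(object@immuneScore) != ncol(sc))
    return("immuneScore must have one entry per sample")
  expected <- colSums(sc[object@immune, , drop = FALSE])
  if (max(abs(expected - object@immuneScore)) > 1e-9)
    return("immuneScore must equal the sum of immune-summand rows (1e-9)")
  TRUE
})

#' A PET SUV volume with tumor and liver spherical VOIs
#'
#' A 3D standardized-uptake-value (SUV) grid with voxel spacing in mm and two
#' spherical volumes of interest: one enclosing the tumor lesion and one on
#' the liver used as the reference for TLRmax normalization. World coordinates
#' are in mm; the voxel with 0-based index \code{v} spans
#' \code{[v*spacing, (v+1)*spacing)} and its center sits at
#' \code{(v + 0.5)*spacing}.
#'
#' @slot suv Non-negative numeric 3D array of SUV values.
#' @slot spacing Positive numeric vector of length 3, voxel edge lengths (mm).
#' @slot tumorVoi Numeric length-4 \code{c(x, y, z, r)} sphere in mm.
#' @slot liverVoi Numeric length-4 \code{c(x, y, z, r)} sphere in mm.
#'
#' @seealso [PetStudy()], [segmentTumor()], [tlrMax()]
#' @exportClass PetStudy
setClass("PetStudy",
  representation(suv = "array", spacing = "numeric",
                 tumorVoi = "numeric", liverVoi = "numeric"))

.sphereInBounds <- function(voi, dims, spacing) {
  extent <- dims * spacing
  all(voi[1:3] - voi[4] >= 0) && all(voi[1:3] + voi[4] <= extent)
}

setValidity("PetStudy", function(object) {
  if (length(dim(object@suv)) != 3L) return("suv must be a 3D array")
  if (any(!is.finite(object@suv)) || any(object@suv < 0))
    return("suv values must be finite and non-negative")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive voxel edge lengths (mm)")
  for (nm in c("tumorVoi", "liverVoi")) {
    voi <- slot(object, nm)
    if (length(voi) != 4L || voi[4] <= 0)
      return(sprintf("%s must be c(x, y, z, radius) with radius > 0", nm))
    if (!.sphereInBounds(voi, dim(object@suv), object@spacing))
      return(sprintf("%s sphere extends beyond the volume bounds", nm))
  }
  TRUE
})

#' Result of adaptive-threshold tumor segmentation
#'
#' @slot mask Logical 3D array; \code{TRUE} voxels form the metabolically
#'   active tumor. Always a subset of the tumor VOI.
#' @slot threshold The adaptive SUV threshold applied.
#' @slot mtvCm3 Metabolic tumor volume in cm^3 (voxel count times voxel
#'   volume).
#'
#' @seealso [segmentTumor()], [filterSmallTumors()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(mask = "array", threshold = "numeric", mtvCm3 = "numeric"))

setValidity("SegmentationResult", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    return("mask must be a logical 3D array")
  if (length(object@threshold) != 1L || object@threshold <= 0)
    return("threshold must be a single positive number")
  if (length(object@mtvCm3) != 1L || object@mtvCm3 < 0)
    return("mtvCm3 must be a single non-negative number")
  TRUE
})

#' Kernel density curve on a regular grid
#'
#' @slot grid Ordered numeric evaluation points.
#' @slot density Non-negative density values (integrates to 1 by trapezoid
#'   rule within 1e-3).
#' @slot bandwidth The Gaussian kernel bandwidth used.
#'
#' @seealso [kdeDensity()], [findSplitThreshold()]
#' @exportClass DensityCurve
setClass("DensityCurve",
  representation(grid = "numeric", density = "numeric", bandwidth = "numeric"))

setValidity("DensityCurve", function(object) {
  if (length(object@grid) != length(object@density))
    return("grid and density must have equal length")
  if (is.unsorted(object@grid)) return("grid must be ordered")
  if (any(object@density < 0)) return("density must be non-negative")
  if (object@bandwidth <= 0) return("bandwidth must be positive")
  g <- object@grid; d <- object@density
  area <- sum(diff(g) * (head(d, -1) + d[-1]) / 2)
  if (abs(area - 1) > 1e-3)
    return("density must integrate to 1 (trapezoid rule, 1e-3)")
  TRUE
})

#' Two-cluster assignment from an ImmuneScore threshold
#'
#' @slot threshold The score threshold; samples strictly above it are labeled
#'   \code{"immune-rich"}, all others \code{"immune-poor"}.
#' @slot labels Named factor of per-sample labels.
#'
#' @seealso [assignClusters()], [findSplitThreshold()]
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(threshold = "numeric", labels = "factor"))

setValidity("ClusterAssignment", function(object) {
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    return("threshold must be a single finite number")
  if (!identical(levels(object@labels), c("immune-poor", "immune-rich")))
    return("labels must have levels immune-poor, immune-rich")
  TRUE
})
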