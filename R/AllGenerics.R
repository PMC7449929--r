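#' Extract gene sets from a SignatureCollection
#'
#' @param x A [SignatureCollection-class].
#' @return Named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @describeIn geneSets Gene sets of a collection.
setMethod("geneSets", "SignatureCollection", function(x) x@sets)

#' Names of the immune-summand signatures
#'
#' @param x A [SignatureCollection-class] or [EnrichmentTable-class].
#' @return Character vector of signature names flagged as immune summands.
#' @export
setGeneric("immuneSignatures", function(x) standardGeneric("immuneSignatures"))

#' @describeIn immuneSignatures Immune-summand set names of a collection.
setMethod("immuneSignatures", "SignatureCollection",
          function(x) names(x@sets)[x@immune])

#' @describeIn immuneSignatures Immune-summand rows of an enrichment table.
setMethod("immuneSignatures", "EnrichmentTable",
          function(x) rownames(x@scores)[x@immune])

#' Per-sample per-signature score matrix
#'
#' @param x An [EnrichmentTable-class].
#' @return Numeric matrix, signatures by samples.
#' @export
setGeneric("enrichmentScores", function(x) standardGeneric("enrichmentScores"))

#' @describeIn enrichmentScores Score matrix of an enrichment table.
setMethod("enrichmentScores", "EnrichmentTable", function(x) x@scores)

#' Per-sample ImmuneScore
#'
#' The ImmuneScore of a sample is the sum of its enrichment scores over the
#' immune-summand signatures (ten immune cell types in the default
#' collection).
#'
#' @param x An [EnrichmentTable-class].
#' @return Named numeric vector of per-sample ImmuneScores.
#' @export
setGeneric("immuneScore", function(x) standardGeneric("immuneScore"))

#' @describeIn immuneScore ImmuneScore vector of an enrichment table.
setMethod("immuneScore", "EnrichmentTable", function(x) x@immuneScore)

#' Cluster labels of a ClusterAssignment
#'
#' @param x A [ClusterAssignment-class].
#' @return Named factor with levels \code{immune-poor}, \code{immune-rich}.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @describeIn clusterLabels Per-sample labels.
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' Threshold accessors
#'
#' @param x A [ClusterAssignment-class] or [SegmentationResult-class].
#' @return The numeric threshold (ImmuneScore split point, or SUV cutoff).
#' @export
setGeneric("splitThreshold", function(x) standardGeneric("splitThreshold"))

#' @describeIn splitThreshold Score threshold of a cluster assignment.
setMethod("splitThreshold", "ClusterAssignment", function(x) x@threshold)

#' Segmentation mask
#'
#' @param x A [SegmentationResult-class].
#' @return Logical 3D array of tumor voxels.
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))

#' @describeIn tumorMask Voxel mask of a segmentation.
setMethod("tumorMask", "SegmentationResult", function(x) x@mask)

#' Metabolic tumor volume in cm^3
#'
#' @param x A [SegmentationResult-class].
#' @return Numeric scalar, segmented volume in cm^3.
#' @export
setGeneric("mtv", function(x) standardGeneric("mtv"))

#' @describeIn mtv MTV of a segmentation result.
setMethod("mtv", "SegmentationResult", function(x) x@mtvCm3)

#' @describeIn SignatureCollection-class Number of sets.
#' @param x A \code{SignatureCollection}.
#' @export
setMethod("length", "SignatureCollection", function(x) length(x@sets))

#' @describeIn SignatureCollection-class Set names.
#' @export
setMethod("names", "SignatureCollection", function(x) names(x@sets))

setMethod("show", "SignatureCollection", function(object) {
  cat(sprintf("SignatureCollection with %d sets (%d immune-summand)\n",
              length(object@sets), sum(object@immune)))
  sizes <- lengths(object@sets)
  cat(sprintf("  set sizes: %d-%d genes\n", min(sizes), max(sizes)))
  flagged <- names(object@sets)[object@immune]
  if (length(flagged))
    cat("  immune summands:", paste(flagged, collapse = ", "), "\n")
})

setMethod("show", "EnrichmentTable", function(object) {
  cat(sprintf("EnrichmentTable: %d signatures x %d samples\n",
              nrow(object@scores), ncol(object@scores)))
  cat(sprintf("  ImmuneScore range: [%.3f, %.3f]\n",
              min(object@immuneScore), max(object@immuneScore)))
})

setMethod("show", "PetStudy", function(object) {
  d <- dim(object@suv)
  cat(sprintf("PetStudy: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  tumor VOI: center (%s) mm, r = %.1f mm\n",
              paste(format(object@tumorVoi[1:3]), collapse = ", "),
              object@tumorVoi[4]))
  cat(sprintf("  liver VOI: center (%s) mm, r = %.1f mm\n",
              paste(format(object@liverVoi[1:3]), collapse = ", "),
              object@liverVoi[4]))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: threshold %.3f, %d voxels, MTV %.2f cm^3\n",
              object@threshold, sum(object@mask), object@mtvCm3))
})

setMethod("show", "DensityCurve", function(object) {
  cat(sprintf("DensityCurve: %d grid points on [%.3f, %.3f], bw = %.4f\n",
              length(object@grid), min(object@grid), max(object@grid),
              object@bandwidth))
})

setMethod("show", "ClusterAssignment", function(object) {
  tab <- table(object@labels)
  cat(sprintf("ClusterAssignment: threshold %.4f (%d immune-poor, %d immune-rich)\n",
              object@threshold, tab[["immune-poor"]], tab[["immune-rich"]]))
})
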