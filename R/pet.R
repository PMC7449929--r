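# Quantification of 3D SUV volumes: spherical VOIs, adaptive-threshold
# tumor segmentation, TLRmax and the metabolic-tumor-volume filter.

#' Construct a PetStudy
#'
#' @param suv Non-negative numeric 3D array of SUV values.
#' @param spacing Voxel edge lengths in mm; a single number is recycled to
#'   the three axes.
#' @param tumorVoi,liverVoi Spheres \code{c(x, y, z, radius)} in mm world
#'   coordinates; both must lie within the volume.
#' @return A validated [PetStudy-class].
#' @examples
#' suv <- array(1, dim = c(40, 40, 40))      # 1 mm voxels
#' study <- PetStudy(suv, spacing = 1,
#'                   tumorVoi = c(12, 12, 12, 8),
#'                   liverVoi = c(30, 30, 30, 6))
#' study
#' @export
PetStudy <- function(suv, spacing, tumorVoi, liverVoi) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PetStudy", suv = suv, spacing = as.numeric(spacing),
      tumorVoi = as.numeric(tumorVoi), liverVoi = as.numeric(liverVoi))
}

# squared distance of every voxel center to a point (mm); returns array
.voxelDist2 <- function(dims, spacing, center) {
  ax <- lapply(1:3, function(k)
    ((seq_len(dims[k]) - 0.5) * spacing[k] - center[k])^2)
  outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
}

.sphereMask <- function(dims, spacing, voi) {
  .voxelDist2(dims, spacing, voi[1:3]) <= voi[4]^2
}

#' Adaptive-threshold tumor segmentation
#'
#' Segments the metabolically active tumor inside the tumor VOI with a
#' threshold adapting to tumor and background intensities:
#' background B is the mean SUV in a shell of \code{shellVoxels} voxel
#' widths just outside the VOI, peak P the maximum SUV inside it, and the
#' threshold is \eqn{T = B + fraction (P - B)}. Voxels inside the VOI with
#' SUV >= T form the mask; the metabolic tumor volume is the voxel count
#' times the voxel volume.
#'
#' @param study A [PetStudy-class].
#' @param fraction Adaptive fraction in (0, 1); default 0.41, a standard
#'   adaptive-threshold choice.
#' @param shellVoxels Background shell width in voxels (default 2).
#' @return A [SegmentationResult-class].
#' @examples
#' suv <- array(1, dim = c(60, 60, 60))
#' d2 <- (slice.index(suv, 1) - 20.5)^2 + (slice.index(suv, 2) - 20.5)^2 +
#'       (slice.index(suv, 3) - 20.5)^2
#' suv[d2 <= 100] <- 10                         # 1 cm sphere of SUV 10
#' study <- PetStudy(suv, 1, c(20, 20, 20, 15), c(45, 45, 45, 8))
#' seg <- segmentTumor(study, fraction = 0.41)  # T = 1 + 0.41 * 9 = 4.69
#' mtv(seg)                                     # ~ 4.19 cm^3
#' @export
segmentTumor <- function(study, fraction = 0.41, shellVoxels = 2) {
  stopifnot(is(study, "PetStudy"))
  .assertNumber(fraction, "fraction", 0, 1, strict = TRUE)
  if (fraction >= 1)
    .stopf("invalidParameter", "'fraction' must be in (0, 1)")
  dims <- dim(study@suv)
  d2 <- .voxelDist2(dims, study@spacing, study@tumorVoi[1:3])
  r <- study@tumorVoi[4]
  voi <- d2 <= r^2
  shell <- !voi & d2 <= (r + shellVoxels * mean(study@spacing))^2
  if (!any(voi) || !any(shell))
    .stopf("segmentationFailed", "tumor VOI or background shell is empty")
  B <- mean(study@suv[shell])
  P <- max(study@suv[voi])
  if (P <= B)
    .stopf("segmentationFailed",
           "no voxel in the tumor VOI exceeds the background")
  threshold <- B + fraction * (P - B)
  mask <- voi & study@suv >= threshold
  if (!any(mask))
    .stopf("segmentationFailed", "adaptive threshold left an empty mask")
  mtvCm3 <- sum(mask) * prod(study@spacing) / 1000
  new("SegmentationResult", mask = mask, threshold = threshold,
      mtvCm3 = mtvCm3)
}

#' Tumor-to-liver ratio of maximum SUV (TLRmax)
#'
#' The maximum SUV over the segmented tumor divided by the mean SUV over
#' the liver reference VOI, normalizing uptake across scanners and
#' reconstructions. Invariant under rescaling of the whole volume.
#'
#' @param study A [PetStudy-class].
#' @param mask Logical 3D tumor mask, e.g. [tumorMask()] of a
#'   [segmentTumor()] result.
#' @return Numeric TLRmax.
#' @export
tlrMax <- function(study, mask) {
  stopifnot(is(study, "PetStudy"))
  if (!is.logical(mask) || !identical(dim(mask), dim(study@suv)))
    .stopf("invalidParameter", "'mask' must be a logical array matching the volume")
  if (!any(mask))
    .stopf("invalidParameter", "tumor mask is empty")
  liver <- .sphereMask(dim(study@suv), study@spacing, study@liverVoi)
  if (!any(liver))
    .stopf("invalidParameter", "liver VOI contains no voxels")
  liverMean <- mean(study@suv[liver])
  if (liverMean == 0)
    .stopf("divisionError", "liver mean SUV is zero")
  max(study@suv[mask]) / liverMean
}

#' Exclude small metabolic tumor volumes
#'
#' TLRmax is underestimated for small lesions, so studies with metabolic
#' tumor volume of at most \code{minVolumeCm3} (strictly: only volumes
#' greater than the cutoff are kept) are excluded; the default cutoff is
#' 5 cm^3. The number excluded is reported via \code{message}.
#'
#' @param results List of [SegmentationResult-class] objects.
#' @param minVolumeCm3 Volume cutoff in cm^3 (default 5).
#' @return The retained sublist, in input order.
#' @export
filterSmallTumors <- function(results, minVolumeCm3 = 5.0) {
  .assertNumber(minVolumeCm3, "minVolumeCm3", 0)
  if (!length(results)) return(results)
  stopifnot(all(vapply(results, is, TRUE, "SegmentationResult")))
  keep <- vapply(results, mtv, numeric(1)) > minVolumeCm3
  if (any(!keep))
    message(sprintf("filterSmallTumors: excluded %d of %d lesion(s) with MTV <= %.1f cm^3",
                    sum(!keep), length(keep), minVolumeCm3))
  results[keep]
}

#' Read a PET SUV volume from a NIfTI file
#'
#' @param path Path to a NIfTI (.nii / .nii.gz) volume.
#' @return A list with \code{suv} (3D array) and \code{spacing} (mm).
#' @export
readPetVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(suv = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}

#' Write a PET SUV volume to a NIfTI file
#'
#' @param suv 3D numeric array.
#' @param spacing Voxel edge lengths in mm (length 1 or 3).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writePetVolume <- function(suv, spacing, path) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  img <- RNifti::asNifti(suv)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read spherical VOIs from a YAML configuration
#'
#' Expects top-level keys \code{tumor} and \code{liver}, each a mapping
#' with \code{center} (3 mm world coordinates) and \code{radius} (mm).
#'
#' @param path Path to a YAML file.
#' @return List with numeric length-4 \code{tumor} and \code{liver}
#'   entries \code{c(x, y, z, r)}.
#' @export
readVoiConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  parse1 <- function(nm) {
    v <- cfg[[nm]]
    if (is.null(v) || length(v$center) != 3L || is.null(v$radius))
      .stopf("malformedFile", "VOI '%s' needs a 3-vector 'center' and a 'radius'", nm)
    c(as.numeric(v$center), as.numeric(v$radius))
  }
  list(tumor = parse1("tumor"), liver = parse1("liver"))
}
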