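test_that("the adaptive threshold follows background and peak intensities", {
  suv <- spherePhantom(sphereSuv = 8, background = 0)
  study <- PetStudy(suv, 1, c(20, 20, 20, 15), c(45, 45, 45, 8))
  seg <- segmentTumor(study, fraction = 0.5)
  expect_equal(seg@threshold, 4.0)  # B = 0, P = 8
  suv2 <- spherePhantom(sphereSuv = 10, background = 1)
  study2 <- PetStudy(suv2, 1, c(20, 20, 20, 15), c(45, 45, 45, 8))
  seg2 <- segmentTumor(study2, fraction = 0.41)
  expect_equal(seg2@threshold, 1 + 0.41 * 9)
})

test_that("a 1 cm sphere phantom recovers the analytic volume", {
  suv <- spherePhantom()
  study <- PetStudy(suv, 1, c(20, 20, 20, 15), c(45, 45, 45, 8))
  seg <- segmentTumor(study, fraction = 0.41)
  analytic <- 4 / 3 * pi * 1.0^3  # cm^3
  shellTol <- 4 * pi * 1.0^2 * 0.15  # 1.5-voxel shell at 1 mm voxels
  expect_lt(abs(mtv(seg) - analytic), shellTol)
  # mask stays inside the VOI and MTV matches the voxel count exactly
  expect_true(all(which(tumorMask(seg)) %in%
                    which(glutTME:::.sphereMask(dim(suv), rep(1, 3),
                                                c(20, 20, 20, 15)))))
  expect_equal(mtv(seg), sum(tumorMask(seg)) / 1000)
})

test_that("voxelization error shrinks as the voxel size decreases", {
  analytic <- 4 / 3 * pi
  errs <- vapply(c(2, 1, 0.5), function(sp) {
    nv <- round(40 / sp)
    suv <- spherePhantom(dimVox = rep(nv, 3), spacing = sp,
                         center = rep(14, 3))
    study <- PetStudy(suv, sp, c(14, 14, 14, 13),
                      c(rep(40 - 8 * sp, 3) - 2, 4))
    abs(mtv(segmentTumor(study, 0.41)) - analytic)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("fraction near 1 shrinks the mask to the peak voxels", {
  suv <- spherePhantom()
  study <- PetStudy(suv, 1, c(20, 20, 20, 15), c(45, 45, 45, 8))
  seg <- segmentTumor(study, fraction = 0.9999)
  expect_true(all(suv[tumorMask(seg)] == max(suv)))
})

test_that("TLRmax is the tumor max over the liver mean and is scale invariant", {
  suv <- spherePhantom(sphereSuv = 4)
  suv[d2liver <- glutTME:::.sphereMask(dim(suv), rep(1, 3),
                                       c(45, 45, 45, 8))] <- 2
  study <- PetStudy(suv, 1, c(20, 20, 20, 15), c(45, 45, 45, 8))
  seg <- segmentTumor(study, 0.41)
  expect_equal(tlrMax(study, tumorMask(seg)), 2.0)
  # multiplying the whole volume by a constant changes nothing
  study3 <- PetStudy(suv * 3.7, 1, c(20, 20, 20, 15), c(45, 45, 45, 8))
  expect_equal(tlrMax(study3, tumorMask(seg)), 2.0, tolerance = 1e-12)
})

test_that("a noisy liver VOI averages to the reference uptake", {
  set.seed(8)
  suv <- spherePhantom(sphereSuv = 6, background = 0.5)
  liver <- glutTME:::.sphereMask(dim(suv), rep(1, 3), c(45, 45, 45, 10))
  suv[liver] <- pmax(rnorm(sum(liver), 2, 0.1), 0)
  study <- PetStudy(suv, 1, c(20, 20, 20, 15), c(45, 45, 45, 10))
  seg <- segmentTumor(study, 0.41)
  expect_lt(abs(tlrMax(study, tumorMask(seg)) - 3.0), 0.05)
})

test_that("small metabolic volumes are excluded with a strict cutoff", {
  mk <- function(vol) {
    mask <- array(FALSE, dim = c(20, 20, 20))
    mask[seq_len(vol * 1000)] <- TRUE  # 1 mm voxels: vol cm^3
    new("SegmentationResult", mask = mask, threshold = 1, mtvCm3 = vol)
  }
  res <- list(mk(4.9), mk(5.0), mk(5.1))
  expect_message(kept <- filterSmallTumors(res), "excluded 2 of 3")
  expect_length(kept, 1L)
  expect_equal(mtv(kept[[1]]), 5.1)
  expect_identical(filterSmallTumors(list()), list())
})

test_that("segmentation failures and invalid studies raise typed errors", {
  flat <- array(1, dim = c(30, 30, 30))
  study <- PetStudy(flat, 1, c(10, 10, 10, 6), c(22, 22, 22, 5))
  expect_error(segmentTumor(study, 0.41), class = "segmentationFailed")
  expect_error(PetStudy(flat, 1, c(2, 2, 2, 6), c(22, 22, 22, 5)),
               "bounds")
  zero <- array(0, dim = c(30, 30, 30))
  zero[10, 10, 10] <- 5
  study0 <- PetStudy(zero, 1, c(10, 10, 10, 6), c(22, 22, 22, 5))
  seg <- segmentTumor(study0, 0.5)
  expect_error(tlrMax(study0, tumorMask(seg)), class = "divisionError")
})

test_that("NIfTI volumes and YAML VOI configs round trip", {
  dir <- withr::local_tempdir()
  suv <- spherePhantom(dimVox = c(20, 20, 20), center = c(8, 8, 8),
                       radiusMm = 4)
  path <- file.path(dir, "scan.nii.gz")
  writePetVolume(suv, 2, path)
  back <- readPetVolume(path)
  expect_equal(back$suv, suv, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$spacing, rep(2, 3), ignore_attr = TRUE)
  yml <- file.path(dir, "vois.yaml")
  writeLines(c("tumor:", "  center: [8, 8, 8]", "  radius: 6",
               "liver:", "  center: [30, 30, 30]", "  radius: 5"), yml)
  voi <- readVoiConfig(yml)
  expect_equal(voi$tumor, c(8, 8, 8, 6))
  expect_equal(voi$liver, c(30, 30, 30, 5))
})
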