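test_that("generators are bit-identical under a fixed seed", {
  b1 <- generateBulkCohort(bulkSimParams(n_samples = 20, seed = 9))
  b2 <- generateBulkCohort(bulkSimParams(n_samples = 20, seed = 9))
  expect_identical(SummarizedExperiment::assay(b1),
                   SummarizedExperiment::assay(b2))
  expect_identical(SummarizedExperiment::colData(b1)$tlr_max,
                   SummarizedExperiment::colData(b2)$tlr_max)

  r1 <- generateResponseCohort(responseSimParams(n_patients = 30, seed = 9))
  r2 <- generateResponseCohort(responseSimParams(n_patients = 30, seed = 9))
  expect_identical(r1, r2)

  s1 <- generateScCohort(scSimParams(n_cells = 150, seed = 9))
  s2 <- generateScCohort(scSimParams(n_cells = 150, seed = 9))
  expect_identical(SummarizedExperiment::assay(s1),
                   SummarizedExperiment::assay(s2))
})

test_that("invalid generator parameters are rejected", {
  expect_error(bulkSimParams(n_samples = 0), class = "invalidParameter")
  expect_error(bulkSimParams(n_genes = -5), class = "invalidParameter")
  expect_error(bulkSimParams(immune_mix_weight = 1.2),
               class = "invalidParameter")
  expect_error(responseSimParams(hazard_scale = -1),
               class = "invalidParameter")
  expect_error(scSimParams(type_proportions = c(cancer = 0.5, tcell = 0.4)),
               class = "invalidParameter")
})

test_that("noise-free PET limit collapses to the cancer GLUT1 term", {
  p <- bulkSimParams(n_samples = 50, pet_noise_sd = 0,
                     pet_coefs = c(0, 0.3, 0), seed = 2)
  se <- generateBulkCohort(p)
  cd <- SummarizedExperiment::colData(se)
  # bulk GLUT1 on the raw scale is (1 - f) * realized cancer level
  g1raw <- expm1(SummarizedExperiment::assay(se)["SLC2A1", ])
  expect_equal(unname(cd$tlr_max), unname(pmax(0.3 * g1raw, 0.05)),
               tolerance = 1e-12)
})

test_that("single-component mixtures have the analytic Beta mean", {
  p <- bulkSimParams(n_samples = 500, immune_mix_weight = 1,
                     poor_beta = c(2, 8), seed = 1)
  f <- SummarizedExperiment::colData(generateBulkCohort(p))$immune_fraction_truth
  expect_lt(abs(mean(f) - 0.2), 0.03)
  expect_true(all(SummarizedExperiment::colData(
    generateBulkCohort(p))$cluster_truth == "immune-poor"))
})

test_that("latent immune fraction drives bulk GLUT expression in opposite directions", {
  for (s in 1:5) {
    se <- generateBulkCohort(bulkSimParams(seed = s))
    f <- SummarizedExperiment::colData(se)$immune_fraction_truth
    e <- SummarizedExperiment::assay(se)
    r1 <- cor(f, e["SLC2A1", ]); r3 <- cor(f, e["SLC2A3", ])
    expect_lt(r1, -0.5)
    expect_gt(r3, 0.5)
  }
})

test_that("bulk expression values are finite, non-negative and labeled", {
  se <- generateBulkCohort(bulkSimParams(n_samples = 30, seed = 3))
  e <- SummarizedExperiment::assay(se)
  expect_true(all(is.finite(e)) && all(e >= 0))
  cd <- SummarizedExperiment::colData(se)
  expect_true(all(cd$immune_fraction_truth >= 0 &
                    cd$immune_fraction_truth <= 1))
  expect_true(all(cd$tlr_max > 0))
  sigs <- S4Vectors::metadata(se)$signatures
  allGenes <- unlist(geneSets(sigs))
  expect_false(anyDuplicated(allGenes) > 0)  # sets disjoint by construction
  expect_true(all(allGenes %in% rownames(e)))
})

test_that("null response slope decouples response from the baseline ratio", {
  p <- responseSimParams(n_patients = 2000, response_slope = 0, seed = 5)
  co <- generateResponseCohort(p)
  pre <- glutRatio(co)
  pre <- pre[pre$timepoint == "pre", ]
  q <- cut(pre$ratio, quantile(pre$ratio, 0:4 / 4), include.lowest = TRUE)
  tab <- table(q, pre$response == "PR_CR")
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.05)
})

test_that("zero pullback and zero change noise keep the ratio fixed", {
  p <- responseSimParams(n_patients = 50, change_pullback = 0,
                         change_noise_sd = 0, seed = 4)
  rt <- glutRatio(generateResponseCohort(p), pseudocount = 0)
  pre <- rt[rt$timepoint == "pre", ]
  on <- rt[rt$timepoint == "on", ]
  expect_equal(on$ratio[match(pre$patient_id, on$patient_id)], pre$ratio,
               tolerance = 1e-12)
})

test_that("baseline ratio and percent change are negatively coupled in reactive patients", {
  co <- generateResponseCohort(responseSimParams(n_patients = 1000, seed = 7))
  wf <- waterfallTable(co)
  reactive <- wf$table$response %in% c("SD", "PR_CR")
  r <- pearsonCorr(wf$table$baseline[reactive], wf$table$change[reactive])$r
  expect_lte(r, -0.4)
})

test_that("large-sample hazard-ratio recovery is within 10% of the target", {
  p <- responseSimParams(n_patients = 5000, hazard_coef = -0.3, seed = 11)
  co <- generateResponseCohort(p)
  pre <- glutRatio(co); pre <- pre[pre$timepoint == "pre", ]
  z <- (log(pre$ratio) - p$ratio_logmean) / p$ratio_logsd
  hr <- coxAssoc(z, pre$pfs_time, pre$event)$hr
  expect_lt(abs(hr - exp(-0.3)) / exp(-0.3), 0.10)
})

test_that("type-restricted GLUT means produce zero counts where disabled", {
  m <- matrix(c(8, 5, 0, 6, 1), ncol = 1,
              dimnames = list(c("marker_cancer", "GLUT1", "GLUT3",
                                "Glycolysis", "Background"), "cancer"))
  p <- scSimParams(n_cells = 200, type_proportions = c(cancer = 1),
                   type_expression_means = m, seed = 2)
  sce <- generateScCohort(p)
  expect_true(all(SummarizedExperiment::assay(sce)["SLC2A3", ] == 0))
})

test_that("Poisson-limit counts match the library-size-scaled mean", {
  p <- scSimParams(n_cells = 5000, poisson = TRUE, seed = 6)
  sce <- generateScCohort(p)
  counts <- SummarizedExperiment::assay(sce)
  ct <- SummarizedExperiment::colData(sce)$cell_type
  cancer <- ct == "cancer"
  # per-cell library factors are recoverable from the background block mean
  expected <- 5 * exp(p$libsize_logmean + p$libsize_logsd^2 / 2)
  observed <- mean(counts["SLC2A1", cancer])
  expect_lt(abs(observed - expected) / expected, 0.05)
})

test_that("cell-type allocation follows the requested proportions exactly", {
  p <- scSimParams(n_cells = 1000, seed = 1)
  tab <- table(SummarizedExperiment::colData(generateScCohort(p))$cell_type)
  expect_identical(as.integer(tab[names(p$type_proportions)]),
                   as.integer(p$type_proportions * 1000))
})
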