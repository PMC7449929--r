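# Synthetic cohort generators. These define the study conditions every
# downstream stage is exercised against: a bimodal immune-fraction bulk
# cohort whose PET uptake is the sum of the cancer-cell GLUT1 and
# immune-cell GLUT3 contributions, an immunotherapy cohort whose response
# probability rises with the GLUT3/GLUT1 ratio, and a multi-cell-type
# single-cell count matrix with type-restricted GLUT expression.

# internal expression scales (raw, pre log-normalization)
.SIG_LEVEL <- 3   # immune / glycolysis signature genes at full activation
.BG_LEVEL <- 1    # background genes
.TLR_FLOOR <- 0.05

#' Parameters of the bulk cohort generator
#'
#' @param n_samples Number of samples (>= 4).
#' @param n_genes Total genes; must leave room for the signature genes and
#'   the two GLUT genes.
#' @param immune_mix_weight Mixture weight of the immune-poor component in
#'   \[0, 1\].
#' @param poor_beta,rich_beta Beta shape pairs \code{c(a, b)} of the
#'   immune-poor and immune-rich latent immune-fraction components.
#' @param glut1_cancer_mean,glut3_immune_mean Cell-intrinsic raw GLUT1
#'   (cancer) and GLUT3 (immune) expression levels.
#' @param pet_coefs Non-negative \code{c(c0, c1, c3)}: intercept and weights
#'   of the cancer-GLUT1 and immune-GLUT3 contributions to TLRmax.
#' @param pet_noise_sd SD of the additive Gaussian TLRmax noise.
#' @param expr_noise_sd SD of the multiplicative lognormal expression noise
#'   (on the log scale).
#' @param signature_size Genes per cell-type signature.
#' @param seed Integer RNG seed.
#'
#' @return A validated list of class \code{BulkSimParams}.
#' @seealso [generateBulkCohort()]
#' @export
bulkSimParams <- function(n_samples = 200L, n_genes = 400L,
                          immune_mix_weight = 0.7,
                          poor_beta = c(2, 8), rich_beta = c(8, 3),
                          glut1_cancer_mean = 5, glut3_immune_mean = 5,
                          pet_coefs = c(0.5, 0.3, 0.3),
                          pet_noise_sd = 0.2, expr_noise_sd = 0.5,
                          signature_size = 8L, seed = 1L) {
  p <- list(
    n_samples = .assertCount(n_samples, "n_samples", min = 4L),
    n_genes = .assertCount(n_genes, "n_genes"),
    immune_mix_weight = .assertNumber(immune_mix_weight, "immune_mix_weight", 0, 1),
    poor_beta = poor_beta, rich_beta = rich_beta,
    glut1_cancer_mean = .assertNumber(glut1_cancer_mean, "glut1_cancer_mean", 0, strict = TRUE),
    glut3_immune_mean = .assertNumber(glut3_immune_mean, "glut3_immune_mean", 0, strict = TRUE),
    pet_coefs = pet_coefs,
    pet_noise_sd = .assertNumber(pet_noise_sd, "pet_noise_sd", 0),
    expr_noise_sd = .assertNumber(expr_noise_sd, "expr_noise_sd", 0),
    signature_size = .assertCount(signature_size, "signature_size"),
    seed = .assertCount(seed, "seed", min = 0L))
  for (nm in c("poor_beta", "rich_beta"))
    if (length(p[[nm]]) != 2L || any(!is.finite(p[[nm]])) || any(p[[nm]] <= 0))
      .stopf("invalidParameter", "'%s' must be two positive Beta shapes", nm)
  if (length(p$pet_coefs) != 3L || any(!is.finite(p$pet_coefs)) ||
      any(p$pet_coefs < 0))
    .stopf("invalidParameter", "'pet_coefs' must be three non-negative reals")
  needed <- 11L * p$signature_size + 2L
  if (p$n_genes < needed)
    .stopf("invalidParameter",
           "n_genes must be >= %d to hold the signature and GLUT genes", needed)
  structure(p, class = "BulkSimParams")
}

# analytic crossing point of the two weighted Beta components; latent truth
# label is immune-rich iff f exceeds it
.betaMixtureCrossing <- function(w, poor, rich) {
  if (w >= 1) return(Inf)
  if (w <= 0) return(-Inf)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 4001L)
  g <- w * stats::dbeta(grid, poor[1], poor[2]) -
    (1 - w) * stats::dbeta(grid, rich[1], rich[2])
  mPoor <- poor[1] / (poor[1] + poor[2])
  mRich <- rich[1] / (rich[1] + rich[2])
  between <- grid > min(mPoor, mRich) & grid < max(mPoor, mRich)
  idx <- which(between)[which(diff(sign(g[between])) != 0)]
  if (!length(idx)) {
    # components too close to cross between their means; fall back to the
    # midpoint of the means
    return((mPoor + mRich) / 2)
  }
  grid[idx[1]]
}

#' Generate a bulk cohort with paired PET readouts
#'
#' For each sample a latent immune fraction f is drawn from a two-component
#' Beta mixture. Bulk GLUT1 is proportional to (1 - f) times the
#' cancer-intrinsic level, bulk GLUT3 to f times the immune-intrinsic level,
#' each with multiplicative lognormal noise; immune cell-type signature genes
#' scale with f and glycolysis genes with (1 - f). The PET readout is
#' \deqn{TLRmax = c_0 + c_1 (1-f) G_1 + c_3 f G_3 + \epsilon,}
#' the sum of the realized cancer GLUT1 and immune GLUT3 contributions plus
#' Gaussian noise, truncated at a small positive floor. Expression is stored
#' log-normalized (log1p of the raw level).
#'
#' @param params A [bulkSimParams()] object.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{logexpr} (genes x samples), \code{rowData(group)} gene grouping,
#'   \code{colData} columns \code{immune_fraction_truth}, \code{tlr_max},
#'   \code{cluster_truth}, and the signature collection, parameters and
#'   analytic mixture crossing point in \code{metadata()}.
#' @examples
#' se <- generateBulkCohort(bulkSimParams(n_samples = 20, seed = 1))
#' SummarizedExperiment::colData(se)[1:3, ]
#' @export
generateBulkCohort <- function(params = bulkSimParams()) {
  if (!inherits(params, "BulkSimParams"))
    params <- do.call(bulkSimParams, as.list(params))
  p <- params
  sigs <- defaultSignatureCollection(p$signature_size)
  sigGenes <- unlist(geneSets(sigs), use.names = FALSE)
  nBg <- p$n_genes - length(sigGenes) - 2L
  genes <- c(sigGenes, "SLC2A1", "SLC2A3",
             if (nBg > 0) paste0("BG.g", seq_len(nBg)))
  group <- c(rep(names(geneSets(sigs)), each = p$signature_size),
             "GLUT1", "GLUT3", rep("Background", nBg))

  .withSeed(p$seed, {
    n <- p$n_samples
    comp <- runif(n) < p$immune_mix_weight
    f <- ifelse(comp,
                rbeta(n, p$poor_beta[1], p$poor_beta[2]),
                rbeta(n, p$rich_beta[1], p$rich_beta[2]))

    # raw means: immune signature genes track f, glycolysis tracks 1 - f
    mu <- matrix(.BG_LEVEL, nrow = length(genes), ncol = n,
                 dimnames = list(genes, sprintf("S%03d", seq_len(n))))
    for (nm in immuneSignatures(sigs))
      mu[geneSets(sigs)[[nm]], ] <-
        matrix(.SIG_LEVEL * (0.1 + 0.9 * f), nrow = p$signature_size,
               ncol = n, byrow = TRUE)
    mu[geneSets(sigs)$Glycolysis, ] <-
      matrix(.SIG_LEVEL * (0.1 + 0.9 * (1 - f)), nrow = p$signature_size,
             ncol = n, byrow = TRUE)

    # realized cell-intrinsic GLUT levels, shared between the expression
    # matrix and the PET model so uptake is the sum of the two contributions
    g1 <- p$glut1_cancer_mean * exp(rnorm(n, 0, p$expr_noise_sd))
    g3 <- p$glut3_immune_mean * exp(rnorm(n, 0, p$expr_noise_sd))
    raw <- mu * exp(matrix(rnorm(length(mu), 0, p$expr_noise_sd),
                           nrow = nrow(mu)))
    raw["SLC2A1", ] <- (1 - f) * g1
    raw["SLC2A3", ] <- f * g3

    tlr <- p$pet_coefs[1] +
      p$pet_coefs[2] * (1 - f) * g1 +
      p$pet_coefs[3] * f * g3 +
      rnorm(n, 0, p$pet_noise_sd)
    tlr <- pmax(tlr, .TLR_FLOOR)

    crossing <- .betaMixtureCrossing(p$immune_mix_weight,
                                     p$poor_beta, p$rich_beta)
    truth <- factor(ifelse(f > crossing, "immune-rich", "immune-poor"),
                    levels = c("immune-poor", "immune-rich"))

    SummarizedExperiment::SummarizedExperiment(
      assays = list(logexpr = log1p(raw)),
      rowData = S4Vectors::DataFrame(group = group, row.names = genes),
      colData = S4Vectors::DataFrame(
        immune_fraction_truth = f, tlr_max = tlr, cluster_truth = truth,
        row.names = colnames(mu)),
      metadata = list(signatures = sigs, params = p, crossing = crossing))
  })
}

#' Parameters of the immunotherapy response-cohort generator
#'
#' @param n_patients Number of patients (>= 10).
#' @param ratio_logmean,ratio_logsd Mean and SD of the baseline
#'   log(GLUT-ratio).
#' @param response_intercept,response_slope Logistic coefficients of the
#'   probability that a patient reacts to therapy (SD or PR/CR rather than
#'   PD), on the z-scale of the baseline log-ratio.
#' @param change_pullback Regression-to-baseline strength in \[0, 1\] applied
#'   to the on-treatment log-ratio of SD and PR/CR patients (PD patients keep
#'   their baseline up to noise).
#' @param change_noise_sd SD of the on-treatment log-ratio noise.
#' @param hazard_scale Baseline exponential hazard of progression (> 0).
#' @param hazard_coef Log-hazard change per unit z of the baseline log-ratio
#'   (negative: high GLUT-ratio is protective).
#' @param censor_horizon Administrative censoring time (> 0).
#' @param seed Integer RNG seed.
#'
#' @return A validated list of class \code{ResponseSimParams}.
#' @seealso [generateResponseCohort()]
#' @export
responseSimParams <- function(n_patients = 100L, ratio_logmean = 0,
                              ratio_logsd = 0.8, response_intercept = -0.3,
                              response_slope = 1.2, change_pullback = 0.6,
                              change_noise_sd = 0.2, hazard_scale = 0.08,
                              hazard_coef = -0.3, censor_horizon = 24,
                              seed = 1L) {
  p <- list(
    n_patients = .assertCount(n_patients, "n_patients", min = 10L),
    ratio_logmean = .assertNumber(ratio_logmean, "ratio_logmean"),
    ratio_logsd = .assertNumber(ratio_logsd, "ratio_logsd", 0, strict = TRUE),
    response_intercept = .assertNumber(response_intercept, "response_intercept"),
    response_slope = .assertNumber(response_slope, "response_slope"),
    change_pullback = .assertNumber(change_pullback, "change_pullback", 0),
    change_noise_sd = .assertNumber(change_noise_sd, "change_noise_sd", 0),
    hazard_scale = .assertNumber(hazard_scale, "hazard_scale", 0, strict = TRUE),
    hazard_coef = .assertNumber(hazard_coef, "hazard_coef"),
    censor_horizon = .assertNumber(censor_horizon, "censor_horizon", 0, strict = TRUE),
    seed = .assertCount(seed, "seed", min = 0L))
  structure(p, class = "ResponseSimParams")
}

#' Generate a paired pre/on-treatment immunotherapy cohort
#'
#' Baseline log(GLUT-ratio) is Normal(\code{ratio_logmean},
#' \code{ratio_logsd}). A patient reacts to therapy (irRECIST SD or PR/CR
#' rather than PD) with logistic probability increasing in the standardized
#' baseline log-ratio; reactive patients are split into PR/CR versus SD by a
#' second logistic draw with two-thirds of \code{response_slope}, so the
#' median baseline ratio orders PD < SD < PR/CR and a null slope decouples
#' every class from the baseline. The on-treatment log-ratio of SD and PR/CR patients is
#' pulled toward the population mean by \code{change_pullback} (immune influx
#' raises low ratios), while PD patients keep their baseline up to noise.
#' Progression-free survival is exponential with hazard
#' \code{hazard_scale * exp(hazard_coef * z(baseline))}, administratively
#' censored at \code{censor_horizon}.
#'
#' @param params A [responseSimParams()] object.
#' @return A long-format \code{data.frame} with one row per (patient,
#'   timepoint): \code{patient_id}, \code{timepoint} (\code{pre}/\code{on}),
#'   \code{glut1}, \code{glut3}, \code{response} (\code{PD}/\code{SD}/
#'   \code{PR_CR}), \code{pfs_time}, \code{event}.
#' @examples
#' head(generateResponseCohort(responseSimParams(n_patients = 12, seed = 7)))
#' @export
generateResponseCohort <- function(params = responseSimParams()) {
  if (!inherits(params, "ResponseSimParams"))
    params <- do.call(responseSimParams, as.list(params))
  p <- params
  .withSeed(p$seed, {
    n <- p$n_patients
    b <- rnorm(n, p$ratio_logmean, p$ratio_logsd)
    z <- (b - p$ratio_logmean) / p$ratio_logsd
    reactive <- runif(n) < stats::plogis(p$response_intercept +
                                           p$response_slope * z)
    # PR/CR vs SD split shares the baseline dependence (2/3 of the main
    # slope) so a null response_slope leaves every class independent of
    # the baseline ratio
    prcr <- runif(n) < stats::plogis(2 / 3 * p$response_slope * z)
    response <- factor(ifelse(!reactive, "PD",
                              ifelse(prcr, "PR_CR", "SD")),
                       levels = c("PD", "SD", "PR_CR"))
    pull <- ifelse(response == "PD", 0, p$change_pullback)
    on <- b - pull * (b - p$ratio_logmean) + rnorm(n, 0, p$change_noise_sd)

    rate <- p$hazard_scale * exp(p$hazard_coef * z)
    t <- rexp(n, rate)
    event <- t <= p$censor_horizon
    pfs <- pmin(t, p$censor_horizon)

    # ratio decomposed into two positive expression values per timepoint
    g1pre <- exp(rnorm(n, 0, 0.2)); g1on <- exp(rnorm(n, 0, 0.2))
    ids <- sprintf("P%03d", seq_len(n))
    data.frame(
      patient_id = rep(ids, 2L),
      timepoint = factor(rep(c("pre", "on"), each = n),
                         levels = c("pre", "on")),
      glut1 = c(g1pre, g1on),
      glut3 = c(g1pre * exp(b), g1on * exp(on)),
      response = rep(response, 2L),
      pfs_time = rep(pfs, 2L),
      event = rep(event, 2L),
      stringsAsFactors = FALSE)
  })
}

.SC_TYPES <- c(cancer = 0.2, myeloid = 0.3, tcell = 0.3,
               endothelial = 0.1, fibroblast = 0.1)

.defaultScMeans <- function(types) {
  groups <- c(paste0("marker_", types), "GLUT1", "GLUT3", "Glycolysis",
              "Background")
  m <- matrix(0.1, nrow = length(groups), ncol = length(types),
              dimnames = list(groups, types))
  for (t in types) m[paste0("marker_", t), t] <- 8
  m["GLUT1", ] <- ifelse(types == "cancer", 5, 0)
  m["GLUT3", ] <- ifelse(types %in% c("myeloid", "tcell", "endothelial"), 3, 0)
  m["Glycolysis", ] <- ifelse(types == "cancer", 6, 1)
  m["Background", ] <- 1
  m
}

#' Parameters of the single-cell cohort generator
#'
#' @param n_cells Number of cells (>= 100).
#' @param type_proportions Named numeric vector of cell-type fractions
#'   summing to 1 (tolerance 1e-9).
#' @param type_expression_means Optional numeric matrix of per-gene-group,
#'   per-type raw expression means (rows \code{marker_<type>}, \code{GLUT1},
#'   \code{GLUT3}, \code{Glycolysis}, \code{Background}; columns the cell
#'   types). Defaults restrict GLUT1 to cancer cells and GLUT3 to
#'   myeloid/T/endothelial cells.
#' @param nb_dispersion Negative-binomial size parameter (> 0).
#' @param libsize_logmean,libsize_logsd Lognormal per-cell library-size
#'   factor parameters.
#' @param poisson Logical; draw Poisson counts (the infinite-dispersion
#'   limit) instead of negative binomial.
#' @param markers_per_type,n_glycolysis,n_background Gene-group sizes.
#' @param seed Integer RNG seed.
#'
#' @return A validated list of class \code{ScSimParams}.
#' @seealso [generateScCohort()]
#' @export
scSimParams <- function(n_cells = 2000L, type_proportions = .SC_TYPES,
                        type_expression_means = NULL, nb_dispersion = 2,
                        libsize_logmean = 0, libsize_logsd = 0.3,
                        poisson = FALSE, markers_per_type = 5L,
                        n_glycolysis = 10L, n_background = 50L, seed = 1L) {
  if (is.null(names(type_proportions)) || any(!nzchar(names(type_proportions))))
    .stopf("invalidParameter", "'type_proportions' must be named")
  if (any(type_proportions < 0) ||
      abs(sum(type_proportions) - 1) > 1e-9)
    .stopf("invalidParameter",
           "'type_proportions' must be non-negative and sum to 1 (1e-9)")
  types <- names(type_proportions)
  if (is.null(type_expression_means))
    type_expression_means <- .defaultScMeans(types)
  if (!identical(colnames(type_expression_means), types))
    .stopf("invalidParameter",
           "'type_expression_means' columns must match the cell types")
  if (any(type_expression_means < 0))
    .stopf("invalidParameter", "expression means must be non-negative")
  structure(list(
    n_cells = .assertCount(n_cells, "n_cells", min = 100L),
    type_proportions = type_proportions,
    type_expression_means = type_expression_means,
    nb_dispersion = .assertNumber(nb_dispersion, "nb_dispersion", 0, strict = TRUE),
    libsize_logmean = .assertNumber(libsize_logmean, "libsize_logmean"),
    libsize_logsd = .assertNumber(libsize_logsd, "libsize_logsd", 0),
    poisson = isTRUE(poisson),
    markers_per_type = .assertCount(markers_per_type, "markers_per_type"),
    n_glycolysis = .assertCount(n_glycolysis, "n_glycolysis"),
    n_background = .assertCount(n_background, "n_background"),
    seed = .assertCount(seed, "seed", min = 0L)), class = "ScSimParams")
}

#' Generate a multi-cell-type single-cell count matrix
#'
#' Draws negative-binomial (or Poisson, in the infinite-dispersion limit)
#' read counts with a lognormal per-cell library-size factor. GLUT1
#' (SLC2A1) has a nonzero mean only in cancer cells; GLUT3 (SLC2A3) only in
#' myeloid, T and endothelial cells; each type carries its own marker-gene
#' group and glycolysis genes are enriched in cancer cells. Cell-type counts
#' follow the requested proportions exactly (largest-remainder rounding).
#'
#' @param params A [scSimParams()] object.
#' @return A [SingleCellExperiment::SingleCellExperiment] with sparse assay
#'   \code{counts} (genes x cells), \code{colData(cell_type)} and
#'   \code{rowData(group)}.
#' @examples
#' sce <- generateScCohort(scSimParams(n_cells = 200, seed = 1))
#' table(SingleCellExperiment::colData(sce)$cell_type)
#' @export
generateScCohort <- function(params = scSimParams()) {
  if (!inherits(params, "ScSimParams"))
    params <- do.call(scSimParams, as.list(params))
  p <- params
  types <- names(p$type_proportions)
  genes <- c(unlist(lapply(types, function(t)
    paste0(toupper(substr(t, 1, 3)), ".mk", seq_len(p$markers_per_type)))),
    "SLC2A1", "SLC2A3",
    paste0("GLYC.g", seq_len(p$n_glycolysis)),
    paste0("BG.g", seq_len(p$n_background)))
  group <- c(rep(paste0("marker_", types), each = p$markers_per_type),
             "GLUT1", "GLUT3",
             rep("Glycolysis", p$n_glycolysis),
             rep("Background", p$n_background))

  # exact largest-remainder allocation of cells to types
  nPer <- floor(p$type_proportions * p$n_cells)
  rem <- p$n_cells - sum(nPer)
  if (rem > 0) {
    frac <- p$type_proportions * p$n_cells - nPer
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    nPer[bump] <- nPer[bump] + 1L
  }
  cellType <- rep(types, nPer)

  .withSeed(p$seed, {
    lib <- rlnorm(p$n_cells, p$libsize_logmean, p$libsize_logsd)
    geneMeans <- p$type_expression_means[group, , drop = FALSE]
    counts <- matrix(0L, nrow = length(genes), ncol = p$n_cells,
                     dimnames = list(genes, sprintf("C%05d", seq_len(p$n_cells))))
    for (j in seq_len(p$n_cells)) {
      mu <- geneMeans[, cellType[j]] * lib[j]
      counts[, j] <- if (p$poisson) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = p$nb_dispersion)
    }
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
      rowData = S4Vectors::DataFrame(group = group, row.names = genes),
      colData = S4Vectors::DataFrame(cell_type = cellType,
                                     row.names = colnames(counts)),
      metadata = list(params = p))
  })
}
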