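# Independent oracle implementations used to cross-check the package's
# statistics, plus small fixture builders. The oracles deliberately use
# different computational routes than the implementation.

# explicit-loop running-sum enrichment score over the ranked gene list
bruteSsgsea <- function(expr, geneSet, alpha) {
  ids <- names(expr)
  ord <- ids[order(-expr, ids, method = "radix")]
  n <- length(ord)
  inSet <- ord %in% geneSet
  denomIn <- 0
  for (i in seq_len(n)) if (inSet[i]) denomIn <- denomIn + (n - i + 1)^alpha
  nOut <- sum(!inSet)
  score <- 0; cumIn <- 0; cumOut <- 0
  for (i in seq_len(n)) {
    if (inSet[i]) cumIn <- cumIn + (n - i + 1)^alpha else cumOut <- cumOut + 1
    score <- score + cumIn / denomIn - cumOut / nOut
  }
  score
}

# closed-form product-moment correlation and t-based p
oraclePearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# exact Mann-Whitney two-sided p via pairwise-count U over all label
# arrangements (different route than the implementation's rank sums)
oracleMWp <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  ustat <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mu <- n1 * (n - n1) / 2
  uObs <- ustat(seq_len(n1))
  idx <- utils::combn(n, n1)
  uAll <- apply(idx, 2, ustat)
  mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
}

# hypergeometric-increment log-rank chi-square statistic
oracleLogrank <- function(time, event, inGroup) {
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event]))) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & inGroup)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & inGroup)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Breslow partial log-likelihood maximized on a grid-free 1D search
bruteCoxBreslow <- function(x, time, event) {
  ll <- function(b) {
    s <- 0
    for (i in which(event)) {
      risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  stats::optimize(ll, c(-10, 10), maximum = TRUE)$maximum
}

# spherical phantom: uniform sphere of a given SUV on a constant background
spherePhantom <- function(dimVox = c(60, 60, 60), spacing = 1,
                          center = c(20, 20, 20), radiusMm = 10,
                          sphereSuv = 10, background = 1) {
  suv <- array(background, dim = dimVox)
  cx <- (slice.index(suv, 1) - 0.5) * spacing
  cy <- (slice.index(suv, 2) - 0.5) * spacing
  cz <- (slice.index(suv, 3) - 0.5) * spacing
  d2 <- (cx - center[1])^2 + (cy - center[2])^2 + (cz - center[3])^2
  suv[d2 <= radiusMm^2] <- sphereSuv
  suv
}

# default bulk cohorts are reused across tests; cache the scored result
.cohortCache <- new.env(parent = emptyenv())
scoredBulkCohort <- function(seed) {
  key <- as.character(seed)
  if (is.null(.cohortCache[[key]])) {
    se <- generateBulkCohort(bulkSimParams(seed = seed))
    et <- suppressMessages(
      scoreCohort(se, S4Vectors::metadata(se)$signatures))
    .cohortCache[[key]] <- list(se = se, et = et)
  }
  .cohortCache[[key]]
}

bulkFeatures <- function(se) {
  expr <- SummarizedExperiment::assay(se)
  f <- cbind(GLUT1 = expr["SLC2A1", ], GLUT3 = expr["SLC2A3", ])
  rownames(f) <- colnames(expr)
  f
}
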