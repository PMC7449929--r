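test_that("GLUT-ratio conventions behave as defined", {
  co <- data.frame(glut1 = c(2, 3, 4), glut3 = c(2, 3, 4))
  expect_equal(glutRatio(co)$ratio, rep(1, 3), tolerance = 1e-6)
  # proportional genes give a constant ratio as the pseudocount vanishes
  co2 <- data.frame(glut1 = c(1, 2, 5), glut3 = 2.5 * c(1, 2, 5))
  expect_equal(glutRatio(co2, pseudocount = 0)$ratio, rep(2.5, 3))
  # z-difference: mean 0 by construction, matches hand arithmetic
  co3 <- data.frame(glut1 = c(1, 2, 3, 4), glut3 = c(4, 1, 3, 2),
                    timepoint = rep("pre", 4))
  zd <- glutRatio(co3, mode = "zdiff")$ratio
  expect_equal(mean(zd), 0)
  z <- function(v) (v - mean(v)) / sd(v)
  expect_equal(zd, z(co3$glut3) - z(co3$glut1))
  # on a cohort whose transporters share sampling depth (positively
  # correlated), the z-difference variance stays at most 2
  co4 <- generateResponseCohort(responseSimParams(n_patients = 200, seed = 9))
  zd4 <- glutRatio(co4, mode = "zdiff")$ratio
  expect_equal(mean(zd4[co4$timepoint == "pre"]), 0)
  expect_lte(var(zd4[co4$timepoint == "pre"]), 2 + 1e-12)
})

test_that("percent change is relative to baseline", {
  expect_equal(percentChange(2, 3), 50)
  expect_equal(percentChange(4, 4), 0)
  expect_equal(percentChange(4, 1), -75)
  expect_error(percentChange(0, 1), class = "undefinedChange")
})

test_that("exact Mann-Whitney p matches enumeration and wilcox.test", {
  # canonical separated case: U = 0, p = 2/20
  got <- compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(got$statistic, 0)
  expect_equal(got$p, 0.1)
  set.seed(31)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    got <- compareGroups(c(x, y), rep(c("a", "b"), c(n1, n2)))
    expect_equal(got$p, oracleMWp(x, y), tolerance = 1e-12)
    # tie-free exact two-sided p agrees with the distribution-based test
    expect_equal(got$p,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # ties: enumeration still applies
  x <- c(1, 1, 2); y <- c(1, 2, 2, 3)
  got <- compareGroups(c(x, y), rep(c("a", "b"), c(3, 4)))
  expect_equal(got$p, oracleMWp(x, y), tolerance = 1e-12)
})

test_that("identical groups give p near 1 and three groups use Kruskal-Wallis", {
  x <- c(1, 2, 3, 4)
  got <- compareGroups(c(x, x), rep(c("a", "b"), each = 4))
  expect_gte(got$p, 0.9)
  set.seed(3)
  kw <- compareGroups(rnorm(30), rep(c("PD", "SD", "PR_CR"), each = 10))
  expect_identical(kw$method, "kruskal-wallis")
  expect_true(kw$p > 0 && kw$p <= 1)
  expect_error(compareGroups(1:4, c("a", "a", "a", "b")),
               class = "invalidParameter")
})

test_that("log-rank statistic matches the hypergeometric-increment oracle", {
  vals <- c(1, 1, 1, 10, 10, 10)  # mean split: first three low
  times <- c(1, 2, 3, 4, 5, 6)
  events <- rep(TRUE, 6)
  got <- kmLogrank(vals, times, events)
  want <- oracleLogrank(times, events, got$group == "high")
  expect_equal(got$chisq, want, tolerance = 1e-10)
  expect_equal(got$p, pchisq(want, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("identically distributed split groups give log-rank p near 1", {
  times <- rep(c(1, 2, 3, 4, 5), 2)
  events <- rep(TRUE, 10)
  vals <- rep(c(0, 1), each = 5)  # arbitrary split, same survival
  got <- kmLogrank(vals, times, events)
  expect_gte(got$p, 0.95)
})

test_that("a protective hazard coefficient orders the KM medians", {
  co <- generateResponseCohort(responseSimParams(n_patients = 400, seed = 2))
  pre <- glutRatio(co); pre <- pre[pre$timepoint == "pre", ]
  km <- kmLogrank(pre$ratio, pre$pfs_time, pre$event)
  med <- summary(km$fit)$table[, "median"]
  expect_gte(med[["group=high"]], med[["group=low"]])
})

test_that("Cox fit matches a brute-force partial likelihood with ties", {
  x <- rep(c(0, 1), each = 3)
  times <- c(2, 3, 3, 1, 4, 4)
  events <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  got <- coxAssoc(c(x, x[1:4]), c(times, times[1:4]),
                  c(events, events[1:4]))
  want <- bruteCoxBreslow(c(x, x[1:4]), c(times, times[1:4]),
                          c(events, events[1:4]))
  expect_equal(got$coef, want, tolerance = 1e-4)
})

test_that("degenerate survival inputs raise typed errors", {
  expect_error(coxAssoc(rnorm(5), rexp(5), rep(TRUE, 5)),
               class = "invalidParameter")
  expect_error(coxAssoc(rnorm(20), rexp(20), rep(FALSE, 20)),
               class = "invalidParameter")
  expect_error(kmLogrank(rnorm(10), rexp(10), rep(FALSE, 10)),
               class = "invalidParameter")
  # monotone likelihood: perfect separation of event times
  x <- c(rep(0, 10), rep(1, 10))
  t <- c(seq(1, 10), seq(100, 109))
  expect_error(coxAssoc(x, t, rep(TRUE, 20)), class = "coxNonconvergence")
})

test_that("waterfall table pairs timepoints and surfaces undefined correlations", {
  co <- generateResponseCohort(responseSimParams(n_patients = 50, seed = 3))
  wf <- waterfallTable(co)
  expect_setequal(wf$table$patient_id, unique(co$patient_id))
  expect_false(is.unsorted(-wf$table$change))
  expect_true(all(c("overall", "PD") %in% wf$correlations$group))

  # pre == on: all changes zero, correlation surfaced as warning + NA
  flat <- data.frame(patient_id = rep(sprintf("P%d", 1:5), 2),
                     timepoint = rep(c("pre", "on"), each = 5),
                     glut1 = 1, glut3 = rep(c(1, 2, 3, 4, 5), 2),
                     response = "SD")
  w2 <- capture_warnings(wf2 <- waterfallTable(flat))
  expect_true(all(grepl("skipped", w2)))
  expect_true(all(wf2$table$change == 0))
  expect_true(is.na(wf2$correlations$r[wf2$correlations$group == "overall"]))

  one <- flat[flat$patient_id == "P1", ]
  w3 <- capture_warnings(wf3 <- waterfallTable(one))
  expect_true(all(grepl("skipped", w3)))
  expect_identical(nrow(wf3$table), 1L)
})
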