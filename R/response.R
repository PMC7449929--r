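# The GLUT3/GLUT1 ratio biomarker and its response-group and survival
# analyses.

#' Per-sample GLUT-ratio
#'
#' The GLUT-ratio is the ratio of GLUT3 to GLUT1 expression, a surrogate
#' for the relative glucose-metabolic activity of immune versus cancer
#' cells. Two conventions are supported: \code{"ratio"} divides the
#' (log-normalized) expression values directly, with a pseudocount guarding
#' zero GLUT1; \code{"zdiff"} is the z-score of GLUT3 minus the z-score of
#' GLUT1, standardized across the samples of the same timepoint (the
#' convention for cohorts distributed as z-scores).
#'
#' @param cohort A \code{data.frame} with numeric columns \code{glut1} and
#'   \code{glut3}, and (for \code{zdiff}) a \code{timepoint} column defining
#'   the standardization groups.
#' @param mode \code{"ratio"} (default) or \code{"zdiff"}.
#' @param pseudocount Small positive value added to both genes in ratio
#'   mode (default 1e-6).
#' @return The cohort with an added numeric \code{ratio} column.
#' @export
glutRatio <- function(cohort, mode = c("ratio", "zdiff"),
                      pseudocount = 1e-6) {
  mode <- match.arg(mode)
  if (!all(c("glut1", "glut3") %in% names(cohort)))
    .stopf("invalidParameter", "'cohort' needs 'glut1' and 'glut3' columns")
  if (any(!is.finite(cohort$glut1)) || any(!is.finite(cohort$glut3)))
    .stopf("invalidParameter", "expression values must be finite")
  if (mode == "ratio") {
    .assertNumber(pseudocount, "pseudocount", 0)
    if (any(cohort$glut1 + pseudocount <= 0))
      .stopf("invalidParameter",
             "glut1 + pseudocount must be positive in ratio mode")
    cohort$ratio <- (cohort$glut3 + pseudocount) /
      (cohort$glut1 + pseudocount)
  } else {
    grp <- if ("timepoint" %in% names(cohort)) cohort$timepoint
    else rep("all", nrow(cohort))
    z <- function(v) {
      s <- sd(v)
      if (s == 0) .stopf("undefinedCorrelation",
                         "zero variance; z-scores undefined")
      (v - mean(v)) / s
    }
    cohort$ratio <- NA_real_
    for (g in unique(grp)) {
      idx <- grp == g
      cohort$ratio[idx] <- z(cohort$glut3[idx]) - z(cohort$glut1[idx])
    }
  }
  cohort
}

#' Percent change of a biomarker between timepoints
#'
#' @param pre,on Numeric vectors of baseline and on-treatment values;
#'   \code{pre} must be positive (percent change is undefined at 0).
#' @return \code{100 * (on - pre) / pre}.
#' @examples
#' percentChange(2, 3)   # +50
#' percentChange(4, 1)   # -75
#' @export
percentChange <- function(pre, on) {
  if (any(pre == 0))
    .stopf("undefinedChange", "percent change undefined for pre = 0")
  100 * (on - pre) / pre
}

# exact Mann-Whitney U two-sided p by enumeration over all subsets of the
# pooled midranks (tie-safe); two-sided as P(|U - n1 n2 / 2| >= observed)
.mwExact <- function(r, n1) {
  n <- length(r)
  n2 <- n - n1
  offset <- n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  uObs <- sum(r[seq_len(n1)]) - offset
  idx <- combn(n, n1)
  uAll <- colSums(matrix(r[idx], nrow = n1)) - offset
  mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
}

#' Compare a biomarker across response groups
#'
#' Two groups: Mann-Whitney U test — exact (complete enumeration of label
#' arrangements, valid with ties) when the combined n is at most 12,
#' otherwise the normal approximation with tie-corrected variance (no
#' continuity correction). Three or more groups: Kruskal-Wallis H with the
#' chi-square p-value.
#'
#' @param values Numeric biomarker values (e.g. GLUT-ratios).
#' @param groups Group labels, at least 2 members per group.
#' @param exactMaxN Combined-n cutoff for the exact two-group test
#'   (default 12).
#' @return List with \code{statistic} (U or H), \code{p}, \code{method}.
#' @examples
#' compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))  # p = 0.1
#' @export
compareGroups <- function(values, groups, exactMaxN = 12L) {
  g <- factor(groups)
  tab <- table(g)
  if (any(tab == 0L) || nlevels(g) < 2L)
    .stopf("invalidParameter", "need at least two non-empty groups")
  if (any(tab < 2L))
    .stopf("invalidParameter", "every group needs at least 2 members")
  if (any(!is.finite(values)))
    .stopf("invalidParameter", "'values' must be finite")

  if (nlevels(g) >= 3L) {
    kt <- kruskal.test(values, g)
    return(list(statistic = unname(kt$statistic), p = kt$p.value,
                method = "kruskal-wallis"))
  }

  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))           # midranks under ties
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n <= exactMaxN) {
    p <- .mwExact(r, n1)
    return(list(statistic = u, p = p, method = "mann-whitney exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u - mu) / sqrt(sigma2)
  list(statistic = u, p = 2 * pnorm(-abs(z)),
       method = "mann-whitney normal approximation")
}

#' Kaplan-Meier curves and log-rank test split at the mean biomarker value
#'
#' Patients are split into high and low groups at the cohort mean of the
#' biomarker (high: strictly greater). Product-limit survival curves are
#' estimated per group and the groups compared by the log-rank test.
#'
#' @param values Numeric per-patient biomarker (e.g. baseline GLUT-ratio).
#' @param times Non-negative follow-up times.
#' @param events Logical (or 0/1) progression/event indicators; at least
#'   one event required.
#' @return List with \code{fit} (a \code{survival::survfit} object),
#'   \code{curves} (data.frame of per-group step coordinates),
#'   \code{chisq}, \code{p}, \code{split} (the mean used) and
#'   \code{group} (the factor).
#' @export
kmLogrank <- function(values, times, events) {
  events <- as.logical(events)
  if (length(values) != length(times) || length(times) != length(events))
    .stopf("invalidParameter", "inputs must have equal length")
  if (!any(events))
    .stopf("invalidParameter", "log-rank requires at least one event")
  split <- mean(values)
  group <- factor(ifelse(values > split, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) < 2L))
    .stopf("invalidParameter", "mean split leaves a group with < 2 patients")
  fit <- survival::survfit(survival::Surv(times, events) ~ group)
  sd1 <- survival::survdiff(survival::Surv(times, events) ~ group)
  curves <- data.frame(
    group = rep(sub("^group=", "", names(fit$strata)),
                fit$strata),
    time = fit$time, surv = fit$surv,
    n_risk = fit$n.risk, n_event = fit$n.event,
    stringsAsFactors = FALSE)
  list(fit = fit, curves = curves, chisq = unname(sd1$chisq),
       p = pchisq(sd1$chisq, df = 1, lower.tail = FALSE),
       split = split, group = group)
}

#' Univariate Cox proportional-hazards association
#'
#' Single-covariate proportional-hazards fit by partial-likelihood
#' maximization with Breslow tie handling; reports the hazard ratio per
#' unit of the biomarker with the Wald 95\% confidence interval and
#' p-value. Non-convergence or a monotone likelihood (infinite
#' coefficient) raises a \code{coxNonconvergence} error.
#'
#' @param values Numeric per-patient biomarker, n >= 10.
#' @param times Non-negative follow-up times.
#' @param events Logical event indicators, at least 3 events.
#' @return List with \code{hr}, \code{ci} (length 2), \code{p},
#'   \code{coef}, \code{se}, \code{n}, \code{events}.
#' @export
coxAssoc <- function(values, times, events) {
  events <- as.logical(events)
  if (length(values) < 10L)
    .stopf("invalidParameter", "Cox fit requires at least 10 patients")
  if (sum(events) < 3L)
    .stopf("invalidParameter", "Cox fit requires at least 3 events")
  dat <- data.frame(x = values, t = times, e = events)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(t, e) ~ x, data = dat, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge|ran out", conditionMessage(w)))
        .stopf("coxNonconvergence", "Cox fit did not converge: %s",
               conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  beta <- co[1, "coef"]; se <- co[1, "se(coef)"]
  if (!is.finite(beta) || !is.finite(se) || se > 100)
    .stopf("coxNonconvergence", "Cox fit yielded an unstable coefficient")
  list(hr = exp(beta),
       ci = exp(beta + c(-1, 1) * qnorm(0.975) * se),
       p = co[1, "Pr(>|z|)"], coef = beta, se = se,
       n = nrow(dat), events = sum(events))
}

#' Waterfall table of baseline GLUT-ratio and its change on treatment
#'
#' Joins each patient's pre- and on-treatment GLUT-ratio, computes the
#' percent change (ratio mode) or absolute difference (zdiff mode, where
#' percent is undefined for signed values), and correlates the change with
#' the baseline ratio overall and within each response class — the analysis
#' showing that the ratio rises on treatment mainly in tumors that start
#' low, except in progressive disease.
#'
#' @param cohort Long-format response cohort (see
#'   [generateResponseCohort()]): columns \code{patient_id},
#'   \code{timepoint}, \code{glut1}, \code{glut3}, \code{response}.
#' @param mode,pseudocount Passed to [glutRatio()].
#' @return List with \code{table} (one row per paired patient:
#'   \code{patient_id}, \code{response}, \code{baseline}, \code{on},
#'   \code{change}; sorted by decreasing change for plotting) and
#'   \code{correlations} (data.frame of \code{group}, \code{r}, \code{p},
#'   \code{n}; \code{NA} with a warning where a correlation is undefined).
#' @export
waterfallTable <- function(cohort, mode = c("ratio", "zdiff"),
                           pseudocount = 1e-6) {
  mode <- match.arg(mode)
  need <- c("patient_id", "timepoint", "glut1", "glut3", "response")
  if (!all(need %in% names(cohort)))
    .stopf("invalidParameter", "cohort needs columns: %s",
           paste(need, collapse = ", "))
  rt <- glutRatio(cohort, mode = mode, pseudocount = pseudocount)
  pre <- rt[rt$timepoint == "pre", ]
  on <- rt[rt$timepoint == "on", ]
  shared <- intersect(pre$patient_id, on$patient_id)
  if (!length(shared))
    .stopf("invalidParameter", "no patients with both timepoints")
  pre <- pre[match(shared, pre$patient_id), ]
  on <- on[match(shared, on$patient_id), ]
  change <- if (mode == "ratio") percentChange(pre$ratio, on$ratio)
  else on$ratio - pre$ratio
  tab <- data.frame(patient_id = shared,
                    response = pre$response,
                    baseline = pre$ratio, on = on$ratio, change = change,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$change), ]

  corRow <- function(label, x, y) {
    pc <- tryCatch(pearsonCorr(x, y), glutTME_error = function(e) {
      warning(sprintf("correlation for '%s' skipped: %s", label,
                      conditionMessage(e)))
      list(r = NA_real_, p = NA_real_, n = length(x))
    })
    data.frame(group = label, r = pc$r, p = pc$p, n = pc$n,
               stringsAsFactors = FALSE)
  }
  cors <- corRow("overall", tab$baseline, tab$change)
  for (cl in levels(droplevels(factor(tab$response)))) {
    idx <- tab$response == cl
    cors <- rbind(cors, corRow(cl, tab$baseline[idx], tab$change[idx]))
  }
  list(table = tab, correlations = cors)
}
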