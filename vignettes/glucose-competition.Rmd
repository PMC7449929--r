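---
title: "Reciprocal glucose metabolism in the tumor microenvironment: models and methods"
author: "glutTME authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocal glucose metabolism in the tumor microenvironment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glutTME)
library(SummarizedExperiment)
```

# The scientific model

Tumors are mixtures of cancer cells and infiltrating immune, stromal and
endothelial cells, all competing for glucose. Cancer cells import glucose
mainly through GLUT1 (*SLC2A1*); activated immune cells — myeloid cells,
T-cells — rely predominantly on GLUT3 (*SLC2A3*). A tumor's total glucose
uptake, as imaged by FDG-PET, is then the sum of two cell-population
contributions. Writing $f$ for the immune fraction of a sample,

$$\mathrm{TLRmax} \;=\; c_0 + c_1\,(1-f)\,G_1 + c_3\,f\,G_3 + \varepsilon,$$

where $G_1$ and $G_3$ are the cell-intrinsic GLUT1 and GLUT3 expression
levels of the cancer and immune compartments and $\varepsilon$ is
measurement noise. Two consequences drive everything in this package:

1. **Reciprocal bulk correlations.** Bulk GLUT1 expression scales with
   $(1-f)$ and bulk GLUT3 with $f$, so an immune enrichment score
   correlates negatively with GLUT1 and positively with GLUT3.
2. **Cluster-conditional uptake correlations.** In immune-poor tumors
   (small $f$) the variance of uptake is dominated by the cancer term, so
   TLRmax tracks GLUT1; in immune-rich tumors it tracks GLUT3.

The GLUT3/GLUT1 expression ratio (**GLUT-ratio**) is then a one-number
surrogate of immune metabolic functionality, and is tested here as an
immunotherapy-response biomarker: response probability rising with the
baseline ratio, the ratio rising on treatment mainly in tumors that start
low (immune influx), and a protective survival association.

# Enrichment scoring and the ImmuneScore

`ssgseaScore()` ranks one sample's genes by descending expression and
accumulates the running-sum statistic

$$\mathrm{score} = \sum_i \big(P_{\mathrm{in}}(i) - P_{\mathrm{out}}(i)\big),
\qquad
P_{\mathrm{in}}(i) = \frac{\sum_{j \le i,\, j \in S} w_j}{\sum_{j \in S} w_j},
\quad w_j = r_j^{\alpha},$$

with $r_j$ the rank position counted from the bottom of the list and
$P_{\mathrm{out}}$ the cumulative fraction of non-set genes. The score
depends only on the ranking, hence is invariant under strictly monotone
transforms of expression; ties are broken by gene identifier so results
are deterministic regardless of input order.

Choices and defaults:

* **$\alpha = 0.25$** — the conventional single-sample GSEA weighting;
  $\alpha = 0$ gives the unweighted Kolmogorov–Smirnov-like sum. Both are
  tested against a brute-force reimplementation.
* **ImmuneScore** — the plain sum of the ten immune cell-type signature
  scores (B-cells, CD4+/CD8+ T-cells, dendritic cells, eosinophils,
  macrophages, monocytes, mast cells, neutrophils, NK cells). Additivity
  is enforced by the `EnrichmentTable` validity check at $10^{-9}$.
* **No cross-sample normalization by default**; a min–max rescale per
  signature is available behind `normalize = TRUE`.
* The default signature collection is generic and configurable (GMT in and
  out). Dedicated compendium scorers with spillover compensation are out
  of scope; the downstream logic needs only per-type scores and their sum.
  The "Glycolysis" set name is a configurable placeholder, not a curated
  pathway.

# Stratification

`kdeDensity()` wraps `stats::density` (Gaussian kernel, 512 grid points,
grid spanning the data range ± 3 bandwidths) with Silverman's
rule-of-thumb bandwidth — the `density()` default — or a fixed override.
`findSplitThreshold()` implements the valley rule: take the two local
maxima with the highest density and return the grid point of minimum
density strictly between them; among tied minima the smaller grid value
wins; a unimodal curve raises a typed `noValley` error so callers can fall
back to a fixed split (the acceptance script falls back to the mean).

Conventions worth stating:

* A sample exactly **at** the threshold is immune-poor (strict `>` for
  immune-rich); the boundary convention is arbitrary and documented.
* With more than two modes we restrict attention to the two highest and
  ignore the rest.
* Correlation p-values are reported raw, with no multiple-testing
  correction, matching how such panels are usually read (sign and
  magnitude, not inference per cell).

A known limitation: when the immune-poor mode is broad, the kernel
estimate can develop a secondary wiggle inside it, and the valley rule —
which takes the *lowest* interior minimum between the two dominant
maxima — may then land below the true class boundary. At the package's
default cohort conditions this occurs at a minority of seeds and shows up
as reduced (but still structurally correct) cluster agreement.

# PET quantification

Volumes are non-negative 3D SUV arrays with voxel spacing in mm; a voxel's
world position is its center $(v + 0.5)\,\mathrm{spacing}$, and spheres are
evaluated against voxel centers. Segmentation inside the tumor VOI uses an
adaptive threshold $T = B + \phi (P - B)$ with background $B$ = mean SUV in
a 2-voxel shell just outside the VOI (width configurable), peak $P$ = max
SUV inside it, and fraction $\phi = 0.41$ by default — a standard adaptive
choice, exposed as an argument since published adaptive methods differ.
The metabolic tumor volume is the voxel count times voxel volume;
`filterSmallTumors()` retains lesions strictly above 5 cm³, the cutoff
below which TLRmax is underestimated. `tlrMax()` divides the masked SUV
maximum by the liver VOI mean, making the readout invariant to global
rescaling of the volume. SUV values are taken as given; decay and weight
corrections are upstream of this package.

# Single-cell gating

Counts are log-normalized as $\ln(1 + 10^4 c / \mathrm{total})$ (natural
log; zeros preserved exactly, per-cell scale invariance exact). The
four-class GLUT gate applies one cutoff to both transporters — default
0.5 on the normalized scale, always reported in outputs, since published
scatter-gates rarely print their cutoff. Per-cell signature scores are
set means rather than rank-based running sums: with the sparsity of
droplet data, per-cell rank statistics are dominated by tie-breaking
noise. Clustering, embedding and marker finding are deliberately not
reimplemented; cell-type labels come from the generator or the user.

# Response biomarker

`glutRatio()` supports two conventions: the direct ratio
$(\mathrm{GLUT3} + \epsilon)/(\mathrm{GLUT1} + \epsilon)$ on
log-normalized values with pseudocount $\epsilon = 10^{-6}$ (zero GLUT1 is
not otherwise handled by the ratio definition), and the z-difference
$z(\mathrm{GLUT3}) - z(\mathrm{GLUT1})$ for cohorts distributed as
z-scores, standardized within timepoint so pre- and on-treatment samples
are each compared to their own cohort. Percent change is relative to
baseline, $100\,(\mathrm{on} - \mathrm{pre})/\mathrm{pre}$; in z-difference
mode the change is reported as an absolute difference because percent is
undefined for signed values. Responder means PR/CR; nonresponder pools PD
and SD.

Group comparisons use the Mann-Whitney U test — exact by complete
enumeration of label arrangements for combined $n \le 12$ (enumeration
rather than the standard distribution recursion because it remains valid
under ties), normal approximation with tie-corrected variance and no
continuity correction otherwise — and Kruskal-Wallis for three groups.
Survival uses Kaplan-Meier with the log-rank test at the **mean** ratio
split (an explicit convention of this analysis; the median is the more
common choice elsewhere) and univariate Cox proportional hazards with
Breslow tie handling; monotone likelihoods surface as a typed error
rather than a silently huge coefficient.

# The synthetic cohorts

The generators define the conditions under which the pipeline is tested.
They are first-class, seeded, and deterministic (bit-identical output for
identical parameters and seed).

**Bulk cohort.** The latent immune fraction $f_i$ follows a two-component
Beta mixture: immune-poor $\mathrm{Beta}(2, 8)$ with weight 0.7, immune-rich
$\mathrm{Beta}(8, 3)$ with weight 0.3 — a visibly imbalanced, bimodal
cohort. The true cluster label is $f_i$ above/below the analytic crossing
of the two weighted component densities (≈ 0.497 at defaults). Immune
signature genes scale linearly with $f_i$, glycolysis genes with $1 - f_i$,
GLUT1 with $(1-f_i) G_1$ and GLUT3 with $f_i G_3$, all with multiplicative
lognormal noise (sd 0.5 on the log scale) and stored as $\log(1 + x)$.
The PET readout uses the *same realized* $G_1, G_3$ draws in the uptake
sum above — uptake is the sum of the two bulk GLUT contributions, which is
what makes the cluster-conditional correlation structure emerge rather
than being painted on. The expression noise default (0.5) was set during
design so the ImmuneScore–fraction map stays near-linear: at low noise the
rank-based score saturates for immune-rich samples, which compresses the
rich mode and misplaces the KDE valley relative to the mixture crossing.
TLRmax noise is additive Gaussian (sd 0.2) truncated at a small positive
floor — a simple PET error model keeping uptake positive.

**Response cohort.** Baseline log GLUT-ratio is
$\mathcal N(0, 0.8)$. A patient reacts to therapy (SD or PR/CR) with
probability $\mathrm{logit}^{-1}(-0.3 + 1.2 z)$ in the standardized
baseline; reactive patients split PR/CR vs SD by a second logistic draw at
two-thirds of the main slope (so a null slope decouples all classes from
baseline, and the median baseline orders PD < SD < PR/CR). On treatment,
reactive patients' log-ratio regresses toward the cohort mean with
pullback 0.6 plus noise (sd 0.2) — immune influx raises low ratios — while
PD patients keep their baseline up to noise. This reproduces the waterfall
structure: %change negatively correlated with baseline overall and within
SD/PR-CR, flat within PD. One structural consequence of the
regression-to-the-mean form is that it *compresses* the responder
distribution on treatment, so the on-treatment responder/nonresponder
separation is typically no stronger than at baseline; a change model with
a response-specific target above the cohort mean would be needed for the
on-treatment separation to sharpen, and is noted as a limitation.
Progression is exponential with hazard $0.08\,e^{-0.3 z}$ per month,
censored at 24 — high ratios are protective with a true hazard ratio of
$e^{-0.3} \approx 0.74$ per unit z.

**Single-cell cohort.** Negative-binomial counts (size 2, lognormal
library factors, sd 0.3; a `poisson` flag gives the infinite-dispersion
limit) over five cell types (cancer 20%, myeloid 30%, T 30%, endothelial
10%, fibroblast 10%; exact largest-remainder allocation). GLUT1's mean is
nonzero only in cancer cells (5), GLUT3's only in myeloid/T/endothelial
cells (3); each type has its own marker block and glycolysis genes are
enriched in cancer. With these means, essentially any nonzero count is
above the 0.5 gate cutoff, so the GLUT1+GLUT3− fraction equals the cancer
proportion minus the NB dropout mass — about 18% — and double positives
are structurally absent.

Where the underlying study reports no effect sizes for these latent
quantities, the defaults are realistic-scale design choices, fixed once;
they are conditions for testing, not estimates of any real cohort.

# What the synthetic tests do and do not show

Passing tests demonstrate that the implementations are correct (against
independent oracles: brute-force running sums, closed-form correlation,
enumeration of rank tests, hypergeometric log-rank increments, brute-force
partial likelihood, analytic phantom volumes) and that the pipeline
recovers the qualitative structure it targets — sign patterns, threshold
placement, hazard-ratio recovery — under a generative model that *assumes*
the reciprocal-GLUT mechanism. They cannot show that real tumors obey that
mechanism, and the generators deliberately omit batch effects, full
transcriptome covariance structure, spatial heterogeneity between the
biopsied site and the imaged volume, and multi-lesion disease. Cell
fractions on synthetic data (≈18% GLUT1+GLUT3−) are design consequences,
not reproductions of any published percentage.

# Problem sizes and numerics

The test suite and acceptance script use: bulk cohorts of n = 200 samples
by 400 genes at five seeds; response cohorts of n = 500 (waterfall,
group tests) and n = 2000 (Cox recovery, 100-replicate null coverage at
n = 500); two-Gaussian KDE checks at n = 1000–10,000; a 60³-voxel, 1 mm
phantom; 2000 single cells; 2000 null replicates for the rank-test
calibration — sizes at which the targeted properties are statistically
stable while the whole suite runs in well under a minute per module.
Numerical conventions: expression ties broken by gene identifier;
exact-test two-sidedness as $P(|U - \mu_U| \ge |u - \mu_U|)$ over the
permutation distribution; KDE thresholds reported at grid resolution
(512 points); Wald confidence intervals for Cox; strict inequalities at
the cluster threshold, gate cutoff and MTV filter boundaries.
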