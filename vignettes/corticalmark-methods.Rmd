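---
title: "Methods: functional cortical deficit-pattern biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional cortical deficit-pattern biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticalmark)
```

# Overview

`corticalmark` implements a pipeline for case-control studies of cortical
function built around four statistical objects:

1. **Voxelwise regional homogeneity (ReHo)** — Kendall's coefficient of
   concordance (KCC, Kendall's W) of each voxel's BOLD time series with its
   3x3x3 neighborhood, reduced to bilateral parcel means.
2. **Covariate-adjusted effect-size maps** — per-region case-control
   Cohen's d after ordinary-least-squares removal of age and sex effects.
3. **Spatial map comparison** — Pearson correlation between two regional
   maps, with significance from spin permutations of spherical parcel
   centroids, and Fisher r-to-z comparison of correlations across cohort
   pairs.
4. **Regional Vulnerability Index (RVI)** — each subject's correlation,
   across regions, between their control-referenced z-deviation profile and
   a template deficit pattern, summarized by a case-control contrast and an
   association with symptom severity.

A synthetic-cohort module generates every input these stages need (toy
atlases, 4-D time series with controllable local coherence, regional tables
with planted effect patterns), so the whole pipeline runs and is tested
end-to-end with no external data.

# Regional homogeneity

## The statistic

For a voxel with $K$ in-mask neighbors (including itself; $K \le 27$) over
$T$ time points, each series is converted to midranks over time. With rank
sums $R_t = \sum_k r_{kt}$,

$$W = \frac{12 \sum_t \left(R_t - K(T+1)/2\right)^2}
           {K^2(T^3 - T) - K \sum_k C_k},
\qquad C_k = \sum_{\text{tied groups } g}(g^3 - g).$$

$W \in [0, 1]$: 1 when all $K$ series rank time points identically, and
about $1/K$ under independence (from the approximation
$K(T-1)W \sim \chi^2_{T-1}$, so the null mean over 27-voxel neighborhoods is
$1/27 \approx 0.037$ — a property the test suite checks by simulation).

## Numerical and edge-case choices

These conventions are the package's own documented defaults; they are
reasonable choices for volumetric ReHo, not claims about any particular
prior implementation:

* **Tie handling.** Midranks with the standard tie-correction term $C_k$.
  Continuous BOLD essentially never ties, but quantized or synthetic data
  can, and the corrected denominator degrades gracefully.
* **Mask edges.** $W$ is computed over however many in-mask neighbors exist
  ($K < 27$ allowed), with a configurable `min_neighbors` floor (default 2)
  below which the voxel is `NaN`. The per-voxel $K$ actually used is
  returned in `neighbor_counts` so downstream users can filter.
* **Constant series.** A flat series carries no rank information and makes
  the tie-corrected denominator degenerate, so constant series are removed
  from the neighborhood before $K$ is counted.
* **Regional reduction.** Arithmetic mean over a region's defined voxels;
  regions with no defined voxel become `NaN` with a warning. Left and right
  members of each bilateral pair are averaged per subject — `(L + R)/2`,
  `NaN` if either side is undefined.
* **No smoothing.** Spatial smoothing inflates ReHo; the package computes
  ReHo on the data as given and treats preprocessing as out of scope.

The implementation computes per-voxel time ranks and tie corrections once
and accumulates neighborhood sums with 27 shifted array additions, making
the whole map one vectorized pass; an independent brute-force rank
implementation (explicit counting loops) is kept in the test suite and must
agree with the production path to 1e-12 on randomized instances.

# Effect-size maps

Age and sex are removed per region by OLS on $[1, \text{age}, \text{sex}]$,
fitted diagnosis-blind on the pooled sample by default (a controls-only
option is provided). The adjusted value is the residual plus the fit at the
mean covariates, preserving the measure's scale. A covariate that is
constant in the estimation sample is dropped from the design; the fit
errors only when age and sex are both constant.

Cohen's d uses the pooled SD (classic d, not Hedges' g — a small-sample
correction toggle exists but is off by default), with the pooled two-sample
t and its two-sided p-value per region. Negative d means a case deficit
(case - control). Multiple-comparison flags are Bonferroni by default
(`p < alpha/R` with `R` taken from the map — never hard-coded), with
Benjamini-Hochberg FDR as an alternative.

The pooled (diagnosis-blind) residualization deserves a caveat: when a
covariate is confounded with diagnosis, the pooled slope absorbs a fraction
of the group effect equal to the share of covariate variance explained by
group membership. With ages uniform over a 50-year span and a 10-year group
gap, that fraction is about 10%, so an adjusted d of -0.3 carries a bias of
roughly 0.03 — small next to the bias of the unadjusted estimate (about
0.5 SD in the same scenario), and this is what the acceptance checks
measure. The controls-only mode avoids this at the cost of estimating the
slopes on fewer subjects.

# Spin permutation test

Parcel-level spatial correlation significance follows the standard
rotate-and-reassign construction: each permutation draws a Haar-uniform
rotation of the sphere (Gaussian 3x3 matrix, QR orthonormalization, column
signs fixed by R's diagonal, one column flipped if the determinant is -1),
rotates all parcel centroids, and gives each region the value of the region
whose *original* centroid is nearest to its rotated position. Nearest on
the unit sphere is resolved by the largest dot product; sampling with
replacement is allowed, as is standard for parcel-level nulls. Only the
first map is permuted — permuting both changes the null. The two-sided
p-value uses the add-one rule $p = (1 + \#\{|r_\pi| \ge |r_{obs}|\})/(n_\pi + 1)$,
so it is never 0 and never below $1/(n_\pi+1)$.

Choices worth noting:

* Bilateral (hemisphere-averaged) maps are spun on left-hemisphere
  centroids.
* Default 999 spins — a documented default, adjustable everywhere.
* A rotation can collapse the nearest-neighbor assignment onto a constant
  map (possible when centroids cluster in a small cap); such permutations
  carry no correlation and contribute $r_\pi = 0$.
* Ties in the nearest-centroid search are broken by first index, keeping
  runs bit-reproducible under a fixed seed.

On spatially unstructured (iid) null maps the test is approximately exact;
the acceptance suite measures the type-I error at $\alpha = 0.05$ over 400
seeded null map pairs and requires it to sit in [0.02, 0.08]. When maps
carry strong smooth spatial autocorrelation, parcel-level spins with
replacement are known to be only approximately calibrated — variogram-based
surrogates are out of scope here.

Fisher's r-to-z comparison of two map correlations uses
$z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$
with a two-sided normal p. The region count $n$ is always an explicit
argument; nothing assumes a particular atlas size.

# Regional Vulnerability Index

RVI asks how much an individual looks like the illness pattern: z-score
each subject's adjusted regional values against the control mean and SD
(controls only, after the same age/sex adjustment as the effect maps), then
correlate that z-profile with a template effect-size vector across regions.
Because templates store case - control d (deficits negative), a subject
expressing the deficit pattern has negative deviations exactly where the
template is negative, hence a *positive* RVI. The correlation form makes
RVI invariant to positive affine rescaling of the template and flips its
sign under negation. Pearson correlation is the default kernel (Spearman
and cosine are selectable).

Whether deviations should be normalized against within-cohort controls or
some external norm is genuinely open; both are supported
(`build_control_reference` on any table) and within-cohort controls are the
documented default. Region matching between template and cohort tables is
by name after lowercase/underscore canonicalization, since the two usually
originate from different tools.

`inst/extdata/synthetic_dk_reho_template.tsv` ships a *synthetic*
illustration template over the 34 bilateral Desikan-Killiany region names
(graded deficits, mean about -0.29, SD about 0.08, strongest in cingulate
and temporal regions). It exists so examples and region-name matching can
be exercised; it is not a measured consortium effect-size table.

# Synthetic cohorts

The generator is the package's study-condition definition, not a tuning
knob; its defaults are fixed and the tests run against them.

**Regional tables.** For subject $i$, region $j$:
$$x_{ij} = \mu_j + \beta^{age}_j \cdot \text{age}_i + \beta^{sex}_j \cdot \text{sex}_i
 + dx_i \cdot d_j \sigma_j + \varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma_j^2),$$
with ages Uniform(20, 70) (a span covering the adult cohorts such analyses
target), sex Bernoulli(0.5) coded 0/1, and an optional case age shift for
confounding experiments. Defaults: $\mu_j = 0$, $\sigma_j = 1$, no
covariate effects, 34 bilateral regions. Regional noise is independent
across regions — no spatial autocorrelation — which isolates each stage's
contract; spin-test behavior under spatial structure is therefore *not*
exercised by these cohorts.

**Severity.** Only cases receive ratings (as with clinical instruments),
which also exercises missing-data handling downstream. Severity is a noisy
*linear* (hence monotone) function of the case's pattern-expression burden
$b_i = \sum_j d_j z_{ij}$, standardized and mixed with Gaussian noise to
reach a configurable burden-severity correlation (default 0.4, a moderate
clinical association), then placed on a rating-like scale ($20 + 8z$). The
linear form is a free choice; any monotone transform would do.

**BOLD volumes.** Voxel series in region $j$ are
$\sqrt{c_j}\, s_j(t) + \sqrt{1 - c_j}\, e_v(t)$ with standard Gaussian
innovations, so the within-region pairwise temporal correlation equals the
coherence $c_j \in [0, 1)$ and ReHo responds monotonically to it. There is
no hemodynamic response, drift, or motion — passing tests demonstrate the
statistics' contracts, not robustness to scanner physics.

**Toy atlas.** Mirrored rectangular blocks on a (y, z) grid in each
hemisphere, separated by one-voxel background gaps so 3x3x3 neighborhoods
never straddle regions (real cortical parcels are likewise separated by
non-cortex in masked data), with centroids = mean voxel coordinate
projected to the unit sphere. The (y, z) layout spreads centroids in two
dimensions, which the spin reassignment needs; exact L/R mirror symmetry
exercises hemisphere averaging.

# Pipeline

`run_pipeline()` executes simulate → reho → esmap → spin → rvi. Stages
communicate only through files (NIfTI-1 volumes; TSV tables with `.`
decimal and `NA` for missing; JSON summaries), so any stage can be re-run
in isolation and a missing upstream file raises a dependency error naming
the producing stage. Every stage draws from its own RNG stream derived by
hashing the stage name with the master seed, so adding a stage never
perturbs another stage's draws; a run manifest records the configuration,
seed, package version and MD5 digests of all outputs. Rerunning a
configuration reproduces byte-identical tables.

In the default end-to-end configuration, case deficits are planted as a
graded per-region *coherence* drop (-0.35 to -0.05 across bilateral pairs,
scaled per case by a pattern-strength factor Uniform(0.5, 1.5) that also
drives severity). Deficits planted on coherence translate into large
standardized ReHo differences because regional ReHo means have small
between-subject variance at these grid sizes, so the default smoke-run
effect sizes (|d| of 1-4) are deliberately strong rather than realistic:
the run is meant to demonstrate detectability and determinism of the whole
chain at a desk-scale problem size (24^3 grid, 60 time points, 30 + 30
subjects, 8 region pairs — a few minutes on one CPU; problem sizes in the
test and acceptance suites were chosen to keep full runs at this scale).

# Known limitations

* Pooled residualization partially absorbs group effects under
  covariate-diagnosis confounding (quantified above).
* Parcel-level spin nulls with replacement are approximate under strong
  spatial autocorrelation; no variogram-matched surrogates.
* The synthetic cohorts have no spatial noise correlation, no site effects
  and no scanner artifacts; conclusions from the test suite are about the
  estimators' contracts, not about field data.
* Surface-based ReHo, voxelwise inference, and preprocessing (motion,
  registration, filtering) are out of scope.
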