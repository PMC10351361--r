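---
title: "Attributing NTCP reductions in online-adaptive proton therapy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing NTCP reductions in online-adaptive proton therapy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model, the numerical choices and the design
decisions behind **adaptNTCP**. It is a methods document: every empirical
number about the simulation is produced by the package's own test suite or
by `scripts/acceptance.R`, and none is asserted here.

## 1. The question the package models

Online-adaptive intensity-modulated proton therapy (IMPT) re-optimizes a
patient's plan on the anatomy of the day. Clinically this helps through two
distinct mechanisms:

* **SUR — setup-uncertainty reduction.** If the plan is adapted to the
  daily position, the 3 mm setup-robustness margin built into conventional
  plans can be dropped. Smaller margins mean less dose to organs at risk
  (OARs) even before any anatomical change is considered.
* **AGC — adaptation to geometric changes.** Inter-fraction anatomy drift
  (tumor shrinkage, parotid shrinkage, larynx displacement) degrades an
  unadapted plan; daily re-optimization compensates.

The package isolates the two mechanisms with a three-scenario comparison on
the *same* simulated treatment course:

| Scenario | Plan | Delivery |
|---|---|---|
| A | 3 mm-robust | unadapted |
| B | non-robust (0 mm) | unadapted |
| C | non-robust (0 mm) | daily online adaptation |

With per-endpoint normal tissue complication probabilities (NTCP, in
percentage points, pp):

$$\Delta\mathrm{NTCP}_{SUR} = \mathrm{NTCP}_B - \mathrm{NTCP}_A,\qquad
  \Delta\mathrm{NTCP}_{AGC} = \mathrm{NTCP}_C - \mathrm{NTCP}_B,$$
$$\Delta\mathrm{NTCP}_{SUR\&AGC} = \mathrm{NTCP}_C - \mathrm{NTCP}_A
  = \Delta\mathrm{NTCP}_{SUR} + \Delta\mathrm{NTCP}_{AGC}.$$

The additivity identity is algebraic; the package asserts it on every
report (`deltaNTCP()`) and export (`writeCohortCSV()`) to machine
precision, so a violation would indicate an implementation error, not a
modeling effect.

## 2. NTCP models

The shipped registry (`inst/extdata/ntcp_models.yaml`,
`defaultNTCPRegistry()`) holds six head-and-neck endpoint models of three
families:

* logistic dose-response
  $\mathrm{NTCP} = (1 + (D_{50}/D)^k)^{-1}$ — acute oral mucositis on the
  oral mucosa mean dose ($D_{50} = 51$ Gy, $k = 1$);
* probit (LKB-type) $\mathrm{NTCP} = \Phi((gEUD - D_{50})/(m D_{50}))$ —
  xerostomia on the contralateral parotid ($D_{50} = 39.9$ Gy, $m = 0.4$,
  volume parameter $n = 1$) and aspiration on the larynx
  ($D_{50} = 46.5$ Gy, $m = 0.5$, $n = 1$);
* multivariable logistic
  $\mathrm{NTCP} = (1 + e^{a - bX_1 - cX_2})^{-1}$ — swallowing dysfunction
  for solids ($a = 5.98$, $b = 0.074$, $c = -1.209$, $X_1$ = supraglottic
  larynx mean dose, $X_2 \equiv 1$), for liquids ($a = 6.89$, $b = 0.049$,
  $c = 0.048$) and physician-rated dysphagia ($a = 6.09$, $b = 0.057$,
  $c = 0.037$), the latter two on the superior pharyngeal constrictor and
  supraglottic larynx mean doses.

With $n = 1$ the generalized equivalent uniform dose reduces exactly to
the mean dose; `geud()` implements the general power mean and the test
suite verifies the reduction on random draws. The *total* probability of
developing any of the four main endpoints (xerostomia, dysphagia, oral
mucositis, aspiration — four distinct structures) is combined under an
independence assumption, $P_{any} = 1 - \prod_i (1 - p_i)$
(`totalAnyToxicity()`); the plain sum of per-endpoint deltas is exported
alongside so the combination rule is always visible in the output.

A mechanism counts as *clinically significant* for a patient when a single
endpoint is reduced by at least 10 pp or the four-endpoint summed reduction
reaches 15 pp (`significanceRule()`, fully configurable).

Structures that are absent, empty, or entirely inside the CTV union are
*not evaluable*; their NTCP propagates as missing, never as zero, and
endpoints evaluable in only some scenarios are excluded from totals with a
warning.

## 3. Synthetic cohort generator

No clinical CBCT cohort ships with the package; the generator is the
first-class substitute and is itself under test.

**Planning anatomy** (`generatePhantom()`): an idealized axial neck
cross-section of ellipsoidal organs in a water-density body — boost and
elective CTVs (lateralized to the ipsilateral side), both parotids,
superior pharyngeal constrictor, larynx, supraglottic larynx, oral mucosa,
spinal cord, brainstem, esophagus. Per-patient shape/position jitter is
drawn under a deterministic per-patient seed, so cohorts are bitwise
reproducible. Two invariants are enforced by construction: the elective
CTV is the shell around the boost volume (disjoint), and CTVs never
overlap cord or brainstem.

A deliberate layout decision: the serial swallowing structures (superior
constrictor, supraglottic larynx) *abut* the elective CTV with a gap of
roughly 0–3 mm instead of lying inside it. A structure inside the CTV
receives prescription dose under every scenario, so its ΔNTCP would be
numerical noise; placing it adjacent makes the setup-robustness margin the
dominant determinant of its dose, which is exactly the mechanism the
scenario comparison is meant to expose (and a planner cannot be asked to
spare an organ inside the target anyway).

**Fraction series** (`generateFractionSeries()`): the number of fractions
is drawn uniformly from 30–35; each fraction gets an i.i.d. Gaussian
residual setup shift (1.5 mm SD per axis; the out-of-plane component is
zeroed in single-slice mode). Systematic drift is a smooth displacement
field: Gaussian-windowed radial contraction of both parotids (10% total)
and the boost CTV (5%), plus a 4 mm Gaussian-windowed larynx displacement,
all scaled by the monotone ramp $k/n_{fx}$. The forward field is inverted
numerically (20 fixed-point iterations); the test suite bounds the
round-trip composition error below 0.1 voxel, and a gradient cap warns if
drift amplitudes ever made the field non-diffeomorphic. Zero-motion
settings reproduce the planning anatomy *exactly* (identity fractions are
flagged and skip resampling entirely), which is what makes the
conservation tests exact.

These defaults are the study conditions of the simulated cohort; they were
frozen while designing the generator and are not tuned against outcomes.

## 4. Dose engine

An analytic spot engine keeps the physics transparent and fast:

* depth dose: a parametrized Bragg curve — plateau switched off by a
  smoothed step past the range plus a Gaussian peak (broad proximal width
  $\max(0.04R, 2)$ mm, sharp 1 mm distal width), maximum at the nominal
  range;
* depth coordinate: water-equivalent depth (WED), the density line
  integral along the ray. It is computed by resampling the density onto a
  beam-aligned lattice (sparse bilinear operators, cached per grid/angle),
  a cumulative sum along depth, and resampling back — and is cross-checked
  in the tests against an independent brute-force ray-marching oracle;
* lateral profile: Gaussian of width $\sigma(d) = 3 + 0.02\,d$ mm with
  $(\sigma_0/\sigma)^2$ normalization; three beams at 60°/180°/300°;
* RBE: the constant factor 1.1 folded into the influence matrix.

The influence matrix (voxels × spots, sparse, entries below $10^{-4}$ of
their column maximum dropped) makes dose exactly linear in the spot
weights. Residual setup shifts are realized as a lateral translation of
the beam in the beam's-eye view; a shift along the beam axis leaves the
WED of every ray unchanged (as it physically does for parallel rays), and
a test pins both properties.

## 5. Planning and online adaptation

**Objective** (`evaluateObjective()`): per-voxel target terms — a
two-sided uniform-dose deviation from prescription (57/70 Gy simultaneous
integrated boost) plus one-sided penalties below 95% and above 107% of
prescription (standing in for D98/D2 criteria) — and OAR terms: quadratic
excess of mean dose over 26 Gy (each parotid), 42 Gy (superior
constrictor), 40 Gy (larynx), and per-voxel quadratic excess over 45 Gy
(cord) and 54 Gy (brainstem). The one-sided band and OAR terms are pure
constraint penalties (zero when satisfied); the uniform term makes the
optimum unique and pins the single-voxel problem to the closed form
$w^* = p/d$, which the tests exploit. Dose outside all constrained
structures never contributes.

**Robust optimization** (`optimizeWeights()`): minimax over the nominal
geometry plus the six axis-aligned shifts of the setup-uncertainty setting
(four in single-slice mode), solved by L-BFGS-B with non-negativity
bounds on a log-sum-exp smoothed maximum (relative smoothing $10^{-3}$).
With one scenario the smoothed maximum is the identity, so the non-robust
plan is plain optimization. A final guard compares against the warm start
under the true (unsmoothed) maximum, so the returned plan is never worse
than its start. The optimizer touches only the rows of the influence
matrix that belong to constrained voxels.

**Online adaptation** (`selectSpots()`, `reoptimizeWeights()`): each
fraction, the subset of spots re-optimized is the smallest set carrying at
least 33% of total spot weight — the descending-weight greedy scan, which
is provably minimum-cardinality for a sum threshold (verified against
exhaustive subset search in the tests) — padded to at least 10% of all
spots, ties broken to the lower index. Only the selected weights move;
non-selected weights are returned bit-identical. The base weights are a
feasible start of the restricted problem, so the daily objective of the
adapted delivery never exceeds the unadapted one (asserted per fraction,
and the solution is only accepted when the solver confirms it).

**Accumulation** (`runScenario()`, `mapToPlanning()`): each fraction's
dose is computed on the daily (deformed, shifted) anatomy, divided by the
number of fractions, and pulled back to the planning grid by trilinear
interpolation at $x + \mathrm{disp}(x)$, using the generator's
ground-truth deformation — dose mapping has no registration error in this
simulation, deliberately, so scenario differences are attributable to
planning and adaptation alone. Identity fractions reuse the nominal
influence matrix, which is mathematically identical to recomputing it and
makes the zero-motion conservation test exact to float tolerance.

## 6. Problem sizes and numerical choices

The default grids are the package's own choice of desk-scale problem, not
a clinical claim: a 64×64 single-slice 2 mm grid for the fast demo cohort
(the full five-patient, ~30-fraction, three-scenario analysis runs in a
couple of minutes on one CPU) and 64×64×32 for the three-dimensional
conservation test. All randomness flows from integer seeds below
$2^{31}$; repeated runs are bitwise identical, which the suite checks at
the phantom, influence and optimizer level.

Tolerances used by the tests: closed-form NTCP values to $10^{-12}$
relative error; DVH percentiles *exactly* equal to the sort-based oracle
($D_{p\%}$ is the $k$-th largest voxel dose, $k = \max(1, \lfloor p/100
\cdot V\rfloor)$); conservation to float round-off; solver-mediated
inequalities with a $10^{-6}$ slack.

## 7. Limitations

* The anatomy is a stylized 2D/3D ellipsoid layout; it reproduces the
  *mechanisms* (margins, drift, adaptation), not patient-realistic dose
  levels. Absolute NTCP values are plausible but not clinical.
* The dose engine is analytic (no nuclear halo, no heterogeneity
  scattering); ranges and lateral widths are parametrized, not Monte
  Carlo.
* Dose accumulation uses the ground-truth deformation; real deformable
  registration error is out of scope by design.
* The independence assumption behind the any-of-four total is a modeling
  convention; the summed deltas are exported so readers can apply their
  own combination.
* Endpoint NTCP parameters are fixed constants of the registry file;
  model-parameter uncertainty is not propagated.

## 8. Reproducing the headline outputs

```r
# from the installed package
res <- runCohortAnalysis(cohortConfig(nPatients = 5,
                                      gridShape = c(64, 64, 1), seed = 1))
res$cohort$endpointMeans
plotDeltaByEndpoint(res$cohort)
```

or, from the command line,

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

which writes the cohort means, per-patient any-of-four totals,
significance counts, and the 0/1/3 mm linearity table to JSON.
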