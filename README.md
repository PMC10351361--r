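# adaptNTCP

Simulation framework quantifying **why** online-adaptive proton therapy
reduces toxicity in head-and-neck cancer: how much of the normal tissue
complication probability (NTCP) reduction comes from dropping setup
margins, and how much from compensating anatomical change.

## The science

Online-adaptive intensity-modulated proton therapy (IMPT) re-optimizes the
spot weights of a plan on each day's anatomy. Its clinical benefit mixes
two mechanisms:

* **SUR (setup-uncertainty reduction):** a daily-adapted plan does not
  need the conventional 3 mm setup-robustness margin, so organs at risk
  next to the target see less dose from day one.
* **AGC (adaptation to geometric changes):** tumor and parotid shrinkage
  and larynx drift over a 30–35 fraction course degrade an unadapted plan;
  daily re-optimization compensates.

The package separates the two by simulating the *same* treatment course
three ways — A: 3 mm-robust plan, unadapted; B: non-robust plan,
unadapted; C: non-robust plan with daily online adaptation — and
attributing, per toxicity endpoint,

```
ΔNTCP_SUR = NTCP_B − NTCP_A      (margin effect)
ΔNTCP_AGC = NTCP_C − NTCP_B      (adaptation effect)
ΔNTCP_SUR&AGC = ΔNTCP_SUR + ΔNTCP_AGC   (exact, asserted to machine precision)
```

## What's inside

* a **synthetic head-and-neck cohort generator**: jittered ellipsoid
  anatomy (two CTV levels, parotids, swallowing structures, cord,
  brainstem) with per-fraction residual setup shifts and a smooth,
  invertible anatomical-drift deformation field;
* an **analytic proton spot engine**: parametrized Bragg curves on
  water-equivalent depth, depth-dependent lateral Gaussian, three beams,
  RBE 1.1, sparse dose-influence matrices;
* **minimax-robust and non-robust spot-weight optimization** (L-BFGS-B on
  a smoothed worst-case objective over setup-error scenarios);
* **online adaptation**: per fraction, re-optimize the smallest spot
  subset carrying ≥ 33 % of total weight (≥ 10 % of spots), exactly the
  greedy minimum-cardinality selection;
* **deformable dose accumulation** back to the planning grid;
* **six published head-and-neck NTCP models** (oral mucositis, xerostomia,
  three dysphagia endpoints, aspiration; logistic, probit/gEUD and
  multivariable-logistic families) in an editable YAML registry;
* **reporting**: per-patient and cohort ΔNTCP tables, an any-of-four total
  under an independence assumption, a configurable clinical-significance
  rule (≥ 10 pp single endpoint or ≥ 15 pp summed), CSV/JSON export and
  ggplot figures.

See the vignette (`vignettes/adaptive-impt-ntcp.Rmd`) for the full methods
description, parameter rationale and limitations.

## Worked example

```r
library(adaptNTCP)

res <- runCohortAnalysis(cohortConfig(nPatients = 5,
                                      gridShape = c(64, 64, 1), seed = 1))
res$cohort$endpointMeans
```

On this default five-patient demo cohort (single-slice 2 mm grid, ~2 min
on one CPU) the cohort-mean ΔNTCP in percentage points is:

| endpoint          | ΔSUR  | ΔAGC  | ΔSUR&AGC |
|-------------------|-------|-------|----------|
| xerostomia        | −6.76 | +0.01 | −6.75    |
| oral_mucositis    | −1.88 | −0.32 | −2.20    |
| dysphagia         | −1.15 | +0.03 | −1.12    |
| dysphagia_liquids | −0.60 | +0.01 | −0.60    |
| dysphagia_solids  | −0.13 | −0.02 | −0.15    |
| aspiration        | −0.63 | −0.35 | −0.98    |

The mean any-of-four total toxicity probability drops by 5.21 pp (SUR
−4.85, AGC −0.36). Three of five patients cross the clinical-significance
threshold for SUR and for the combined mechanism; none for AGC alone — on
this small demo phantom, margin reduction dominates, while the
anatomical-drift amplitudes are modest. Per-patient tables, verdicts and
figures:

```r
res$cohort$significanceCounts
plotDeltaByEndpoint(res$cohort)
writeCohortCSV(res$cohort, res$reports, "results/")
```

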