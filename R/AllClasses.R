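#' @import methods
#' @importClassesFrom Matrix Matrix dgCMatrix
#' @importFrom stats optim pnorm plogis rnorm runif quantile
#' @importFrom utils write.csv write.table
NULL

# All structure roles the NTCP registry and planning objectives may reference.
.allRoles <- c("CTV_HIGH", "CTV_LOW", "ORAL_MUCOSA", "PAROTID_CONTRA",
               "PAROTID_IPSI", "PCM_SUPERIOR", "LARYNX_SUPRAGLOTTIC",
               "LARYNX", "SPINAL_CORD", "BRAINSTEM", "ESOPHAGUS")

#' Voxelized planning anatomy
#'
#' A `Phantom` holds the voxel grid on which all dose calculation, planning
#' and NTCP evaluation take place: a relative (water-equivalent) stopping
#' power density per voxel, the grid shape, the isotropic-by-default voxel
#' spacing in mm, and the world origin of the grid corner.
#'
#' @slot gridShape integer vector of length 3, voxels per axis.
#' @slot spacingMm numeric vector of length 3, voxel spacing in mm (> 0).
#' @slot originMm numeric vector of length 3, world position (mm) of the
#'   grid corner; voxel centers sit at `origin + (index - 0.5) * spacing`.
#' @slot density numeric array of dimension `gridShape`; unitless
#'   water-relative density, >= 0 (0 outside the body).
#' @exportClass Phantom
setClass("Phantom",
  representation(gridShape = "integer", spacingMm = "numeric",
                 originMm = "numeric", density = "array"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      msg <- c(msg, "gridShape must be 3 positive integers")
    if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
      msg <- c(msg, "spacingMm must be positive on every axis")
    if (!identical(dim(object@density), object@gridShape))
      msg <- c(msg, "density extent does not match gridShape")
    if (any(object@density < 0))
      msg <- c(msg, "density must be non-negative everywhere")
    if (length(msg)) msg else TRUE
  })

#' Named organ masks on a phantom grid
#'
#' Maps structure roles (CTVs and the organs at risk feeding the NTCP
#' models) to boolean voxel masks of the phantom's shape. Roles that are
#' absent propagate downstream as "not evaluable" rather than as errors.
#'
#' @slot masks named list of logical arrays, one per structure role.
#' @slot gridShape integer vector of length 3.
#' @exportClass StructureSet
setClass("StructureSet",
  representation(masks = "list", gridShape = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (is.null(names(object@masks)) || any(names(object@masks) == ""))
      msg <- c(msg, "all masks must be named by structure role")
    for (nm in names(object@masks)) {
      m <- object@masks[[nm]]
      if (!is.logical(m) || !identical(dim(m), object@gridShape))
        msg <- c(msg, sprintf("mask '%s' is not a logical array of the grid shape", nm))
    }
    if (length(msg)) msg else TRUE
  })

#' One treatment day of a fraction series
#'
#' Bundles the residual rigid setup shift, the smooth systematic
#' deformation (stored with its ground-truth inverse so deformable dose
#' accumulation is exactly testable), and the deformed daily density and
#' structures. A `NULL` displacement denotes the identity deformation.
#'
#' @slot fractionIndex 1-based index, unique within a series.
#' @slot setupShiftMm numeric length-3 residual setup shift (mm).
#' @slot dispMm forward displacement field mapping planning to daily
#'   coordinates, as an `nx x ny x nz x 3` array in mm, or `NULL`.
#' @slot invDispMm inverse displacement field (daily to planning), or `NULL`.
#' @slot dailyDensity numeric array, the deformed density.
#' @slot dailyStructures [StructureSet] of deformed masks.
#' @exportClass FractionAnatomy
setClass("FractionAnatomy",
  representation(fractionIndex = "integer", setupShiftMm = "numeric",
                 dispMm = "ANY", invDispMm = "ANY",
                 dailyDensity = "array", dailyStructures = "StructureSet"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@setupShiftMm) != 3L)
      msg <- c(msg, "setupShiftMm must have length 3")
    if (object@fractionIndex < 1L)
      msg <- c(msg, "fractionIndex must be >= 1")
    if (!is.null(object@dispMm) && is.null(object@invDispMm))
      msg <- c(msg, "a non-identity displacement must store its inverse")
    if (length(msg)) msg else TRUE
  })

#' Cohort simulation settings
#'
#' Defines the study conditions for the synthetic cohort: number of
#' patients, fractions per patient (sampled uniformly in 30--35 by
#' default), the residual setup error standard deviation, and the
#' systematic drift parameters (parotid/target shrinkage, larynx
#' displacement amplitude).
#'
#' @slot nPatients integer.
#' @slot fractionRange integer length-2 inclusive range, within [1, 50].
#' @slot setupSigmaMm per-axis residual setup error SD in mm (>= 0).
#' @slot parotidShrink total fractional linear contraction of the parotids
#'   reached at the final fraction.
#' @slot targetShrink same, for the high-risk CTV.
#' @slot larynxAmpMm peak larynx displacement amplitude in mm.
#' @slot gridShape integer length-3 voxel grid (use `nz = 1` for the fast
#'   single-slice mode).
#' @slot spacingMm voxel spacing in mm.
#' @slot seed base random seed for the cohort.
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(nPatients = "integer", fractionRange = "integer",
                 setupSigmaMm = "numeric", parotidShrink = "numeric",
                 targetShrink = "numeric", larynxAmpMm = "numeric",
                 gridShape = "integer", spacingMm = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
    fr <- object@fractionRange
    if (length(fr) != 2L || fr[1] > fr[2] || fr[1] < 1L || fr[2] > 50L)
      msg <- c(msg, "fractionRange must lie within [1, 50]")
    if (object@setupSigmaMm < 0) msg <- c(msg, "setupSigmaMm must be >= 0")
    if (object@parotidShrink < 0 || object@parotidShrink >= 0.5)
      msg <- c(msg, "parotidShrink must be in [0, 0.5)")
    if (object@larynxAmpMm < 0) msg <- c(msg, "larynxAmpMm must be >= 0")
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      msg <- c(msg, "gridShape must be 3 positive integers")
    if (length(msg)) msg else TRUE
  })

#' Scanned pencil-beam spot set
#'
#' Ordered list of proton spots (beam gantry angle, lateral position in the
#' beam's-eye view, nominal water-equivalent range) together with the
#' MU-like non-negative weight vector and the beam isocenter.
#'
#' @slot spots data.frame with columns `id`, `angleDeg`, `tMm`, `zMm`,
#'   `rangeMm`.
#' @slot weights numeric vector, one non-negative weight per spot.
#' @slot isocenterMm numeric length-3 world isocenter (mm).
#' @exportClass SpotSet
setClass("SpotSet",
  representation(spots = "data.frame", weights = "numeric",
                 isocenterMm = "numeric"),
  validity = function(object) {
    msg <- character(0)
    need <- c("id", "angleDeg", "tMm", "zMm", "rangeMm")
    if (!all(need %in% names(object@spots)))
      msg <- c(msg, "spots must have columns id, angleDeg, tMm, zMm, rangeMm")
    else {
      if (anyDuplicated(object@spots$id)) msg <- c(msg, "spot ids must be unique")
      if (any(object@spots$rangeMm <= 0)) msg <- c(msg, "nominal ranges must be > 0")
      if (any(object@spots$angleDeg < 0 | object@spots$angleDeg >= 360))
        msg <- c(msg, "beam angles must lie in [0, 360)")
    }
    if (length(object@weights) != nrow(object@spots))
      msg <- c(msg, "one weight per spot required")
    if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Dose-influence operator
#'
#' Sparse matrix `D[i, j]` giving dose in Gy(RBE) per unit weight to voxel
#' `i` from spot `j`, with the biological effectiveness factor 1.1 already
#' folded in. Columns follow the spot ordering of the [SpotSet] it was
#' computed from.
#'
#' @slot mat a `dgCMatrix` (voxels x spots), entries >= 0.
#' @slot gridShape integer length-3 voxel grid of the rows.
#' @slot setupShiftMm the rigid setup shift the geometry was computed under.
#' @exportClass InfluenceMatrix
setClass("InfluenceMatrix",
  representation(mat = "Matrix", gridShape = "integer",
                 setupShiftMm = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@mat) != prod(object@gridShape))
      msg <- c(msg, "row count must equal number of voxels")
    if (any(object@mat@x < 0)) msg <- c(msg, "influence entries must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Planning dose objectives
#'
#' The simultaneous-integrated-boost prescription (57 / 70 Gy to the low-
#' and high-risk CTVs), the per-voxel target bounds used as optimization
#' surrogates for the D98/D2 criteria, and the organ-at-risk mean/max dose
#' constraints with their penalty weights.
#'
#' @slot rxLowGy,rxHighGy prescriptions in Gy(RBE).
#' @slot d98Frac,d2Frac target band bounds as fractions of prescription.
#' @slot wUniform,wUnder,wOver penalty weights of the target terms.
#' @slot oarMean data.frame `role`, `limitGy`, `weight` (mean-dose limits).
#' @slot oarMax data.frame `role`, `limitGy`, `weight` (max-dose limits,
#'   applied per voxel).
#' @exportClass PlanObjectives
setClass("PlanObjectives",
  representation(rxLowGy = "numeric", rxHighGy = "numeric",
                 d98Frac = "numeric", d2Frac = "numeric",
                 wUniform = "numeric", wUnder = "numeric", wOver = "numeric",
                 oarMean = "data.frame", oarMax = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    if (object@rxLowGy <= 0 || object@rxHighGy <= 0)
      msg <- c(msg, "prescriptions must be > 0")
    if (object@d98Frac <= 0 || object@d98Frac > 2 ||
        object@d2Frac <= 0 || object@d2Frac > 2)
      msg <- c(msg, "target band fractions must lie in (0, 2]")
    for (df in list(object@oarMean, object@oarMax))
      if (!all(c("role", "limitGy", "weight") %in% names(df)))
        msg <- c(msg, "OAR constraint tables need columns role, limitGy, weight")
    if (length(msg)) msg else TRUE
  })

#' Setup-robustness setting
#'
#' The isotropic setup uncertainty (mm) and the discrete scenario shifts
#' the minimax optimizer protects against. The nominal (zero) scenario is
#' always included.
#'
#' @slot setupUncertaintyMm scalar >= 0.
#' @slot scenarioShifts numeric matrix (n x 3) of shifts in mm, first row
#'   the nominal zero shift.
#' @exportClass RobustnessSetting
setClass("RobustnessSetting",
  representation(setupUncertaintyMm = "numeric", scenarioShifts = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (object@setupUncertaintyMm < 0)
      msg <- c(msg, "setupUncertaintyMm must be >= 0")
    sh <- object@scenarioShifts
    if (ncol(sh) != 3L) msg <- c(msg, "scenarioShifts must be n x 3")
    else {
      if (!all(sh[1, ] == 0)) msg <- c(msg, "nominal (zero) scenario must come first")
      mags <- sqrt(rowSums(sh^2))
      if (any(mags > object@setupUncertaintyMm + 1e-9))
        msg <- c(msg, "all shift magnitudes must be <= setupUncertaintyMm")
    }
    if (length(msg)) msg else TRUE
  })

#' Optimized IMPT plan
#'
#' @slot spots [SpotSet] with the optimized weights.
#' @slot robustness [RobustnessSetting] used during optimization.
#' @slot objectiveValue achieved worst-case objective.
#' @slot converged logical; `FALSE` means the iteration cap was reached and
#'   the best iterate was returned.
#' @slot phantomHash fingerprint of the planning phantom.
#' @exportClass ProtonPlan
setClass("ProtonPlan",
  representation(spots = "SpotSet", robustness = "RobustnessSetting",
                 objectiveValue = "numeric", converged = "logical",
                 phantomHash = "character"),
  validity = function(object) {
    if (!is.finite(object@objectiveValue)) "objective value must be finite" else TRUE
  })

#' Online-adaptation settings
#'
#' The beamlet-subset rule of the daily re-optimization: the smallest set
#' of spots carrying at least `weightFraction` of the total weight, padded
#' to at least `countFraction` of all spots.
#'
#' @slot weightFraction default 0.33.
#' @slot countFraction default 0.10.
#' @slot maxIter,tol solver settings of the restricted re-optimization.
#' @slot startFrom `"plan"` (default) restarts each fraction from the
#'   original plan weights; `"previous"` chains from the prior fraction.
#' @exportClass AdaptationConfig
setClass("AdaptationConfig",
  representation(weightFraction = "numeric", countFraction = "numeric",
                 maxIter = "integer", tol = "numeric", startFrom = "character"),
  validity = function(object) {
    msg <- character(0)
    if (object@weightFraction <= 0 || object@weightFraction > 1)
      msg <- c(msg, "weightFraction must lie in (0, 1]")
    if (object@countFraction <= 0 || object@countFraction > 1)
      msg <- c(msg, "countFraction must lie in (0, 1]")
    if (!object@startFrom %in% c("plan", "previous"))
      msg <- c(msg, "startFrom must be 'plan' or 'previous'")
    if (length(msg)) msg else TRUE
  })

#' Selected beamlet subset
#'
#' @slot indices sorted unique spot indices.
#' @slot achievedWeightFraction fraction of total weight carried.
#' @slot achievedCountFraction fraction of all spots selected.
#' @exportClass SpotSelection
setClass("SpotSelection",
  representation(indices = "integer", achievedWeightFraction = "numeric",
                 achievedCountFraction = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (anyDuplicated(object@indices)) msg <- c(msg, "indices must be unique")
    if (is.unsorted(object@indices)) msg <- c(msg, "indices must be sorted")
    if (length(msg)) msg else TRUE
  })

#' Accumulated scenario dose
#'
#' Sum over a fraction series of the per-fraction doses mapped back to the
#' planning grid through the ground-truth deformation, for one of the
#' treatment scenarios (A: robust plan unadapted, B: non-robust unadapted,
#' C: non-robust with daily online adaptation).
#'
#' @slot dose numeric array on the planning grid, Gy(RBE).
#' @slot label scenario label.
#' @slot fractionLog data.frame with one row per fraction (shift, daily
#'   objective of the delivered and of the unadapted weights).
#' @exportClass AccumulatedDose
setClass("AccumulatedDose",
  representation(dose = "array", label = "character", fractionLog = "data.frame"),
  validity = function(object) {
    if (any(object@dose < 0)) "accumulated dose must be non-negative" else TRUE
  })

#' NTCP dose-response model
#'
#' One endpoint of the shipped six-model head-and-neck registry. Families:
#' `logistic_d50k` \eqn{(1 + (D50/D)^k)^{-1}} on a mean dose,
#' `probit_geud` \eqn{\Phi((gEUD - D50)/(m D50))},
#' `multivar_logistic` \eqn{(1 + e^{a - b X_1 - c X_2})^{-1}}.
#'
#' @slot endpoint endpoint name.
#' @slot family model family string.
#' @slot structures named character vector mapping model inputs to
#'   structure roles (an `NA` X2 role with a `x2const` parameter denotes a
#'   constant second covariate).
#' @slot params named numeric parameter vector.
#' @exportClass NTCPModel
setClass("NTCPModel",
  representation(endpoint = "character", family = "character",
                 structures = "character", params = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!object@family %in% c("logistic_d50k", "probit_geud", "multivar_logistic"))
      msg <- c(msg, "unknown model family")
    p <- object@params
    if (object@family %in% c("logistic_d50k", "probit_geud") &&
        (!"D50" %in% names(p) || p[["D50"]] <= 0))
      msg <- c(msg, "D50 must be present and > 0")
    if (object@family == "probit_geud" &&
        (!"m" %in% names(p) || p[["m"]] <= 0))
      msg <- c(msg, "m must be present and > 0")
    if (object@family == "probit_geud" &&
        (!"n" %in% names(p) || p[["n"]] == 0))
      msg <- c(msg, "volume parameter n must be non-zero")
    if (length(msg)) msg else TRUE
  })

#' Per-scenario NTCP evaluation
#'
#' @slot label scenario label.
#' @slot results data.frame with columns `endpoint`, `family`, `input1`,
#'   `input2`, `ntcp` (unit-interval probability, `NA` when not
#'   evaluable), `evaluable`, `reason`.
#' @exportClass ScenarioNTCP
setClass("ScenarioNTCP",
  representation(label = "character", results = "data.frame"),
  validity = function(object) {
    r <- object@results
    if (!all(c("endpoint", "ntcp", "evaluable") %in% names(r)))
      return("results must have endpoint, ntcp, evaluable columns")
    v <- r$ntcp[r$evaluable]
    if (any(v < 0 | v > 1, na.rm = TRUE)) return("NTCP values must lie in [0, 1]")
    TRUE
  })

#' Per-patient delta-NTCP report
#'
#' Per-endpoint NTCP differences (percentage points) attributing the
#' toxicity-risk reduction to setup-uncertainty reduction (SUR = B - A),
#' adaptation to geometric changes (AGC = C - B) and both combined
#' (C - A), plus the any-of-four toxicity totals.
#'
#' @slot patientId identifier.
#' @slot endpoints data.frame: `endpoint`, `ntcpA/B/C` (percent),
#'   `dSUR`, `dAGC`, `dBOTH` (pp), `evaluable`.
#' @slot totals data.frame of the any-of-four combined probability per
#'   scenario and its deltas, plus the sum-of-deltas alternative.
#' @slot combination how endpoint probabilities were combined
#'   (`"independence"` complement-product or `"sum"`).
#' @exportClass DeltaNTCPReport
setClass("DeltaNTCPReport",
  representation(patientId = "character", endpoints = "data.frame",
                 totals = "data.frame", combination = "character"))

#' Clinical-significance rule
#'
#' A mechanism counts as clinically significant when any single endpoint
#' reduction meets `singleThresholdPp`, or the summed reduction over the
#' participating endpoints meets `sumThresholdPp` (reductions, i.e.
#' negative deltas, qualify).
#'
#' @slot singleThresholdPp default 10 pp.
#' @slot sumThresholdPp default 15 pp.
#' @slot endpoints participating endpoints.
#' @exportClass SignificanceRule
setClass("SignificanceRule",
  representation(singleThresholdPp = "numeric", sumThresholdPp = "numeric",
                 endpoints = "character"),
  validity = function(object) {
    if (object@singleThresholdPp <= 0 || object@sumThresholdPp <= 0)
      "thresholds must be > 0" else TRUE
  })
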