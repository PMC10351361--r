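# Scenario orchestration: per-fraction dose on the daily anatomy, mapped
# to the planning grid through the ground-truth deformation, accumulated
# over the fraction series.

.dailyPhantom <- function(phantom, fraction) {
  new("Phantom", gridShape = phantom@gridShape, spacingMm = phantom@spacingMm,
      originMm = phantom@originMm, density = fraction@dailyDensity)
}

.isIdentityFraction <- function(fraction) {
  is.null(fraction@dispMm) && all(fraction@setupShiftMm == 0)
}

#' Dose delivered at one fraction
#'
#' Influence on the daily (deformed) anatomy with the fraction's residual
#' setup shift applied as a beam-isocenter translation, times the plan
#' weights, divided by the number of fractions (uniform fractionation of
#' the simultaneous-integrated-boost plan).
#'
#' @param weights spot weight vector to deliver.
#' @param spots the plan's [SpotSet].
#' @param fraction a [FractionAnatomy].
#' @param phantom the planning [Phantom] (grid geometry).
#' @param nFractions total fractions in the series (>= 1).
#' @param influence optional precomputed daily [InfluenceMatrix].
#' @return dose array on the daily grid, Gy(RBE).
#' @export
fractionDose <- function(weights, spots, fraction, phantom, nFractions,
                         influence = NULL) {
  if (nFractions < 1) stop("nFractions must be >= 1")
  if (is.null(influence))
    influence <- computeInfluence(.dailyPhantom(phantom, fraction), spots,
                                  setupShiftMm = fraction@setupShiftMm)
  computeDose(influence, weights) / nFractions
}

#' Map a daily dose onto the planning grid
#'
#' Deformable dose mapping by trilinear pull-back: planning voxel `x`
#' receives the daily dose interpolated at `x + displacement(x)`, the
#' fraction's ground-truth planning-to-daily deformation. Points mapping
#' outside the daily grid contribute zero (with a warning). Identity
#' deformations return the input exactly.
#'
#' @param dailyDose dose array on the daily grid.
#' @param fraction the [FractionAnatomy] whose deformation to use.
#' @param phantom the planning [Phantom].
#' @return dose array on the planning grid.
#' @export
mapToPlanning <- function(dailyDose, fraction, phantom) {
  gs <- phantom@gridShape
  if (!identical(dim(dailyDose), gs)) stop("daily dose shape mismatch")
  if (is.null(fraction@dispMm)) return(dailyDose)
  sp <- phantom@spacingMm; or <- phantom@originMm
  co <- voxelCoordArrays(gs, sp, or)
  pts <- cbind(co$x, co$y, co$z) + matrix(fraction@dispMm, ncol = 3)
  lo <- or; hi <- or + gs * sp
  out <- pts[, 1] < lo[1] | pts[, 1] > hi[1] |
    pts[, 2] < lo[2] | pts[, 2] > hi[2]
  if (gs[3] > 1L) out <- out | pts[, 3] < lo[3] | pts[, 3] > hi[3]
  if (any(out))
    warning(sum(out), " planning voxels map outside the daily grid; ",
            "their accumulated contribution is zero")
  mapped <- trilinearSample(dailyDose, pts, sp, or)
  array(mapped, dim = gs)
}

#' Scenario specification
#'
#' The three scenarios compared by the analysis -- A: 3 mm-robust plan
#' delivered unadapted; B: non-robust plan unadapted; C: non-robust plan
#' with daily online adaptation -- plus the `EXTENDED` 1 mm-robust
#' no-adaptation arm used by the linearity experiment.
#'
#' @param label one of `"A"`, `"B"`, `"C"`, `"EXTENDED"`.
#' @return list with `label`, `plan` (which plan to deliver) and `adapt`.
#' @export
scenarioSpec <- function(label = c("A", "B", "C", "EXTENDED")) {
  label <- match.arg(label)
  switch(label,
         A = list(label = "A", plan = "robust", adapt = FALSE),
         B = list(label = "B", plan = "nonrobust", adapt = FALSE),
         C = list(label = "C", plan = "nonrobust", adapt = TRUE),
         EXTENDED = list(label = "EXTENDED", plan = "robust1mm", adapt = FALSE))
}

#' Run one scenario over a fraction series
#'
#' Delivers the scenario's plan at every fraction (with daily partial
#' re-optimization for scenario C: the beamlet subset is selected from
#' the original planning weights by the 33\%-weight / 10\%-count rule and
#' re-optimized on each fraction's anatomy under the original
#' objectives), maps each fraction dose to the planning grid through the
#' ground-truth deformation, and sums. Identity fractions (zero shift,
#' zero deformation) reuse the nominal planning influence, which is
#' mathematically identical to recomputing it.
#'
#' @param spec a [scenarioSpec()] list.
#' @param plans named list of [ProtonPlan]s providing the plan named by
#'   `spec$plan` (e.g. `robust`, `nonrobust`).
#' @param fractions list of [FractionAnatomy] (one series).
#' @param phantom planning [Phantom].
#' @param objectives [PlanObjectives] (also used for adaptation).
#' @param adaptConfig an [AdaptationConfig].
#' @param nominalInfluence optional precomputed nominal [InfluenceMatrix]
#'   for the plan's spots.
#' @return an [AccumulatedDose]; the per-fraction log records the setup
#'   shift and the daily objective of the delivered and of the unadapted
#'   weights.
#' @export
runScenario <- function(spec, plans, fractions, phantom,
                        objectives = planObjectives(),
                        adaptConfig = adaptationConfig(),
                        nominalInfluence = NULL) {
  plan <- plans[[spec$plan]]
  if (is.null(plan)) stop("no plan supplied for scenario ", spec$label)
  spots <- plan@spots
  wPlan <- plan@spots@weights
  nFx <- length(fractions)
  gs <- phantom@gridShape
  accum <- array(0, dim = gs)
  if (is.null(nominalInfluence)) nominalInfluence <- NA
  selection <- if (spec$adapt) selectSpots(wPlan, adaptConfig) else NULL
  wPrev <- wPlan
  log <- vector("list", nFx)
  for (k in seq_len(nFx)) {
    fx <- fractions[[k]]
    identityFx <- .isIdentityFraction(fx)
    if (identityFx) {
      if (!is(nominalInfluence, "InfluenceMatrix"))
        nominalInfluence <- computeInfluence(phantom, spots)
      Ddaily <- nominalInfluence
    } else {
      Ddaily <- computeInfluence(.dailyPhantom(phantom, fx), spots,
                                 setupShiftMm = fx@setupShiftMm)
    }
    structuresDaily <- fx@dailyStructures
    objBase <- evaluateObjective(computeDose(Ddaily, wPlan),
                                 structuresDaily, objectives)
    if (spec$adapt) {
      base <- if (adaptConfig@startFrom == "plan") wPlan else wPrev
      wUse <- reoptimizeWeights(Ddaily, base, selection, structuresDaily,
                                objectives, adaptConfig)
      wPrev <- wUse
      objUsed <- evaluateObjective(computeDose(Ddaily, wUse),
                                   structuresDaily, objectives)
    } else {
      wUse <- wPlan
      objUsed <- objBase
    }
    daily <- fractionDose(wUse, spots, fx, phantom, nFx, influence = Ddaily)
    accum <- accum + mapToPlanning(daily, fx, phantom)
    log[[k]] <- data.frame(fraction = fx@fractionIndex,
                           shiftX = fx@setupShiftMm[1],
                           shiftY = fx@setupShiftMm[2],
                           shiftZ = fx@setupShiftMm[3],
                           objUnadapted = objBase, objDelivered = objUsed)
  }
  new("AccumulatedDose", dose = accum, label = spec$label,
      fractionLog = do.call(rbind, log))
}
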