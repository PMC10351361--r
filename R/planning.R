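# Treatment planning: spot placement, the composite dose objective, and
# minimax-robust non-negative spot-weight optimization.

#' Default planning objectives
#'
#' The simultaneous-integrated-boost prescription (57 Gy low-risk, 70 Gy
#' high-risk CTV), per-voxel target bounds at 95\% and 107\% of
#' prescription standing in for the D98/D2 criteria, and the OAR limits:
#' mean dose < 26 Gy to each parotid, < 42 Gy to the superior pharyngeal
#' constrictor, < 40 Gy to the larynx; max dose < 45 Gy to the spinal
#' cord and < 54 Gy to the brainstem. A two-sided uniform-dose term pulls
#' the target dose toward the prescription so the optimum is unique; the
#' one-sided band and OAR terms are pure constraint penalties (zero when
#' satisfied).
#'
#' @param rxLowGy,rxHighGy prescriptions in Gy(RBE).
#' @param d98Frac,d2Frac target band bounds (fractions of prescription).
#' @param wUniform,wUnder,wOver target penalty weights.
#' @param oarMean,oarMax data.frames `role`, `limitGy`, `weight`.
#' @return a [PlanObjectives].
#' @export
planObjectives <- function(rxLowGy = 57, rxHighGy = 70,
                           d98Frac = 0.95, d2Frac = 1.07,
                           wUniform = 1, wUnder = 10, wOver = 10,
                           oarMean = data.frame(
                             role = c("PAROTID_CONTRA", "PAROTID_IPSI",
                                      "PCM_SUPERIOR", "LARYNX"),
                             limitGy = c(26, 26, 42, 40),
                             weight = c(2, 2, 2, 2)),
                           oarMax = data.frame(
                             role = c("SPINAL_CORD", "BRAINSTEM"),
                             limitGy = c(45, 54),
                             weight = c(10, 10))) {
  new("PlanObjectives", rxLowGy = rxLowGy, rxHighGy = rxHighGy,
      d98Frac = d98Frac, d2Frac = d2Frac, wUniform = wUniform,
      wUnder = wUnder, wOver = wOver, oarMean = oarMean, oarMax = oarMax)
}

#' Setup-robustness setting with the discrete minimax scenario set
#'
#' For an isotropic setup uncertainty of `mm`, the scenario set is the
#' nominal geometry plus the six axis-aligned shifts of magnitude `mm`
#' (the standard discrete approximation of an isotropic uncertainty).
#' `mm = 0` yields the nominal-only setting (non-robust plan). In
#' single-slice mode only the four in-plane shifts are used.
#'
#' @param mm isotropic setup uncertainty in mm (>= 0).
#' @param twoD drop the out-of-plane shifts (single-slice grids).
#' @return a [RobustnessSetting].
#' @export
robustnessSetting <- function(mm, twoD = FALSE) {
  shifts <- matrix(0, 1, 3)
  if (mm > 0) {
    ax <- if (twoD) 1:2 else 1:3
    for (a in ax) for (sgn in c(1, -1)) {
      s <- c(0, 0, 0); s[a] <- sgn * mm
      shifts <- rbind(shifts, s)
    }
  }
  dimnames(shifts) <- NULL
  new("RobustnessSetting", setupUncertaintyMm = mm, scenarioShifts = shifts)
}

#' Place scanned spots covering the target volumes
#'
#' For each gantry angle, lays a lateral grid (beam's-eye view) over the
#' union of the two CTVs and, at every lateral position that intersects
#' the target, places one spot per energy layer spanning the
#' water-equivalent depth extent of the target there. Every target voxel
#' ends up within one lateral spacing of a spot axis and one layer
#' spacing of a spot peak. Deterministic.
#'
#' @param phantom planning [Phantom].
#' @param structures [StructureSet] containing `CTV_LOW` (and usually
#'   `CTV_HIGH`).
#' @param anglesDeg gantry angles in degrees (default 60, 180, 300).
#' @param lateralSpacingMm spot spacing on the lateral grid (mm).
#' @param layerSpacingMm energy-layer spacing in water-equivalent mm.
#' @return a [SpotSet] with zero weights and the isocenter at the target
#'   centroid.
#' @export
placeSpots <- function(phantom, structures, anglesDeg = c(60, 180, 300),
                       lateralSpacingMm = 6, layerSpacingMm = 6) {
  stopifnot(is(phantom, "Phantom"), is(structures, "StructureSet"))
  if (lateralSpacingMm <= 0 || layerSpacingMm <= 0)
    stop("spot spacings must be > 0")
  ctvLow <- structures@masks[["CTV_LOW"]]
  ctvHigh <- structures@masks[["CTV_HIGH"]]
  if (is.null(ctvLow) || !any(ctvLow)) stop("CTV_LOW is empty")
  target <- ctvLow
  if (!is.null(ctvHigh)) target <- target | ctvHigh
  gs <- phantom@gridShape; sp <- phantom@spacingMm; or <- phantom@originMm
  iso <- .maskCentroid(target, sp, or)
  nxy <- gs[1] * gs[2]; nz <- gs[3]
  co <- voxelAxes(gs, sp, or)
  zVox <- rep(co[[3]], each = nxy) - iso[3]
  tgtIdx <- which(as.vector(target))
  rows <- list()
  for (ang in anglesDeg) {
    B3 <- .beamAxes(ang)
    op <- .wedOperators(gs, sp, or, ang)
    wed <- .wedField(phantom@density, gs, sp, or, ang)
    tShift <- sum((iso[1:2] - op$c0[1:2]) * B3$t[1:2])
    tAll <- rep(op$tVox, times = nz) - tShift
    tT <- tAll[tgtIdx]; zT <- zVox[tgtIdx]; wT <- wed[tgtIdx]
    tGrid <- seq(min(tT), max(tT) + lateralSpacingMm / 2, by = lateralSpacingMm)
    zGrid <- if (nz == 1L) 0 else
      seq(min(zT), max(zT) + lateralSpacingMm / 2, by = lateralSpacingMm)
    for (tk in tGrid) for (zk in zGrid) {
      cell <- abs(tT - tk) <= lateralSpacingMm / 2 + 1e-9 &
        abs(zT - zk) <= lateralSpacingMm / 2 + 1e-9
      if (!any(cell)) next
      w1 <- min(wT[cell]); w2 <- max(wT[cell])
      ranges <- seq(w1, w2 + layerSpacingMm / 2, by = layerSpacingMm)
      for (R in ranges)
        rows[[length(rows) + 1L]] <-
          data.frame(angleDeg = ang, tMm = tk, zMm = zk, rangeMm = max(R, 1))
    }
  }
  df <- do.call(rbind, rows)
  df <- cbind(id = seq_len(nrow(df)), df)
  new("SpotSet", spots = df, weights = rep(0, nrow(df)), isocenterMm = iso)
}

# index bookkeeping for fast objective evaluation: restrict the influence
# operator to the voxels any objective term touches.
.objectiveContext <- function(structures, objectives) {
  masks <- structures@masks
  need <- c("CTV_HIGH", "CTV_LOW", objectives@oarMean$role, objectives@oarMax$role)
  for (r in unique(need))
    if (is.null(masks[[r]]))
      stop("objective references missing structure role '", r, "'")
  tgtH <- which(as.vector(masks$CTV_HIGH))
  tgtL <- which(as.vector(masks$CTV_LOW))
  vox <- sort(unique(c(tgtH, tgtL,
                       unlist(lapply(objectives@oarMean$role,
                                     function(r) which(as.vector(masks[[r]])))),
                       unlist(lapply(objectives@oarMax$role,
                                     function(r) which(as.vector(masks[[r]])))))))
  loc <- function(idx) match(idx, vox)
  rx <- c(rep(objectives@rxHighGy, length(tgtH)),
          rep(objectives@rxLowGy, length(tgtL)))
  list(vox = vox,
       tgt = c(loc(tgtH), loc(tgtL)), rx = rx,
       oarMean = lapply(seq_len(nrow(objectives@oarMean)), function(i) {
         r <- objectives@oarMean$role[i]
         list(idx = loc(which(as.vector(masks[[r]]))),
              limit = objectives@oarMean$limitGy[i],
              weight = objectives@oarMean$weight[i])
       }),
       oarMax = lapply(seq_len(nrow(objectives@oarMax)), function(i) {
         r <- objectives@oarMax$role[i]
         list(idx = loc(which(as.vector(masks[[r]]))),
              limit = objectives@oarMax$limitGy[i],
              weight = objectives@oarMax$weight[i])
       }))
}

# objective value (and optionally d(objective)/d(dose) on the context
# voxels) from the dose restricted to context voxels.
.objectiveOnContext <- function(dSub, ctx, obj, grad = FALSE) {
  nT <- length(ctx$tgt)
  dT <- dSub[ctx$tgt]
  dev <- dT - ctx$rx
  under <- pmax(0, obj@d98Frac * ctx$rx - dT)
  over <- pmax(0, dT - obj@d2Frac * ctx$rx)
  val <- obj@wUniform * mean(dev^2) + obj@wUnder * mean(under^2) +
    obj@wOver * mean(over^2)
  g <- if (grad) numeric(length(dSub)) else NULL
  if (grad) {
    g[ctx$tgt] <- g[ctx$tgt] + 2 / nT *
      (obj@wUniform * dev - obj@wUnder * under + obj@wOver * over)
  }
  for (tm in ctx$oarMean) {
    mn <- mean(dSub[tm$idx])
    exc <- max(0, mn - tm$limit)
    val <- val + tm$weight * exc^2
    if (grad && exc > 0)
      g[tm$idx] <- g[tm$idx] + 2 * tm$weight * exc / length(tm$idx)
  }
  for (tm in ctx$oarMax) {
    exc <- pmax(0, dSub[tm$idx] - tm$limit)
    val <- val + tm$weight * mean(exc^2)
    if (grad)
      g[tm$idx] <- g[tm$idx] + 2 * tm$weight * exc / length(tm$idx)
  }
  list(value = val, grad = g)
}

#' Evaluate the planning objective of a dose distribution
#'
#' Sum of the target terms (two-sided uniform-dose deviation from the
#' prescription plus one-sided penalties below 95\% and above 107\% of
#' prescription, averaged per voxel) and the OAR terms (quadratic excess
#' of the structure mean dose over its limit, weighted per constraint,
#' and per-voxel quadratic excess over the max-dose limits). Zero when
#' the targets are exactly at prescription and every OAR constraint is
#' met; dose outside all constrained structures does not contribute.
#'
#' @param dose dose array (or vector) on the planning grid, Gy(RBE).
#' @param structures [StructureSet]; every role referenced by a
#'   constraint must be present.
#' @param objectives a [PlanObjectives].
#' @return scalar penalty (>= 0).
#' @export
evaluateObjective <- function(dose, structures, objectives = planObjectives()) {
  ctx <- .objectiveContext(structures, objectives)
  d <- as.vector(dose)
  .objectiveOnContext(d[ctx$vox], ctx, objectives, grad = FALSE)$value
}

#' Minimax-robust spot-weight optimization
#'
#' Minimizes the worst case over the setup-error scenarios of the
#' planning objective, subject to non-negative weights, using L-BFGS-B on
#' a log-sum-exp smoothed maximum (smoothing scale `tau` relative to the
#' starting objective). With a single (nominal) scenario this reduces
#' exactly to plain non-robust optimization. The returned objective never
#' exceeds the objective of the warm start under the same scenarios.
#'
#' @param influences list of [InfluenceMatrix], one per scenario shift of
#'   `robustness` (same spot ordering).
#' @param structures planning [StructureSet].
#' @param objectives a [PlanObjectives].
#' @param robustness the [RobustnessSetting] the influences realize.
#' @param spots the [SpotSet] the influences were computed from.
#' @param w0 optional warm-start weights (default: a uniform weight
#'   scaled by least squares to the prescription).
#' @param maxIter iteration cap (default 500).
#' @param tau relative smoothing of the scenario max.
#' @return a [ProtonPlan]; `converged = FALSE` flags an iteration-capped
#'   run (best iterate returned).
#' @export
optimizeWeights <- function(influences, structures, objectives, robustness,
                            spots, w0 = NULL, maxIter = 500, tau = 1e-3) {
  stopifnot(length(influences) >= 1,
            length(influences) == nrow(robustness@scenarioShifts))
  nspot <- ncol(influences[[1]]@mat)
  for (D in influences)
    if (ncol(D@mat) != nspot) stop("influence matrices must share spot ordering")
  ctx <- .objectiveContext(structures, objectives)
  subs <- lapply(influences, function(D) D@mat[ctx$vox, , drop = FALSE])
  if (is.null(w0)) {
    a <- as.vector(subs[[1]] %*% rep(1, nspot))[ctx$tgt]
    cc <- sum(a * ctx$rx) / max(sum(a^2), 1e-12)
    w0 <- rep(max(cc, 0), nspot)
  }
  scen <- function(w, grad = FALSE)
    lapply(subs, function(S) {
      r <- .objectiveOnContext(as.vector(S %*% w), ctx, objectives, grad = grad)
      if (grad) r$gw <- as.vector(Matrix::crossprod(S, r$grad))
      r
    })
  f0 <- max(vapply(scen(w0), `[[`, numeric(1), "value"))
  tauAbs <- max(tau * max(f0, 1), 1e-12)
  smoothMax <- function(vals) {
    m <- max(vals)
    m + tauAbs * log(sum(exp((vals - m) / tauAbs)))
  }
  fn <- function(w) {
    vals <- vapply(scen(w), `[[`, numeric(1), "value")
    smoothMax(vals)
  }
  gr <- function(w) {
    rs <- scen(w, grad = TRUE)
    vals <- vapply(rs, `[[`, numeric(1), "value")
    sw <- exp((vals - max(vals)) / tauAbs)
    sw <- sw / sum(sw)
    Reduce(`+`, Map(function(r, s) s * r$gw, rs, sw))
  }
  fit <- optim(w0, fn, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = maxIter, factr = 1e7))
  w <- pmax(fit$par, 0)
  worst <- max(vapply(scen(w), `[[`, numeric(1), "value"))
  worst0 <- max(vapply(scen(w0), `[[`, numeric(1), "value"))
  if (worst > worst0) { w <- w0; worst <- worst0 }  # never worse than warm start
  ss <- spots
  ss@weights <- w
  new("ProtonPlan", spots = ss, robustness = robustness,
      objectiveValue = worst, converged = fit$convergence == 0L,
      phantomHash = "")
}

#' Create a full plan for a phantom at a given robustness setting
#'
#' Convenience wrapper: builds the scenario influence matrices for the
#' setting's shifts and runs the minimax optimization.
#'
#' @param phantom planning [Phantom].
#' @param structures planning [StructureSet].
#' @param spots [SpotSet] from [placeSpots()].
#' @param robustness a [RobustnessSetting].
#' @param objectives a [PlanObjectives].
#' @param nominalInfluence optional precomputed nominal-geometry
#'   [InfluenceMatrix] (reused as the first scenario).
#' @param ... passed on to [optimizeWeights()].
#' @return a [ProtonPlan].
#' @export
makePlan <- function(phantom, structures, spots, robustness,
                     objectives = planObjectives(),
                     nominalInfluence = NULL, ...) {
  shifts <- robustness@scenarioShifts
  infl <- lapply(seq_len(nrow(shifts)), function(i) {
    if (i == 1L && !is.null(nominalInfluence)) return(nominalInfluence)
    computeInfluence(phantom, spots, setupShiftMm = shifts[i, ])
  })
  plan <- optimizeWeights(infl, structures, objectives, robustness, spots, ...)
  plan@phantomHash <- .phantomFingerprint(phantom)
  plan
}

.phantomFingerprint <- function(phantom) {
  paste(c(phantom@gridShape, signif(sum(phantom@density), 12),
          signif(sum(phantom@density * seq_along(phantom@density)), 12)),
        collapse = "-")
}
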