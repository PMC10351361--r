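# Synthetic phantoms and per-fraction anatomy series.
#
# The generator emulates the statistical structure the scenario analysis
# assumes: a residual rigid setup error per fraction (i.i.d. Gaussian per
# axis, modelling what is left AFTER the online 6-DOF alignment) plus a
# systematic anatomical drift (parotid/target shrinkage toward their
# centroids and a larynx offset) that grows monotonically over the course
# and is stored with its ground-truth inverse deformation.

#' Cohort configuration
#'
#' Study conditions of the synthetic cohort. Defaults: fractions sampled
#' uniformly in 30--35; residual setup error SD 1.5 mm per axis; parotids
#' contracting by 10\% (linear) over the course; 4 mm peak larynx offset
#' (the larynx moves substantially more between fractions than the
#' oropharyngeal organs); 64 x 64 x 32 grid at 2 mm isotropic spacing.
#' Use `gridShape = c(64, 64, 1)` for the fast single-slice mode.
#'
#' @param nPatients number of synthetic patients.
#' @param fractionRange inclusive integer range fractions are sampled from.
#' @param setupSigmaMm residual setup error SD per axis (mm).
#' @param parotidShrink total fractional linear parotid contraction.
#' @param targetShrink total fractional linear high-risk CTV contraction.
#' @param larynxAmpMm peak larynx displacement amplitude (mm).
#' @param gridShape integer length-3 voxel grid.
#' @param spacingMm voxel spacing (mm), 2 mm isotropic by default.
#' @param seed base random seed.
#' @return a [CohortConfig].
#' @examples
#' cfg <- cohortConfig(nPatients = 2, gridShape = c(64, 64, 1))
#' @export
cohortConfig <- function(nPatients = 10, fractionRange = c(30, 35),
                         setupSigmaMm = 1.5, parotidShrink = 0.10,
                         targetShrink = 0.05, larynxAmpMm = 4,
                         gridShape = c(64, 64, 32), spacingMm = c(2, 2, 2),
                         seed = 1) {
  new("CohortConfig", nPatients = as.integer(nPatients),
      fractionRange = as.integer(fractionRange),
      setupSigmaMm = as.numeric(setupSigmaMm),
      parotidShrink = as.numeric(parotidShrink),
      targetShrink = as.numeric(targetShrink),
      larynxAmpMm = as.numeric(larynxAmpMm),
      gridShape = as.integer(gridShape),
      spacingMm = as.numeric(spacingMm), seed = as.integer(seed))
}

# Baseline organ layout in coordinates normalized to the grid extent
# (in-plane fractions of extentX/extentY, z as fraction of extentZ).
# Idealized neck cross-section: posterior = low y, anterior = high y,
# target volumes lateralized to the right (ipsilateral) side.
.organLayout <- function() {
  L <- list(
    BODY                = list(c = c(0.50, 0.45, 0.50), r = c(0.47, 0.42, 0.60)),
    SPINAL_CORD         = list(c = c(0.50, 0.23, 0.50), r = c(0.035, 0.035, 0.60)),
    BRAINSTEM           = list(c = c(0.50, 0.11, 0.78), r = c(0.040, 0.040, 0.22)),
    ESOPHAGUS           = list(c = c(0.44, 0.27, 0.25), r = c(0.030, 0.030, 0.28)),
    PCM_SUPERIOR        = list(c = c(0.50, 0.295, 0.58), r = c(0.065, 0.035, 0.24)),
    LARYNX              = list(c = c(0.50, 0.44, 0.42), r = c(0.070, 0.060, 0.28)),
    LARYNX_SUPRAGLOTTIC = list(c = c(0.42, 0.47, 0.58), r = c(0.060, 0.045, 0.14)),
    ORAL_MUCOSA         = list(c = c(0.46, 0.66, 0.62), r = c(0.130, 0.095, 0.30)),
    CTV_HIGH            = list(c = c(0.69, 0.44, 0.50), r = c(0.095, 0.085, 0.26)),
    CTV_LOW             = list(c = c(0.625, 0.42, 0.50), r = c(0.170, 0.125, 0.31)),
    PAROTID_IPSI        = list(c = c(0.80, 0.55, 0.63), r = c(0.060, 0.075, 0.23)),
    PAROTID_CONTRA      = list(c = c(0.20, 0.55, 0.63), r = c(0.060, 0.075, 0.23))
  )
  L
}

.ellipsoidMask <- function(gridShape, spacingMm, originMm, centerMm, radiiMm) {
  ax <- voxelAxes(gridShape, spacingMm, originMm)
  dx2 <- ((ax[[1]] - centerMm[1]) / radiiMm[1])^2
  dy2 <- ((ax[[2]] - centerMm[2]) / radiiMm[2])^2
  if (gridShape[3] == 1L) dz2 <- 0
  else dz2 <- ((ax[[3]] - centerMm[3]) / radiiMm[3])^2
  arr <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  dim(arr) <- gridShape
  arr
}

#' Generate a synthetic planning phantom and its structure set
#'
#' Builds an idealized head-and-neck cross-section: a water-density body
#' with ellipsoidal organs (two CTVs, both parotids, superior pharyngeal
#' constrictor, larynx and supraglottic larynx, oral mucosa/oral cavity,
#' spinal cord, brainstem, esophagus). Organ positions and sizes are
#' jittered per patient under the cohort seed, so repeated calls with the
#' same `(config, patientIndex)` are bitwise identical. The high- and
#' low-risk CTVs are generated disjoint (the low-risk volume is the shell
#' around the boost volume) and never overlap spinal cord or brainstem.
#'
#' @param config a [CohortConfig].
#' @param patientIndex patient number in `1..nPatients`.
#' @return list with elements `phantom` ([Phantom]) and
#'   `structures` ([StructureSet]).
#' @examples
#' p <- generatePhantom(cohortConfig(nPatients = 1, gridShape = c(64, 64, 1)), 1)
#' sum(structureMask(p$structures, "CTV_HIGH"))
#' @export
generatePhantom <- function(config, patientIndex) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  if (patientIndex < 1 || patientIndex > config@nPatients)
    stop("patientIndex must lie in [1, nPatients]")
  gs <- config@gridShape
  if (gs[1] < 32L || gs[2] < 32L)
    stop("gridShape too small to host all structures (need >= 32 voxels in-plane)")
  sp <- config@spacingMm
  origin <- c(0, 0, 0)
  extent <- gs * sp
  layout <- .organLayout()

  seed <- (config@seed * 7919 + patientIndex * 104729) %% 2147483647
  layout <- withSeed(seed, {
    for (nm in names(layout)) {
      if (nm == "BODY") next
      jc <- rnorm(3, 0, 0.012)
      jr <- runif(3, 0.93, 1.07)
      layout[[nm]]$c <- layout[[nm]]$c + jc
      layout[[nm]]$r <- layout[[nm]]$r * jr
    }
    layout
  })

  toMm <- function(v) v * extent
  mk <- function(nm) .ellipsoidMask(gs, sp, origin, toMm(layout[[nm]]$c),
                                    toMm(layout[[nm]]$r))
  body <- mk("BODY")
  masks <- list()
  for (nm in setdiff(names(layout), "BODY")) masks[[nm]] <- mk(nm) & body
  # low-risk CTV is the shell around the boost volume (disjoint by design)
  masks$CTV_LOW <- masks$CTV_LOW & !masks$CTV_HIGH
  # hard anatomical exclusions: CTVs never overlap cord or brainstem
  excl <- masks$SPINAL_CORD | masks$BRAINSTEM
  masks$CTV_HIGH <- masks$CTV_HIGH & !excl
  masks$CTV_LOW <- masks$CTV_LOW & !excl

  density <- array(0, dim = gs)
  density[body] <- 1
  phantom <- new("Phantom", gridShape = gs, spacingMm = sp,
                 originMm = origin, density = density)
  structures <- new("StructureSet", masks = masks, gridShape = gs)
  list(phantom = phantom, structures = structures)
}

# Centroid (mm) and rms radius of a mask.
.maskCentroid <- function(mask, spacingMm, originMm) {
  co <- voxelCoordArrays(dim(mask), spacingMm, originMm)
  w <- as.vector(mask)
  c(mean(co$x[w]), mean(co$y[w]), mean(co$z[w]))
}

.maskRmsRadius <- function(mask, spacingMm, originMm, center) {
  co <- voxelCoordArrays(dim(mask), spacingMm, originMm)
  w <- as.vector(mask)
  d2 <- (co$x[w] - center[1])^2 + (co$y[w] - center[2])^2 +
    (co$z[w] - center[3])^2
  sqrt(mean(d2))
}

# Full-amplitude drift field U (nx, ny, nz, 3): radial contraction of the
# parotids and high-risk CTV plus a directional larynx offset, each under a
# Gaussian spatial window so the composite field stays smooth.
.baseDriftField <- function(phantom, structures, config) {
  gs <- phantom@gridShape; sp <- phantom@spacingMm; or <- phantom@originMm
  co <- voxelCoordArrays(gs, sp, or)
  n <- prod(gs)
  U <- matrix(0, n, 3)
  contract <- function(role, frac, widen = 1.8) {
    m <- structures@masks[[role]]
    if (is.null(m) || !any(m)) return(invisible())
    ctr <- .maskCentroid(m, sp, or)
    re <- .maskRmsRadius(m, sp, or, ctr)
    sig <- widen * re
    d2 <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2
    w <- exp(-d2 / (2 * sig^2))
    U[, 1] <<- U[, 1] - frac * (co$x - ctr[1]) * w
    U[, 2] <<- U[, 2] - frac * (co$y - ctr[2]) * w
    if (gs[3] > 1L) U[, 3] <<- U[, 3] - frac * (co$z - ctr[3]) * w
  }
  if (config@parotidShrink > 0) {
    contract("PAROTID_CONTRA", config@parotidShrink)
    contract("PAROTID_IPSI", config@parotidShrink)
  }
  if (config@targetShrink > 0) contract("CTV_HIGH", config@targetShrink)
  if (config@larynxAmpMm > 0) {
    m <- structures@masks[["LARYNX"]]
    if (!is.null(m) && any(m)) {
      ctr <- .maskCentroid(m, sp, or)
      re <- .maskRmsRadius(m, sp, or, ctr)
      sig <- 1.3 * re
      d2 <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2
      w <- config@larynxAmpMm * exp(-d2 / (2 * sig^2))
      if (gs[3] > 1L) U[, 3] <- U[, 3] + w else U[, 2] <- U[, 2] + w
    }
  }
  array(U, dim = c(gs, 3))
}

# Numerically invert a displacement field by fixed-point iteration on
# x = y - d(x).
.invertDisplacement <- function(disp, spacingMm, originMm, iters = 20) {
  gs <- dim(disp)[1:3]
  co <- voxelCoordArrays(gs, spacingMm, originMm)
  Y <- cbind(co$x, co$y, co$z)
  X <- Y
  d1 <- disp[, , , 1, drop = FALSE]; dim(d1) <- gs
  d2 <- disp[, , , 2, drop = FALSE]; dim(d2) <- gs
  d3 <- disp[, , , 3, drop = FALSE]; dim(d3) <- gs
  for (it in seq_len(iters)) {
    dX <- cbind(trilinearSample(d1, X, spacingMm, originMm),
                trilinearSample(d2, X, spacingMm, originMm),
                trilinearSample(d3, X, spacingMm, originMm))
    X <- Y - dX
  }
  inv <- X - Y
  array(inv, dim = c(gs, 3))
}

# Max discrete gradient (mm per mm) of a displacement field.
.maxFieldGradient <- function(disp, spacingMm) {
  gs <- dim(disp)[1:3]
  g <- 0
  for (comp in 1:3) {
    a <- disp[, , , comp, drop = FALSE]; dim(a) <- gs
    if (gs[1] > 1)
      g <- max(g, max(abs(a[-1, , , drop = FALSE] -
                          a[-gs[1], , , drop = FALSE])) / spacingMm[1])
    if (gs[2] > 1)
      g <- max(g, max(abs(a[, -1, , drop = FALSE] -
                          a[, -gs[2], , drop = FALSE])) / spacingMm[2])
    if (gs[3] > 1)
      g <- max(g, max(abs(a[, , -1, drop = FALSE] -
                          a[, , -gs[3], drop = FALSE])) / spacingMm[3])
  }
  g
}

# Pull an image (numeric array) from planning to daily coordinates:
# daily(y) = planning(y + invDisp(y)).
.deformImage <- function(img, invDisp, spacingMm, originMm) {
  gs <- dim(img)
  co <- voxelCoordArrays(gs, spacingMm, originMm)
  Y <- cbind(co$x, co$y, co$z)
  inv <- matrix(invDisp, ncol = 3)
  out <- trilinearSample(img, Y + inv, spacingMm, originMm)
  array(out, dim = gs)
}

#' Generate the per-fraction anatomy series of one patient
#'
#' Draws the number of fractions uniformly from the configured range,
#' samples i.i.d. Gaussian residual setup shifts (SD `setupSigmaMm` per
#' axis), and applies the systematic drift field scaled by a monotone ramp
#' `k / nFractions`, storing for every fraction the forward displacement,
#' its numerically inverted ground-truth inverse, and the deformed daily
#' density and structure masks. With zero setup error and zero drift
#' amplitudes every fraction is exactly the planning anatomy.
#'
#' @param phantom,structures output of [generatePhantom()].
#' @param config the same [CohortConfig].
#' @param patientIndex patient number in `1..nPatients`.
#' @return list of [FractionAnatomy], one per fraction.
#' @export
generateFractionSeries <- function(phantom, structures, config, patientIndex) {
  stopifnot(is(phantom, "Phantom"), is(structures, "StructureSet"),
            is(config, "CohortConfig"))
  if (patientIndex < 1 || patientIndex > config@nPatients)
    stop("patientIndex must lie in [1, nPatients]")
  gs <- phantom@gridShape; sp <- phantom@spacingMm; or <- phantom@originMm
  seed <- (config@seed * 7919 + patientIndex * 104729 + 13) %% 2147483647
  fxChoices <- seq(config@fractionRange[1], config@fractionRange[2])
  nFx <- if (length(fxChoices) == 1L) fxChoices
    else withSeed(seed, sample(fxChoices, 1))
  shifts <- withSeed(seed + 1, matrix(rnorm(nFx * 3, 0, config@setupSigmaMm),
                                      nFx, 3))
  if (gs[3] == 1L) shifts[, 3] <- 0

  hasDrift <- config@parotidShrink > 0 || config@targetShrink > 0 ||
    config@larynxAmpMm > 0
  U <- if (hasDrift) .baseDriftField(phantom, structures, config) else NULL
  if (!is.null(U) && .maxFieldGradient(U, sp) > 0.5)
    warning("drift field gradient exceeds smoothness cap 0.5; ",
            "reduce drift amplitudes")

  maskNames <- names(structures@masks)
  lapply(seq_len(nFx), function(k) {
    if (is.null(U)) {
      return(new("FractionAnatomy", fractionIndex = as.integer(k),
                 setupShiftMm = shifts[k, ], dispMm = NULL, invDispMm = NULL,
                 dailyDensity = phantom@density, dailyStructures = structures))
    }
    ramp <- k / nFx
    disp <- U * ramp
    inv <- .invertDisplacement(disp, sp, or)
    dens <- .deformImage(phantom@density, inv, sp, or)
    dens[dens < 0] <- 0
    dmasks <- lapply(structures@masks, function(m) {
      s <- .deformImage(array(as.numeric(m), dim = gs), inv, sp, or)
      arr <- s >= 0.5
      dim(arr) <- gs
      arr
    })
    names(dmasks) <- maskNames
    new("FractionAnatomy", fractionIndex = as.integer(k),
        setupShiftMm = shifts[k, ], dispMm = disp, invDispMm = inv,
        dailyDensity = dens,
        dailyStructures = new("StructureSet", masks = dmasks, gridShape = gs))
  })
}

#' Ground-truth invertibility error of a fraction's deformation
#'
#' Largest voxel-unit distance between a planning point and the round trip
#' through the stored forward and inverse displacement fields. Identity
#' fractions return 0.
#'
#' @param fraction a [FractionAnatomy].
#' @param phantom the planning [Phantom].
#' @return max composition error in voxel units.
#' @export
deformationInverseError <- function(fraction, phantom) {
  if (is.null(fraction@dispMm)) return(0)
  gs <- phantom@gridShape; sp <- phantom@spacingMm; or <- phantom@originMm
  co <- voxelCoordArrays(gs, sp, or)
  X <- cbind(co$x, co$y, co$z)
  Y <- X + matrix(fraction@dispMm, ncol = 3)
  inv <- lapply(1:3, function(comp) {
    a <- fraction@invDispMm[, , , comp, drop = FALSE]; dim(a) <- gs
    trilinearSample(a, Y, sp, or)
  })
  Xback <- Y + do.call(cbind, inv)
  # restrict to points whose image stays inside the grid (the inverse is
  # sampled with zero padding outside)
  lo <- or + 0.5 * sp; hi <- or + gs * sp - 0.5 * sp
  inb <- Y[, 1] >= lo[1] & Y[, 1] <= hi[1] & Y[, 2] >= lo[2] & Y[, 2] <= hi[2]
  if (gs[3] > 1L) inb <- inb & Y[, 3] >= lo[3] & Y[, 3] <= hi[3]
  err <- sqrt(rowSums((Xback - X)^2)) / min(sp)
  max(err[inb])
}
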