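# Analytic spot-based proton dose engine.
#
# Each spot deposits a parametrized Bragg depth-dose along its ray (depth
# measured in water-equivalent mm via the density line integral) times a
# lateral Gaussian whose width grows with depth. Gantry angles rotate in
# the axial (x-y) plane; the second beam's-eye-view lateral axis is z.
# Doses are Gy(RBE) per unit spot weight with the constant biological
# effectiveness factor 1.1 folded into the influence matrix.

# beam direction (unit, into the patient) and in-plane lateral axis for a
# gantry angle in degrees (0 = beam entering from anterior/+y).
.beamAxes <- function(angleDeg) {
  th <- angleDeg * pi / 180
  u <- c(-sin(th), -cos(th), 0)
  tv <- c(u[2], -u[1], 0)
  list(u = u, t = tv)
}

#' Pristine Bragg depth-dose curve
#'
#' Analytic single-peaked depth-dose: a plateau that switches off past the
#' range through a smoothed step, plus a Gaussian peak centered at the
#' nominal range with a broader proximal and a sharp (1 mm default) distal
#' width. The curve is continuous, has its maximum at the range, and falls
#' below 1\% of the peak a few distal widths beyond it. Units are
#' dose-per-unit-weight (arbitrary but fixed scale).
#'
#' @param rangeMm nominal range in water-equivalent mm (> 0).
#' @param depthMm water-equivalent depth(s), >= 0.
#' @param distalSigmaMm distal falloff width (mm).
#' @return numeric vector of the same length as `depthMm`.
#' @examples
#' depthDose(100, c(0, 50, 100, 120))
#' @export
depthDose <- function(rangeMm, depthMm, distalSigmaMm = 1) {
  if (any(rangeMm <= 0)) stop("rangeMm must be > 0")
  if (any(depthMm < 0)) stop("depthMm must be non-negative")
  sigP <- pmax(0.04 * rangeMm, 2)
  sig <- ifelse(depthMm < rangeMm, sigP, distalSigmaMm)
  plateau <- 0.3 * pnorm((rangeMm + 2 * distalSigmaMm - depthMm) / distalSigmaMm)
  peak <- 0.9 * exp(-(depthMm - rangeMm)^2 / (2 * sig^2))
  plateau + peak
}

# cache of geometry-only rotation/sampling operators, keyed by grid + angle
.wedCache <- new.env(parent = emptyenv())

.wedOperators <- function(gridShape, spacingMm, originMm, angleDeg) {
  key <- paste(c(gridShape, round(spacingMm, 6), round(originMm, 6),
                 round(angleDeg, 4)), collapse = "|")
  hit <- .wedCache[[key]]
  if (!is.null(hit)) return(hit)
  ax <- voxelAxes(gridShape, spacingMm, originMm)
  c0 <- originMm + gridShape * spacingMm / 2
  B2 <- .beamAxes(angleDeg)
  u2 <- B2$u[1:2]; v2 <- B2$t[1:2]
  h <- spacingMm[1]
  L <- 0.5 * sqrt((gridShape[1] * spacingMm[1])^2 +
                  (gridShape[2] * spacingMm[2])^2) + h
  sseq <- seq(-L, L, by = h)
  tseq <- sseq
  ns <- length(sseq); nt <- length(tseq)
  S <- rep(sseq, times = nt); Tt <- rep(tseq, each = ns)
  Px <- c0[1] + S * u2[1] + Tt * v2[1]
  Py <- c0[2] + S * u2[2] + Tt * v2[2]
  A <- bilinearOperator(cbind(Px, Py), ax[[1]], ax[[2]])
  nx <- gridShape[1]; ny <- gridShape[2]
  vx <- rep(ax[[1]], times = ny); vy <- rep(ax[[2]], each = nx)
  sVox <- (vx - c0[1]) * u2[1] + (vy - c0[2]) * u2[2]
  tVox <- (vx - c0[1]) * v2[1] + (vy - c0[2]) * v2[2]
  Bop <- bilinearOperator(cbind(sVox, tVox), sseq, tseq)
  out <- list(A = A, B = Bop, ns = ns, nt = nt, h = h, tVox = tVox, c0 = c0)
  .wedCache[[key]] <- out
  out
}

# water-equivalent depth of every voxel for one gantry angle:
# resample density on a beam-aligned grid, cumulative-sum along depth,
# sample back at voxel centers.
.wedField <- function(density, gridShape, spacingMm, originMm, angleDeg) {
  op <- .wedOperators(gridShape, spacingMm, originMm, angleDeg)
  nxy <- gridShape[1] * gridShape[2]; nz <- gridShape[3]
  D <- matrix(density, nxy, nz)
  Drot <- as.matrix(op$A %*% D)
  dim(Drot) <- c(op$ns, op$nt * nz)
  cs <- apply(Drot, 2, cumsum)
  wedRot <- (cs - 0.5 * Drot) * op$h
  dim(wedRot) <- c(op$ns * op$nt, nz)
  wed <- as.matrix(op$B %*% wedRot)
  pmax(as.vector(wed), 0)
}

#' Compute the dose-influence matrix of a spot set
#'
#' Dose per unit weight from every spot to every voxel on the given
#' phantom: the Bragg depth-dose evaluated at each voxel's
#' water-equivalent depth times a lateral Gaussian of width
#' `sigma0Mm + sigmaKPerMm * depth`, scaled by the RBE factor 1.1. A
#' residual setup shift (rigid patient displacement, mm) is realized by
#' translating the beam geometry laterally in the beam's-eye view;
#' displacement along the beam axis leaves the water-equivalent depth of
#' the anatomy unchanged, as it physically does for parallel proton rays.
#' Entries below `cutoffRel` of their column maximum are dropped to keep
#' the operator sparse. Deterministic for fixed inputs.
#'
#' @param phantom a [Phantom] (planning or deformed daily anatomy).
#' @param spots a [SpotSet].
#' @param setupShiftMm rigid patient shift in mm (default none).
#' @param sigma0Mm lateral Gaussian width at zero depth (mm).
#' @param sigmaKPerMm lateral width growth per mm of depth.
#' @param cutoffRel relative sparsity cutoff per column.
#' @return an [InfluenceMatrix].
#' @export
computeInfluence <- function(phantom, spots, setupShiftMm = c(0, 0, 0),
                             sigma0Mm = 3, sigmaKPerMm = 0.02,
                             cutoffRel = 1e-4) {
  stopifnot(is(phantom, "Phantom"), is(spots, "SpotSet"))
  sdf <- spots@spots
  if (nrow(sdf) == 0L) stop("spot set is empty")
  gs <- phantom@gridShape; sp <- phantom@spacingMm; or <- phantom@originMm
  n <- prod(gs)
  nz <- gs[3]; nxy <- gs[1] * gs[2]
  co <- voxelAxes(gs, sp, or)
  zVox <- rep(co[[3]], each = nxy)
  densPos <- as.vector(phantom@density) > 0
  iso <- spots@isocenterMm
  triplets <- vector("list", nrow(sdf))
  missedSpots <- integer(0)
  for (ang in unique(sdf$angleDeg)) {
    B3 <- .beamAxes(ang)
    op <- .wedOperators(gs, sp, or, ang)
    wed <- .wedField(phantom@density, gs, sp, or, ang)
    # BEV lateral coordinates relative to the isocenter
    tShift <- sum((iso[1:2] - op$c0[1:2]) * B3$t[1:2])
    tAll <- rep(op$tVox, times = nz) - tShift
    zAll <- zVox - iso[3]
    # patient shifted by delta => spots effectively at t - delta.t, z - delta.z
    dT <- sum(setupShiftMm * B3$t)
    dZ <- setupShiftMm[3]
    sig <- sigma0Mm + sigmaKPerMm * wed
    sigFac <- (sigma0Mm / sig)^2
    rows <- which(sdf$angleDeg == ang)
    for (r in rows) {
      R <- sdf$rangeMm[r]
      tj <- sdf$tMm[r] - dT
      zj <- sdf$zMm[r] - dZ
      sigMax <- sigma0Mm + sigmaKPerMm * (R + 8)
      lim <- 3.5 * sigMax
      cand <- which(densPos & wed <= R + 8 &
                    abs(tAll - tj) <= lim &
                    (nz == 1L | abs(zAll - zj) <= lim))
      if (!length(cand)) { missedSpots <- c(missedSpots, sdf$id[r]); next }
      rho2 <- (tAll[cand] - tj)^2 + if (nz == 1L) 0 else (zAll[cand] - zj)^2
      val <- 1.1 * depthDose(R, wed[cand]) *
        exp(-rho2 / (2 * sig[cand]^2)) * sigFac[cand]
      keep <- val >= cutoffRel * max(val)
      if (!any(keep)) { missedSpots <- c(missedSpots, sdf$id[r]); next }
      triplets[[r]] <- list(i = cand[keep], j = rep(r, sum(keep)),
                            x = val[keep])
    }
  }
  if (length(missedSpots))
    warning("spot(s) ", paste(missedSpots, collapse = ", "),
            " deposit no dose on the grid (zero column)")
  ii <- unlist(lapply(triplets, `[[`, "i"))
  jj <- unlist(lapply(triplets, `[[`, "j"))
  xx <- unlist(lapply(triplets, `[[`, "x"))
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(n, nrow(sdf)))
  new("InfluenceMatrix", mat = mat, gridShape = gs,
      setupShiftMm = as.numeric(setupShiftMm))
}

#' Dose from an influence matrix and weight vector
#'
#' Exactly linear: `dose = influence \%*\% weights`.
#'
#' @param influence an [InfluenceMatrix].
#' @param weights non-negative numeric vector, one entry per spot.
#' @return numeric dose array in Gy(RBE) on the influence grid.
#' @export
computeDose <- function(influence, weights) {
  stopifnot(is(influence, "InfluenceMatrix"))
  if (length(weights) != ncol(influence@mat))
    stop("weight vector length does not match spot count")
  if (any(weights < 0)) stop("weights must be non-negative")
  d <- as.vector(influence@mat %*% weights)
  array(d, dim = influence@gridShape)
}

#' @rdname computeDose
#' @param x an [InfluenceMatrix].
#' @return `influenceMat` returns the underlying sparse matrix (voxels x
#'   spots).
#' @export
influenceMat <- function(x) {
  stopifnot(is(x, "InfluenceMatrix"))
  x@mat
}
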