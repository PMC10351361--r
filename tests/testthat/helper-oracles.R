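# Independent reference implementations ("oracles") used to cross-check
# the package code through a different computational route.

# D_p% by explicit subset construction: the minimum dose within the set of
# the k hottest voxels, k = floor(p/100 * V), at least one voxel.
oracleDoseAtVolume <- function(doses, p) {
  k <- max(1L, floor(p / 100 * length(doses)))
  min(sort(doses, decreasing = TRUE)[seq_len(k)])
}

# gEUD by direct power-mean formula written independently.
oracleGeud <- function(doses, n) {
  (sum(doses^(1 / n)) / length(doses))^n
}

# Exhaustive minimum-cardinality subset search: the smallest subset size s
# such that some s-element subset of `weights` sums to at least
# frac * sum(weights) (with the same 1e-12 slack the implementation uses).
# Enumerates every subset of each size; feasible for n <= 15.
oracleMinSubsetSize <- function(weights, frac) {
  n <- length(weights)
  thr <- frac * sum(weights) - 1e-12
  for (s in seq_len(n)) {
    sums <- combn(n, s, FUN = function(ix) sum(weights[ix]))
    if (any(sums >= thr)) return(s)
  }
  n
}

# Water-equivalent depth by brute-force ray marching: step from the point
# back toward the source along the beam axis, accumulating trilinearly
# sampled density until well outside the grid.
oracleWed <- function(phantom, angleDeg, ptMm, stepMm = 0.25) {
  th <- angleDeg * pi / 180
  u <- c(-sin(th), -cos(th), 0)          # beam direction, into the patient
  gs <- gridShape(phantom); sp <- voxelSpacing(phantom)
  L <- sqrt(sum((gs * sp)^2)) + 10
  s <- seq(stepMm / 2, L, by = stepMm)
  pts <- cbind(ptMm[1] - s * u[1], ptMm[2] - s * u[2], rep(ptMm[3], length(s)))
  dens <- adaptNTCP:::trilinearSample(phantom@density, pts, sp, phantom@originMm)
  sum(dens) * stepMm
}

# Plain (single-scenario) spot-weight optimization written directly against
# the public objective evaluator, with an independently derived analytic
# gradient of the documented objective and the same solver settings the
# package uses. Used to cross-check that single-scenario minimax reduces to
# plain optimization.
oraclePlainOptimize <- function(influence, structures, objectives, w0,
                                maxIter = 500) {
  D <- influenceMat(influence)
  maskIdx <- function(role) which(as.vector(structureMask(structures, role)))
  tgtH <- maskIdx("CTV_HIGH"); tgtL <- maskIdx("CTV_LOW")
  tgt <- c(tgtH, tgtL)
  rx <- c(rep(objectives@rxHighGy, length(tgtH)),
          rep(objectives@rxLowGy, length(tgtL)))
  fn <- function(w) {
    d <- computeDose(influence, pmax(w, 0))
    evaluateObjective(d, structures, objectives)
  }
  gr <- function(w) {
    d <- as.vector(D %*% pmax(w, 0))
    g <- numeric(length(d))
    nT <- length(tgt)
    dev <- d[tgt] - rx
    under <- pmax(0, objectives@d98Frac * rx - d[tgt])
    over <- pmax(0, d[tgt] - objectives@d2Frac * rx)
    g[tgt] <- g[tgt] + 2 / nT * (objectives@wUniform * dev -
                                 objectives@wUnder * under +
                                 objectives@wOver * over)
    om <- objectives@oarMean
    for (i in seq_len(nrow(om))) {
      idx <- maskIdx(om$role[i])
      exc <- max(0, mean(d[idx]) - om$limitGy[i])
      if (exc > 0) g[idx] <- g[idx] + 2 * om$weight[i] * exc / length(idx)
    }
    ox <- objectives@oarMax
    for (i in seq_len(nrow(ox))) {
      idx <- maskIdx(ox$role[i])
      exc <- pmax(0, d[idx] - ox$limitGy[i])
      g[idx] <- g[idx] + 2 * ox$weight[i] * exc / length(idx)
    }
    as.vector(Matrix::crossprod(D, g))
  }
  fit <- optim(w0, fn, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = maxIter, factr = 1e7))
  pmax(fit$par, 0)
}
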