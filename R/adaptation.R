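# Daily online adaptation: beamlet-subset selection and partial
# spot-intensity re-optimization on the fraction anatomy.

#' Online-adaptation configuration
#'
#' @param weightFraction minimum fraction of total spot weight the
#'   selected subset must carry (default 0.33).
#' @param countFraction minimum fraction of all spots that must be
#'   selected (default 0.10, applied as a ceiling).
#' @param maxIter,tol solver settings of the restricted re-optimization.
#' @param startFrom `"plan"` restarts each fraction from the original
#'   plan weights (default); `"previous"` chains from the prior
#'   fraction's adapted weights.
#' @return an [AdaptationConfig].
#' @export
adaptationConfig <- function(weightFraction = 0.33, countFraction = 0.10,
                             maxIter = 200, tol = 1e-6,
                             startFrom = c("plan", "previous")) {
  new("AdaptationConfig", weightFraction = weightFraction,
      countFraction = countFraction, maxIter = as.integer(maxIter),
      tol = tol, startFrom = match.arg(startFrom))
}

#' Select the highly weighted beamlet subset
#'
#' The smallest subset of spots carrying at least `weightFraction` of the
#' total weight -- attained by the descending-weight greedy scan, which is
#' provably minimum-cardinality for a sum threshold -- padded with the
#' next-heaviest spots until at least `ceiling(countFraction * n)` spots
#' are selected. Ties are broken toward the lower spot index, so the
#' selection is deterministic.
#'
#' @param weights non-negative spot weights, at least one positive.
#' @param config an [AdaptationConfig].
#' @return a [SpotSelection].
#' @examples
#' selectSpots(c(0.5, 0.3, 0.1, 0.1), adaptationConfig())
#' @export
selectSpots <- function(weights, config = adaptationConfig()) {
  stopifnot(is(config, "AdaptationConfig"))
  if (any(weights < 0)) stop("weights must be non-negative")
  tot <- sum(weights)
  if (tot <= 0) stop("all spot weights are zero: nothing to adapt")
  n <- length(weights)
  ord <- order(-weights, seq_len(n))
  cw <- cumsum(weights[ord])
  k1 <- which(cw >= config@weightFraction * tot - 1e-12)[1]
  k <- max(k1, ceiling(config@countFraction * n))
  idx <- sort(ord[seq_len(k)])
  new("SpotSelection", indices = as.integer(idx),
      achievedWeightFraction = cw[k] / tot,
      achievedCountFraction = k / n)
}

#' Re-optimize the selected spot weights on the daily anatomy
#'
#' Restricted single-scenario optimization with the original planning
#' objectives, evaluated on the daily structures: only the selected
#' weights move (positions and energies are untouched, and non-selected
#' weights are returned bit-identical to `baseWeights`). The base
#' weights are a feasible start of the restricted problem, so the daily
#' objective of the result never exceeds the unadapted objective (within
#' solver tolerance).
#'
#' @param dailyInfluence [InfluenceMatrix] on the fraction anatomy (with
#'   the fraction's setup shift applied).
#' @param baseWeights plan weights to adapt from (>= 0).
#' @param selection a [SpotSelection].
#' @param structuresDaily the fraction's deformed [StructureSet].
#' @param objectives the original [PlanObjectives].
#' @param config an [AdaptationConfig].
#' @return full adapted weight vector.
#' @export
reoptimizeWeights <- function(dailyInfluence, baseWeights, selection,
                              structuresDaily, objectives = planObjectives(),
                              config = adaptationConfig()) {
  stopifnot(is(dailyInfluence, "InfluenceMatrix"), is(selection, "SpotSelection"))
  if (length(baseWeights) != ncol(dailyInfluence@mat))
    stop("baseWeights length does not match the daily influence spot count")
  if (any(selection@indices > length(baseWeights)))
    stop("selection indices exceed the spot count")
  ctx <- .objectiveContext(structuresDaily, objectives)
  S <- dailyInfluence@mat[ctx$vox, , drop = FALSE]
  sel <- selection@indices
  fixedDose <- as.vector(S[, -sel, drop = FALSE] %*% baseWeights[-sel])
  Ssel <- S[, sel, drop = FALSE]
  fn <- function(ws)
    .objectiveOnContext(fixedDose + as.vector(Ssel %*% ws), ctx, objectives)$value
  gr <- function(ws) {
    r <- .objectiveOnContext(fixedDose + as.vector(Ssel %*% ws), ctx,
                             objectives, grad = TRUE)
    as.vector(Matrix::crossprod(Ssel, r$grad))
  }
  fit <- optim(baseWeights[sel], fn, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = config@maxIter, factr = 1e7))
  w <- baseWeights
  if (fit$value <= fn(baseWeights[sel]) + config@tol)
    w[sel] <- pmax(fit$par, 0)
  w
}
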