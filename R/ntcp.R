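# DVH metrics, gEUD and the six head-and-neck NTCP dose-response models.

#' Dose-volume metrics of one structure
#'
#' Computed on the exact voxel-dose empirical distribution (no binning):
#' `Dmean` is the volume-weighted mean (equal voxel volumes), `Dmax` the
#' maximum voxel dose, and `D_p\%` the minimum dose received by the
#' hottest `p`\% of the structure volume -- the `k`-th largest voxel dose
#' with `k = floor(p/100 * V)`, at least one voxel. A binned cumulative
#' DVH curve is attached for export/plotting only.
#'
#' @param dose dose array, Gy(RBE).
#' @param mask logical array of the same shape.
#' @param binWidthGy bin width of the exported cumulative curve.
#' @return list with `Dmean`, `Dmax`, `D2`, `D98` (Gy) and `curve`
#'   (data.frame `doseGy`, `volumeFrac`), or `NULL` (not evaluable) for
#'   an empty mask.
#' @examples
#' d <- array(c(20, 60), c(2, 1, 1)); m <- array(TRUE, c(2, 1, 1))
#' dvhMetrics(d, m)$Dmean  # 40
#' @export
dvhMetrics <- function(dose, mask, binWidthGy = 0.1) {
  if (is.null(mask) || !any(mask)) return(NULL)
  v <- as.vector(dose)[as.vector(mask)]
  bins <- seq(0, max(v) + binWidthGy, by = binWidthGy)
  curve <- data.frame(doseGy = bins,
                      volumeFrac = vapply(bins, function(b) mean(v >= b),
                                          numeric(1)))
  list(Dmean = mean(v), Dmax = max(v),
       D2 = doseAtVolume(v, 2), D98 = doseAtVolume(v, 98),
       curve = curve)
}

#' @rdname dvhMetrics
#' @param doses numeric vector of structure voxel doses.
#' @param p volume percentage.
#' @return `doseAtVolume` returns the `D_p\%` metric in Gy.
#' @export
doseAtVolume <- function(doses, p) {
  if (p < 0 || p > 100) stop("p must lie in [0, 100]")
  k <- max(1L, floor(p / 100 * length(doses)))
  sort(doses, decreasing = TRUE)[k]
}

#' Generalized equivalent uniform dose
#'
#' Power-mean of the structure voxel doses with volume parameter `n`:
#' \eqn{gEUD = ((1/V) \sum_i d_i^{1/n})^n}. `n = 1` reduces exactly to
#' the mean dose; a uniform dose returns itself for any `n`. An all-zero
#' dose returns 0.
#'
#' @param dose dose array, Gy(RBE).
#' @param mask logical array of the same shape (non-empty).
#' @param n volume parameter (non-zero).
#' @return gEUD in Gy.
#' @export
geud <- function(dose, mask, n = 1) {
  if (n == 0) stop("volume parameter n must be non-zero")
  if (is.null(mask) || !any(mask)) stop("empty mask")
  v <- as.vector(dose)[as.vector(mask)]
  if (all(v == 0)) return(0)
  mean(v^(1 / n))^n
}

#' NTCP dose-response functions
#'
#' The three model families of the shipped registry:
#' `ntcpLogisticD50k` is the logistic dose-response
#' \eqn{(1 + (D_{50}/D)^k)^{-1}} (defined as 0 at zero dose by
#' continuity); `ntcpProbitGeud` the probit model
#' \eqn{\Phi((gEUD - D_{50})/(m D_{50}))} with \eqn{\Phi} the standard
#' normal CDF; `ntcpMultivarLogistic` the multivariable logistic
#' \eqn{(1 + e^{a - b X_1 - c X_2})^{-1}}.
#'
#' @param D,geudGy,X1,X2 dose metric inputs in Gy (X2 may be a unitless
#'   indicator).
#' @param D50 dose of 50\% complication probability (Gy, > 0).
#' @param k logistic steepness.
#' @param m probit slope parameter (> 0).
#' @param a,b,c multivariable logistic coefficients.
#' @return probability in [0, 1].
#' @examples
#' ntcpLogisticD50k(51, 51, 1)        # 0.5
#' ntcpProbitGeud(39.9, 39.9, 0.4)    # 0.5
#' ntcpMultivarLogistic(0, 0, 6.09, 0.057, 0.037)
#' @export
ntcpLogisticD50k <- function(D, D50, k) {
  stopifnot(D50 > 0)
  if (any(D < 0)) stop("dose must be non-negative")
  ifelse(D == 0, 0, 1 / (1 + (D50 / D)^k))
}

#' @rdname ntcpLogisticD50k
#' @export
ntcpProbitGeud <- function(geudGy, D50, m) {
  stopifnot(D50 > 0, m > 0)
  pnorm((geudGy - D50) / (m * D50))
}

#' @rdname ntcpLogisticD50k
#' @export
ntcpMultivarLogistic <- function(X1, X2, a, b, c) {
  stopifnot(is.finite(X1), is.finite(X2))
  plogis(b * X1 + c * X2 - a)
}

.ntcpModelFromList <- function(x) {
  new("NTCPModel", endpoint = x$endpoint, family = x$family,
      structures = unlist(x$structures),
      params = unlist(x$params))
}

#' The shipped six-endpoint NTCP registry
#'
#' Head-and-neck models for acute oral mucositis (logistic on the oral
#' mucosa mean dose, D50 = 51 Gy, k = 1), xerostomia (probit on the
#' contralateral parotid gEUD with n = 1, D50 = 39.9 Gy, m = 0.4),
#' swallowing dysfunction for solids and liquids and physician-rated
#' dysphagia (multivariable logistic on the superior pharyngeal
#' constrictor / supraglottic larynx mean doses) and aspiration (probit
#' on the larynx gEUD with n = 1, D50 = 46.5 Gy, m = 0.5). The registry
#' ships as a versioned YAML in `inst/extdata/ntcp_models.yaml`.
#'
#' @param path optional path to a registry YAML (defaults to the shipped
#'   file).
#' @return list of [NTCPModel].
#' @export
defaultNTCPRegistry <- function(path = system.file("extdata",
                                                   "ntcp_models.yaml",
                                                   package = "adaptNTCP")) {
  spec <- yaml::read_yaml(path)
  lapply(spec$models, .ntcpModelFromList)
}

# evaluate one model on a dose distribution; returns list(value, inputs)
.evalModel <- function(model, dose, structures) {
  meanOf <- function(role) {
    m <- structures@masks[[role]]
    mean(as.vector(dose)[as.vector(m)])
  }
  p <- model@params
  switch(model@family,
    logistic_d50k = {
      D <- meanOf(model@structures[["D"]])
      list(value = ntcpLogisticD50k(D, p[["D50"]], p[["k"]]),
           input1 = D, input2 = NA_real_)
    },
    probit_geud = {
      g <- geud(dose, structures@masks[[model@structures[["gEUD"]]]], p[["n"]])
      list(value = ntcpProbitGeud(g, p[["D50"]], p[["m"]]),
           input1 = g, input2 = NA_real_)
    },
    multivar_logistic = {
      X1 <- meanOf(model@structures[["X1"]])
      X2 <- if ("x2const" %in% names(p)) p[["x2const"]]
        else meanOf(model@structures[["X2"]])
      list(value = ntcpMultivarLogistic(X1, X2, p[["a"]], p[["b"]], p[["c"]]),
           input1 = X1, input2 = X2)
    })
}

# roles a model needs evaluated on the dose
.modelRoles <- function(model) {
  r <- model@structures
  r[!is.na(r) & nzchar(r)]
}

#' Evaluate every registry model on an accumulated dose
#'
#' Applies each NTCP model to the cumulative dose distribution on the
#' planning grid. Models whose structure is absent from the structure
#' set, empty, or fully encompassed by a target volume are marked not
#' evaluable (and propagate downstream as missing, never as zero).
#'
#' @param dose cumulative dose array (or [AccumulatedDose]) on the
#'   planning grid.
#' @param structures planning [StructureSet].
#' @param registry list of [NTCPModel] (default: the shipped registry).
#' @param label scenario label attached to the result.
#' @return a [ScenarioNTCP].
#' @export
evaluateNTCP <- function(dose, structures, registry = defaultNTCPRegistry(),
                         label = "") {
  if (is(dose, "AccumulatedDose")) {
    if (!nzchar(label)) label <- dose@label
    dose <- dose@dose
  }
  assertDoseGrid(dose)
  ctv <- array(FALSE, dim = structures@gridShape)
  for (r in c("CTV_HIGH", "CTV_LOW"))
    if (!is.null(structures@masks[[r]])) ctv <- ctv | structures@masks[[r]]
  rows <- lapply(registry, function(model) {
    roles <- .modelRoles(model)
    known <- roles %in% .allRoles
    if (!all(known))
      stop("registry model '", model@endpoint, "' references unknown role(s): ",
           paste(roles[!known], collapse = ", "))
    reason <- ""
    for (r in roles) {
      m <- structures@masks[[r]]
      if (is.null(m) || !any(m)) { reason <- paste0("structure ", r, " absent"); break }
      if (all(ctv[m])) { reason <- paste0(r, " fully within target volume"); break }
    }
    if (nzchar(reason))
      return(data.frame(endpoint = model@endpoint, family = model@family,
                        input1 = NA_real_, input2 = NA_real_,
                        ntcp = NA_real_, evaluable = FALSE, reason = reason))
    ev <- .evalModel(model, dose, structures)
    data.frame(endpoint = model@endpoint, family = model@family,
               input1 = ev$input1, input2 = ev$input2,
               ntcp = ev$value, evaluable = TRUE, reason = "")
  })
  new("ScenarioNTCP", label = label, results = do.call(rbind, rows))
}
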