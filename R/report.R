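# Delta-NTCP attribution, any-of-four totals, the clinical-significance
# rule, the setup-uncertainty linearity experiment and cohort reporting.

# endpoints entering the any-of-four total (distinct anatomical structures)
.anyOfFourEndpoints <- c("xerostomia", "dysphagia", "oral_mucositis",
                         "aspiration")

#' Probability of developing any of a set of toxicities
#'
#' Under the assumption that the endpoint complications occur
#' independently, `P(any) = 1 - prod(1 - p_i)`. Bounded below by
#' `max(p_i)` and above by `sum(p_i)`.
#'
#' @param p vector of endpoint probabilities in [0, 1] (no missing
#'   values; a missing endpoint means the total is not computed).
#' @return probability in [0, 1].
#' @examples
#' totalAnyToxicity(c(0.5, 0.5, 0, 0))  # 0.75
#' @export
totalAnyToxicity <- function(p) {
  if (any(is.na(p))) stop("all endpoint probabilities must be available")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  1 - prod(1 - p)
}

#' Per-patient delta-NTCP report
#'
#' For each endpoint, the NTCP differences attributing the risk change to
#' setup-uncertainty reduction (SUR: scenario B minus A), adaptation to
#' geometric changes (AGC: C minus B) and both combined (C minus A), in
#' percentage points. The additivity identity `dSUR + dAGC = dBOTH`
#' holds algebraically and is asserted on every report. Endpoints
#' evaluable in some scenarios but not all are flagged inconsistent and
#' excluded from the totals; the any-of-four combined probability is
#' computed per scenario (independence complement-product by default,
#' with plain summation of the per-endpoint deltas exported alongside).
#'
#' @param ntcpA,ntcpB,ntcpC [ScenarioNTCP] of scenarios A, B, C for the
#'   same patient and registry.
#' @param patientId identifier attached to the report.
#' @param combination `"independence"` (default) or `"sum"` for the
#'   headline total.
#' @return a [DeltaNTCPReport].
#' @export
deltaNTCP <- function(ntcpA, ntcpB, ntcpC, patientId = "1",
                      combination = c("independence", "sum")) {
  combination <- match.arg(combination)
  ta <- ntcpA@results; tb <- ntcpB@results; tc <- ntcpC@results
  stopifnot(identical(ta$endpoint, tb$endpoint),
            identical(ta$endpoint, tc$endpoint))
  evalAll <- ta$evaluable & tb$evaluable & tc$evaluable
  inconsistent <- (ta$evaluable | tb$evaluable | tc$evaluable) & !evalAll
  if (any(inconsistent))
    warning("endpoint(s) evaluable in only some scenarios, excluded: ",
            paste(ta$endpoint[inconsistent], collapse = ", "))
  pctA <- 100 * ta$ntcp; pctB <- 100 * tb$ntcp; pctC <- 100 * tc$ntcp
  endpoints <- data.frame(
    endpoint = ta$endpoint,
    ntcpA = pctA, ntcpB = pctB, ntcpC = pctC,
    dSUR = pctB - pctA, dAGC = pctC - pctB, dBOTH = pctC - pctA,
    evaluable = evalAll)
  ok <- endpoints$evaluable
  stopifnot(all(abs(endpoints$dSUR[ok] + endpoints$dAGC[ok] -
                    endpoints$dBOTH[ok]) < 1e-9))
  four <- match(.anyOfFourEndpoints, endpoints$endpoint)
  totals <- NULL
  if (!anyNA(four) && all(endpoints$evaluable[four])) {
    pAny <- vapply(list(ta, tb, tc),
                   function(t) totalAnyToxicity(t$ntcp[four]), numeric(1))
    sums <- vapply(list("dSUR", "dAGC", "dBOTH"),
                   function(cl) sum(endpoints[[cl]][four]), numeric(1))
    totals <- rbind(
      data.frame(quantity = "any_of_four",
                 valueA = 100 * pAny[1], valueB = 100 * pAny[2],
                 valueC = 100 * pAny[3],
                 dSUR = 100 * (pAny[2] - pAny[1]),
                 dAGC = 100 * (pAny[3] - pAny[2]),
                 dBOTH = 100 * (pAny[3] - pAny[1])),
      data.frame(quantity = "sum_of_deltas",
                 valueA = NA_real_, valueB = NA_real_, valueC = NA_real_,
                 dSUR = sums[1], dAGC = sums[2], dBOTH = sums[3]))
  } else {
    totals <- data.frame(quantity = character(0), valueA = numeric(0),
                         valueB = numeric(0), valueC = numeric(0),
                         dSUR = numeric(0), dAGC = numeric(0),
                         dBOTH = numeric(0))
  }
  new("DeltaNTCPReport", patientId = as.character(patientId),
      endpoints = endpoints, totals = totals, combination = combination)
}

#' Clinical-significance rule
#'
#' Default thresholds modelled on model-based patient-selection criteria:
#' a mechanism is clinically significant when any single endpoint is
#' reduced by at least 10 pp, or the summed reduction over the four main
#' endpoints reaches 15 pp. Fully configurable.
#'
#' @param singleThresholdPp single-endpoint reduction threshold (pp).
#' @param sumThresholdPp summed-reduction threshold (pp).
#' @param endpoints participating endpoints.
#' @return a [SignificanceRule].
#' @export
significanceRule <- function(singleThresholdPp = 10, sumThresholdPp = 15,
                             endpoints = .anyOfFourEndpoints) {
  new("SignificanceRule", singleThresholdPp = singleThresholdPp,
      sumThresholdPp = sumThresholdPp, endpoints = endpoints)
}

#' Classify the clinical significance of each mechanism
#'
#' Reductions (negative deltas) qualify: a mechanism fires the single
#' branch when any participating endpoint reduction meets the
#' single-endpoint threshold, and the sum branch when the total summed
#' reduction over participating endpoints meets the summed threshold.
#'
#' @param report a [DeltaNTCPReport].
#' @param rule a [SignificanceRule].
#' @return data.frame with one row per mechanism (`SUR`, `AGC`,
#'   `SUR&AGC`): `significant`, `branch` (`"single"`, `"sum"` or
#'   `"none"`), `maxSingleReduction`, `sumReduction` (pp).
#' @export
classifySignificance <- function(report, rule = significanceRule()) {
  e <- report@endpoints
  part <- e$evaluable & e$endpoint %in% rule@endpoints
  out <- lapply(c(SUR = "dSUR", AGC = "dAGC", `SUR&AGC` = "dBOTH"),
                function(cl) {
    red <- -e[[cl]][part]          # positive = reduction
    maxSingle <- if (any(part)) max(red) else 0
    sumRed <- sum(red)
    branch <- if (maxSingle >= rule@singleThresholdPp) "single"
      else if (sumRed >= rule@sumThresholdPp) "sum" else "none"
    data.frame(significant = branch != "none", branch = branch,
               maxSingleReduction = maxSingle, sumReduction = sumRed)
  })
  cbind(mechanism = names(out), do.call(rbind, out), row.names = NULL)
}

#' NTCP versus setup-uncertainty setting (no adaptation)
#'
#' Optimizes one plan per setup-uncertainty setting (e.g. 0, 1, 3 mm),
#' delivers each unadapted over the same fraction series, and tabulates
#' the per-endpoint NTCP of the accumulated doses. For three or more
#' settings the interpolation residual of each middle setting against
#' the straight line through the two endpoint settings is reported,
#' probing whether NTCP varies linearly with the setting.
#'
#' @param phantom,structures planning anatomy.
#' @param fractions fraction series to deliver over.
#' @param settingsMm setup-uncertainty settings in mm.
#' @param spots [SpotSet] (shared across settings).
#' @param objectives [PlanObjectives].
#' @param registry NTCP registry.
#' @return list with `table` (endpoint x setting NTCP in percent),
#'   `residualPp` (named per-endpoint residuals of the middle settings,
#'   pp) and `plans`.
#' @export
linearityExperiment <- function(phantom, structures, fractions,
                                settingsMm = c(0, 1, 3), spots,
                                objectives = planObjectives(),
                                registry = defaultNTCPRegistry()) {
  twoD <- phantom@gridShape[3] == 1L
  nominal <- computeInfluence(phantom, spots)
  plans <- lapply(settingsMm, function(mm)
    makePlan(phantom, structures, spots, robustnessSetting(mm, twoD = twoD),
             objectives, nominalInfluence = nominal))
  ntcps <- lapply(seq_along(settingsMm), function(i) {
    acc <- runScenario(list(label = sprintf("S%gmm", settingsMm[i]),
                            plan = "p", adapt = FALSE),
                       list(p = plans[[i]]), fractions, phantom, objectives,
                       nominalInfluence = nominal)
    evaluateNTCP(acc, structures, registry)
  })
  tab <- data.frame(endpoint = ntcps[[1]]@results$endpoint)
  for (i in seq_along(settingsMm))
    tab[[sprintf("ntcp_%gmm", settingsMm[i])]] <- 100 * ntcps[[i]]@results$ntcp
  residual <- NULL
  if (length(settingsMm) >= 3) {
    s <- settingsMm; k <- length(s)
    lo <- tab[[2]]; hi <- tab[[k + 1]]
    residual <- sapply(2:(k - 1), function(i) {
      lin <- lo + (hi - lo) * (s[i] - s[1]) / (s[k] - s[1])
      tab[[i + 1]] - lin
    })
    residual <- matrix(residual, nrow = nrow(tab),
                       dimnames = list(tab$endpoint, s[2:(k - 1)]))
  }
  list(table = tab, residualPp = residual, plans = plans)
}

#' Cohort summary over per-patient reports
#'
#' Per-endpoint cohort means of the three delta mechanisms over the
#' evaluable patients, mean any-of-four totals, and the count of
#' patients with a clinically significant reduction per mechanism.
#'
#' @param reports list of [DeltaNTCPReport] (>= 1).
#' @param rule a [SignificanceRule].
#' @return list with `endpointMeans`, `totalsMeans`,
#'   `significanceCounts`, `nPatients` and the per-patient `verdicts`.
#' @export
cohortReport <- function(reports, rule = significanceRule()) {
  if (!length(reports)) stop("empty cohort")
  allE <- do.call(rbind, lapply(reports, function(r)
    cbind(patient = r@patientId, r@endpoints)))
  ev <- allE[allE$evaluable, ]
  endpointMeans <- do.call(rbind, lapply(split(ev, ev$endpoint), function(g)
    data.frame(endpoint = g$endpoint[1], n = nrow(g),
               meanDSUR = mean(g$dSUR), meanDAGC = mean(g$dAGC),
               meanDBOTH = mean(g$dBOTH))))
  row.names(endpointMeans) <- NULL
  allT <- do.call(rbind, lapply(reports, function(r) {
    t <- r@totals[r@totals$quantity == "any_of_four", ]
    if (nrow(t)) cbind(patient = r@patientId, t) else NULL
  }))
  totalsMeans <- if (!is.null(allT) && nrow(allT))
    data.frame(n = nrow(allT), meanDSUR = mean(allT$dSUR),
               meanDAGC = mean(allT$dAGC), meanDBOTH = mean(allT$dBOTH))
  else data.frame(n = 0L, meanDSUR = NA_real_, meanDAGC = NA_real_,
                  meanDBOTH = NA_real_)
  verdicts <- lapply(reports, classifySignificance, rule = rule)
  names(verdicts) <- vapply(reports, function(r) r@patientId, character(1))
  counts <- Reduce(`+`, lapply(verdicts, function(v) as.integer(v$significant)))
  significanceCounts <- data.frame(mechanism = verdicts[[1]]$mechanism,
                                   nSignificant = counts)
  list(endpointMeans = endpointMeans, totalsMeans = totalsMeans,
       significanceCounts = significanceCounts,
       nPatients = length(reports), verdicts = verdicts,
       perPatientEndpoints = allE, perPatientTotals = allT)
}

#' Write the cohort CSV exports
#'
#' Writes `ntcp_by_scenario.csv` (per patient/endpoint/scenario NTCP),
#' `delta_ntcp.csv` (per-endpoint deltas with the additivity identity
#' asserted on every row) and `cohort_summary.csv`, plus a JSON verdict
#' file. Every file header records the probability-combination rule.
#'
#' @param cohort output of [cohortReport()].
#' @param reports the list of [DeltaNTCPReport] it was built from.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeCohortCSV <- function(cohort, reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comb <- reports[[1]]@combination
  e <- cohort$perPatientEndpoints
  stopifnot(all(abs(e$dSUR[e$evaluable] + e$dAGC[e$evaluable] -
                    e$dBOTH[e$evaluable]) < 1e-9))
  long <- do.call(rbind, lapply(c("A", "B", "C"), function(sc)
    data.frame(patient = e$patient, scenario = sc, endpoint = e$endpoint,
               ntcpPct = e[[paste0("ntcp", sc)]], evaluable = e$evaluable)))
  f1 <- file.path(dir, "ntcp_by_scenario.csv")
  f2 <- file.path(dir, "delta_ntcp.csv")
  f3 <- file.path(dir, "cohort_summary.csv")
  f4 <- file.path(dir, "verdicts.json")
  hdr <- sprintf("# units: percent / percentage points; totals combination: %s",
                 comb)
  for (f in c(f1, f2, f3)) writeLines(hdr, f)
  suppressWarnings({
    write.table(long, f1, sep = ",", row.names = FALSE, append = TRUE)
    write.table(e, f2, sep = ",", row.names = FALSE, append = TRUE)
    write.table(cohort$endpointMeans, f3, sep = ",", row.names = FALSE,
                append = TRUE)
  })
  jsonlite::write_json(
    list(combination = comb,
         significanceCounts = cohort$significanceCounts,
         verdicts = cohort$verdicts),
    f4, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3, f4))
}

#' Cohort figures
#'
#' `plotDeltaByEndpoint` draws the per-patient delta-NTCP lines per
#' endpoint and mechanism with the cohort mean overlaid;
#' `plotTotalReductions` the per-patient any-of-four total reductions as
#' bars; `plotSignificanceCounts` the number of significant patients per
#' mechanism.
#'
#' @param cohort output of [cohortReport()].
#' @return a ggplot object.
#' @export
plotDeltaByEndpoint <- function(cohort) {
  e <- cohort$perPatientEndpoints
  e <- e[e$evaluable, ]
  long <- do.call(rbind, lapply(c("dSUR", "dAGC", "dBOTH"), function(cl)
    data.frame(patient = e$patient, endpoint = e$endpoint,
               mechanism = sub("^d", "", cl), deltaPp = e[[cl]])))
  means <- stats::aggregate(deltaPp ~ endpoint + mechanism, long, mean)
  ggplot2::ggplot(long, ggplot2::aes(x = mechanism, y = deltaPp,
                                     group = patient)) +
    ggplot2::geom_line(alpha = 0.4, color = "steelblue") +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(group = 1), linewidth = 1.2,
                       color = "black") +
    ggplot2::facet_wrap(~endpoint) +
    ggplot2::labs(y = "Delta NTCP (pp)", x = NULL)
}

#' @rdname plotDeltaByEndpoint
#' @export
plotTotalReductions <- function(cohort) {
  t <- cohort$perPatientTotals
  long <- do.call(rbind, lapply(c("dSUR", "dAGC", "dBOTH"), function(cl)
    data.frame(patient = t$patient, mechanism = sub("^d", "", cl),
               deltaPp = t[[cl]])))
  ggplot2::ggplot(long, ggplot2::aes(x = patient, y = deltaPp,
                                     fill = mechanism)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "Total any-of-four delta NTCP (pp)", x = "patient")
}

#' @rdname plotDeltaByEndpoint
#' @export
plotSignificanceCounts <- function(cohort) {
  ggplot2::ggplot(cohort$significanceCounts,
                  ggplot2::aes(x = mechanism, y = nSignificant)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(y = "patients with clinically significant reduction",
                  x = NULL)
}
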