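# End-to-end orchestration: simulate -> plan -> scenarios -> NTCP -> report.

#' Run the full analysis for one synthetic patient
#'
#' Generates the patient's phantom and fraction series, optimizes the
#' 3 mm-robust and the non-robust plan on the planning anatomy, runs
#' scenarios A (robust, unadapted), B (non-robust, unadapted) and C
#' (non-robust, daily online adaptation), evaluates the NTCP registry on
#' each accumulated dose and assembles the per-patient delta report.
#'
#' @param config a [CohortConfig].
#' @param patientIndex patient number in `1..nPatients`.
#' @param objectives [PlanObjectives].
#' @param adaptConfig [AdaptationConfig].
#' @param registry NTCP registry.
#' @param robustMm setup uncertainty of the robust plan (mm, default 3).
#' @return list with `phantom`, `structures`, `fractions`, `plans`,
#'   `scenarios` (accumulated doses A/B/C), `ntcp` and `report`.
#' @export
runPatientAnalysis <- function(config, patientIndex,
                               objectives = planObjectives(),
                               adaptConfig = adaptationConfig(),
                               registry = defaultNTCPRegistry(),
                               robustMm = 3) {
  anat <- generatePhantom(config, patientIndex)
  fractions <- generateFractionSeries(anat$phantom, anat$structures,
                                      config, patientIndex)
  twoD <- config@gridShape[3] == 1L
  spots <- placeSpots(anat$phantom, anat$structures)
  nominal <- computeInfluence(anat$phantom, spots)
  plans <- list(
    robust = makePlan(anat$phantom, anat$structures, spots,
                      robustnessSetting(robustMm, twoD = twoD), objectives,
                      nominalInfluence = nominal),
    nonrobust = makePlan(anat$phantom, anat$structures, spots,
                         robustnessSetting(0), objectives,
                         nominalInfluence = nominal))
  scenarios <- lapply(c("A", "B", "C"), function(lb)
    runScenario(scenarioSpec(lb), plans, fractions, anat$phantom,
                objectives, adaptConfig, nominalInfluence = nominal))
  names(scenarios) <- c("A", "B", "C")
  ntcp <- lapply(scenarios, evaluateNTCP, structures = anat$structures,
                 registry = registry)
  report <- deltaNTCP(ntcp$A, ntcp$B, ntcp$C, patientId = patientIndex)
  list(phantom = anat$phantom, structures = anat$structures,
       fractions = fractions, plans = plans, scenarios = scenarios,
       ntcp = ntcp, report = report)
}

#' Run the full analysis for a synthetic cohort
#'
#' [runPatientAnalysis()] for every patient plus the cohort summary.
#'
#' @param config a [CohortConfig].
#' @param rule [SignificanceRule] for the verdict counts.
#' @param verbose print one line per patient.
#' @param ... passed to [runPatientAnalysis()].
#' @return list with `patients` (per-patient results), `reports` and
#'   `cohort` (the [cohortReport()] summary).
#' @export
runCohortAnalysis <- function(config, rule = significanceRule(),
                              verbose = FALSE, ...) {
  patients <- lapply(seq_len(config@nPatients), function(i) {
    if (verbose) message("patient ", i, " / ", config@nPatients)
    runPatientAnalysis(config, i, ...)
  })
  reports <- lapply(patients, `[[`, "report")
  list(patients = patients, reports = reports,
       cohort = cohortReport(reports, rule = rule))
}
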