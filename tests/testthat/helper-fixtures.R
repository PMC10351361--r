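# Shared seeded fixtures, memoized so expensive objects are built once per
# test run regardless of which test file touches them first.

.fixtureCache <- new.env(parent = emptyenv())

.fixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

# One seeded single-slice patient taken end to end: anatomy, spots, the
# robust and non-robust plans, the six-fraction series, scenarios A/B/C,
# their NTCP evaluations and the per-patient delta report.
smallPatientFixture <- function() .fixture("small2d", function() {
  cfg <- cohortConfig(nPatients = 1, gridShape = c(64, 64, 1), seed = 7,
                      fractionRange = c(6, 6))
  anat <- generatePhantom(cfg, 1)
  spots <- placeSpots(anat$phantom, anat$structures)
  nominal <- computeInfluence(anat$phantom, spots)
  obj <- planObjectives()
  plans <- list(
    robust = makePlan(anat$phantom, anat$structures, spots,
                      robustnessSetting(3, twoD = TRUE), obj,
                      nominalInfluence = nominal),
    nonrobust = makePlan(anat$phantom, anat$structures, spots,
                         robustnessSetting(0), obj,
                         nominalInfluence = nominal))
  fractions <- generateFractionSeries(anat$phantom, anat$structures, cfg, 1)
  scenarios <- lapply(c(A = "A", B = "B", C = "C"), function(lb)
    runScenario(scenarioSpec(lb), plans, fractions, anat$phantom, obj,
                adaptationConfig(), nominalInfluence = nominal))
  ntcp <- lapply(scenarios, evaluateNTCP, structures = anat$structures)
  report <- deltaNTCP(ntcp$A, ntcp$B, ntcp$C, patientId = "1")
  list(config = cfg, phantom = anat$phantom, structures = anat$structures,
       spots = spots, nominal = nominal, objectives = obj, plans = plans,
       fractions = fractions, scenarios = scenarios, ntcp = ntcp,
       report = report)
})

# The seeded five-patient single-slice demo cohort.
cohortFixture <- function() .fixture("cohort5", function()
  runCohortAnalysis(cohortConfig(nPatients = 5, gridShape = c(64, 64, 1),
                                 seed = 1)))

# A uniform-density phantom (no body outline) for dose-engine symmetry and
# oracle comparisons.
uniformPhantom <- function(nx = 64, ny = 64, density = 1,
                           spacingMm = c(2, 2, 2)) {
  new("Phantom", gridShape = as.integer(c(nx, ny, 1)), spacingMm = spacingMm,
      originMm = c(0, 0, 0),
      density = array(density, c(nx, ny, 1)))
}

maskFromIdx <- function(gs, idx) {
  m <- array(FALSE, dim = gs)
  m[idx] <- TRUE
  m
}

# Planning objectives with no OAR constraints (hand-built tiny problems).
targetOnlyObjectives <- function(...) {
  planObjectives(...,
    oarMean = data.frame(role = character(0), limitGy = numeric(0),
                         weight = numeric(0)),
    oarMax = data.frame(role = character(0), limitGy = numeric(0),
                        weight = numeric(0)))
}

# Wrap a plain matrix as an InfluenceMatrix on an nVox x 1 x 1 grid.
handInfluence <- function(mat, gridShape = c(nrow(mat), 1L, 1L)) {
  new("InfluenceMatrix", mat = methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                           "CsparseMatrix"),
      gridShape = as.integer(gridShape), setupShiftMm = c(0, 0, 0))
}
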