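test_that("fraction dose divides the full delivery by the fraction count", {
  fx <- smallPatientFixture()
  fr <- fx$fractions[[1]]
  w <- spotWeights(fx$plans$nonrobust)
  daily <- computeInfluence(adaptNTCP:::.dailyPhantom(fx$phantom, fr),
                            fx$spots, setupShiftMm = fr@setupShiftMm)
  d1 <- fractionDose(w, fx$spots, fr, fx$phantom, 6, influence = daily)
  expect_equal(d1 * 6, computeDose(daily, w), tolerance = 1e-12)
  expect_error(fractionDose(w, fx$spots, fr, fx$phantom, 0), "nFractions")
})

test_that("identity deformations map doses through unchanged", {
  gs <- c(12, 10, 1)
  ph <- new("Phantom", gridShape = as.integer(gs), spacingMm = c(2, 2, 2),
            originMm = c(0, 0, 0), density = array(1, gs))
  idFx <- new("FractionAnatomy", fractionIndex = 1L,
              setupShiftMm = c(0, 0, 0), dispMm = NULL, invDispMm = NULL,
              dailyDensity = ph@density,
              dailyStructures = new("StructureSet",
                                    masks = list(CTV_HIGH = maskFromIdx(gs, 1)),
                                    gridShape = as.integer(gs)))
  set.seed(8)
  dose <- array(runif(prod(gs)), gs)
  expect_identical(mapToPlanning(dose, idFx, ph), dose)
  expect_error(mapToPlanning(dose[-1], idFx, ph))
})

test_that("a one-voxel translation field shifts the pulled-back dose", {
  gs <- c(12, 10, 1)
  ph <- new("Phantom", gridShape = as.integer(gs), spacingMm = c(2, 2, 2),
            originMm = c(0, 0, 0), density = array(1, gs))
  disp <- array(0, dim = c(gs, 3)); disp[, , , 1] <- 2    # +2 mm in x
  inv <- array(0, dim = c(gs, 3)); inv[, , , 1] <- -2
  fr <- new("FractionAnatomy", fractionIndex = 1L, setupShiftMm = c(0, 0, 0),
            dispMm = disp, invDispMm = inv, dailyDensity = ph@density,
            dailyStructures = new("StructureSet",
                                  masks = list(CTV_HIGH = maskFromIdx(gs, 1)),
                                  gridShape = as.integer(gs)))
  set.seed(9)
  daily <- array(runif(prod(gs)), gs)
  expect_warning(mapped <- mapToPlanning(daily, fr, ph), "outside")
  # planning voxel i samples the daily dose one voxel to the right
  expect_equal(mapped[1:11, , 1, drop = FALSE],
               daily[2:12, , 1, drop = FALSE], tolerance = 1e-12)
  # dose mass is conserved up to the single boundary column
  expect_equal(sum(mapped), sum(daily) - sum(daily[1, , 1]),
               tolerance = 1e-10)
})

test_that("scenario accumulation equals the sum of mapped fraction doses", {
  fx <- smallPatientFixture()
  accB <- fx$scenarios$B
  w <- spotWeights(fx$plans$nonrobust)
  nFx <- length(fx$fractions)
  manual <- array(0, dim = gridShape(fx$phantom))
  for (fr in fx$fractions) {
    daily <- computeInfluence(adaptNTCP:::.dailyPhantom(fx$phantom, fr),
                              fx$spots, setupShiftMm = fr@setupShiftMm)
    manual <- manual +
      mapToPlanning(computeDose(daily, w) / nFx, fr, fx$phantom)
  }
  expect_equal(doseArray(accB), manual, tolerance = 1e-12)
  expect_identical(accB@label, "B")
  expect_equal(nrow(accB@fractionLog), nFx)
})

test_that("zero-motion delivery accumulates exactly the planned dose", {
  cfg <- cohortConfig(nPatients = 1, gridShape = c(48, 48, 1), seed = 12,
                      fractionRange = c(4, 4), setupSigmaMm = 0,
                      parotidShrink = 0, targetShrink = 0, larynxAmpMm = 0)
  anat <- generatePhantom(cfg, 1)
  spots <- placeSpots(anat$phantom, anat$structures)
  nominal <- computeInfluence(anat$phantom, spots)
  obj <- planObjectives()
  plan <- makePlan(anat$phantom, anat$structures, spots, robustnessSetting(0),
                   obj, nominalInfluence = nominal)
  fractions <- generateFractionSeries(anat$phantom, anat$structures, cfg, 1)
  plans <- list(robust = plan, nonrobust = plan)
  accB <- runScenario(scenarioSpec("B"), plans, fractions, anat$phantom, obj,
                      nominalInfluence = nominal)
  planned <- computeDose(nominal, spotWeights(plan))
  expect_equal(doseArray(accB), planned, tolerance = 1e-12)
  # adaptation has nothing to fix: B and C coincide within solver tolerance
  accC <- runScenario(scenarioSpec("C"), plans, fractions, anat$phantom, obj,
                      nominalInfluence = nominal)
  objB <- evaluateObjective(doseArray(accB), anat$structures, obj)
  objC <- evaluateObjective(doseArray(accC), anat$structures, obj)
  expect_lte(objC, objB + 1e-6)
  expect_lt(max(abs(doseArray(accC) - doseArray(accB))) /
            max(doseArray(accB)), 0.005)
})

test_that("scenario specifications and plan lookup behave as documented", {
  expect_identical(scenarioSpec("A")$plan, "robust")
  expect_false(scenarioSpec("A")$adapt)
  expect_identical(scenarioSpec("B")$plan, "nonrobust")
  expect_true(scenarioSpec("C")$adapt)
  expect_identical(scenarioSpec("EXTENDED")$plan, "robust1mm")
  expect_error(scenarioSpec("D"))
  fx <- smallPatientFixture()
  expect_error(runScenario(scenarioSpec("A"), list(nonrobust = NULL),
                           fx$fractions, fx$phantom, fx$objectives),
               "no plan")
})

test_that("adapted delivery never degrades the per-fraction objective", {
  fx <- smallPatientFixture()
  log <- fx$scenarios$C@fractionLog
  expect_true(all(log$objDelivered <= log$objUnadapted + 1e-6))
})
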