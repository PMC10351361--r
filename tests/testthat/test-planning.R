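dummySpots <- function(n) {
  new("SpotSet",
      spots = data.frame(id = seq_len(n), angleDeg = 0, tMm = 0, zMm = 0,
                         rangeMm = 50),
      weights = rep(0, n), isocenterMm = c(0, 0, 0))
}

test_that("robustness scenario sets have the documented structure", {
  r0 <- robustnessSetting(0)
  expect_equal(nrow(r0@scenarioShifts), 1)
  expect_true(all(r0@scenarioShifts == 0))
  r3 <- robustnessSetting(3)
  expect_equal(nrow(r3@scenarioShifts), 7)
  expect_equal(sort(unique(abs(r3@scenarioShifts[-1, ])[
    abs(r3@scenarioShifts[-1, ]) > 0])), 3)
  expect_true(all(rowSums(r3@scenarioShifts[-1, ] != 0) == 1))
  r2d <- robustnessSetting(3, twoD = TRUE)
  expect_equal(nrow(r2d@scenarioShifts), 5)
  expect_true(all(r2d@scenarioShifts[, 3] == 0))
})

test_that("spot placement is deterministic and densifies with spacing", {
  anat <- generatePhantom(cohortConfig(nPatients = 1,
                                       gridShape = c(48, 48, 1), seed = 4), 1)
  s1 <- placeSpots(anat$phantom, anat$structures)
  s2 <- placeSpots(anat$phantom, anat$structures)
  expect_identical(spotTable(s1), spotTable(s2))
  expect_gt(nrow(spotTable(s1)), 0)
  expect_setequal(unique(spotTable(s1)$angleDeg), c(60, 180, 300))
  expect_true(all(spotTable(s1)$rangeMm >= 1))
  dense <- placeSpots(anat$phantom, anat$structures, lateralSpacingMm = 3,
                      layerSpacingMm = 3)
  expect_gt(nrow(spotTable(dense)), nrow(spotTable(s1)))
  expect_error(placeSpots(anat$phantom, anat$structures,
                          lateralSpacingMm = 0), "spacings")
})

test_that("objective reproduces hand-computed values", {
  gs <- c(8, 8, 1)
  structures <- new("StructureSet", gridShape = as.integer(gs), masks = list(
    CTV_HIGH = maskFromIdx(gs, 1:4),
    CTV_LOW = maskFromIdx(gs, 9:10),
    PAROTID_CONTRA = maskFromIdx(gs, 17:18),
    SPINAL_CORD = maskFromIdx(gs, 25)))
  obj <- planObjectives(
    oarMean = data.frame(role = "PAROTID_CONTRA", limitGy = 26, weight = 2),
    oarMax = data.frame(role = "SPINAL_CORD", limitGy = 45, weight = 10))

  dose <- array(999, gs)           # unconstrained voxels must not contribute
  dose[1:4] <- 70; dose[9:10] <- 57
  dose[17:18] <- 30                # parotid mean 30 -> 2 * (30-26)^2 = 32
  dose[25] <- 50                   # cord excess 5   -> 10 * 5^2      = 250
  expect_equal(evaluateObjective(dose, structures, obj), 282,
               tolerance = 1e-12)

  dose[17:18] <- 20; dose[25] <- 40
  expect_identical(evaluateObjective(dose, structures, obj), 0)

  # target underdose: uniform term + one-sided band term below 95% of rx
  dose[1:4] <- 63                  # dev -7, under 66.5 - 63 = 3.5
  expect_equal(evaluateObjective(dose, structures, obj),
               (4 * 49) / 6 + 10 * (4 * 3.5^2) / 6, tolerance = 1e-12)

  # target overdose above 107% of rx
  dose[1:4] <- 77                  # dev 7, over 77 - 74.9 = 2.1
  expect_equal(evaluateObjective(dose, structures, obj),
               (4 * 49) / 6 + 10 * (4 * 2.1^2) / 6, tolerance = 1e-10)

  # missing referenced structure is an error
  s2 <- new("StructureSet", gridShape = as.integer(gs),
            masks = structures@masks[c("CTV_HIGH", "CTV_LOW")])
  expect_error(evaluateObjective(dose, s2, obj), "missing structure")
})

test_that("one-voxel one-spot optimization recovers the closed form p/d", {
  gs <- c(2, 1, 1)
  structures <- new("StructureSet", gridShape = as.integer(gs), masks = list(
    CTV_HIGH = maskFromIdx(gs, 1), CTV_LOW = maskFromIdx(gs, integer(0))))
  infl <- handInfluence(matrix(c(2, 0.3), 2, 1), gs)
  obj <- targetOnlyObjectives()
  plan <- optimizeWeights(list(infl), structures, obj, robustnessSetting(0),
                          dummySpots(1), w0 = 5)
  expect_equal(spotWeights(plan), 35, tolerance = 1e-4)   # 70 Gy / 2 Gy
  expect_lt(plan@objectiveValue, 1e-6)
})

test_that("optimization is deterministic and never worse than its start", {
  fx <- smallPatientFixture()
  p1 <- optimizeWeights(list(fx$nominal), fx$structures, fx$objectives,
                        robustnessSetting(0), fx$spots, maxIter = 60)
  p2 <- optimizeWeights(list(fx$nominal), fx$structures, fx$objectives,
                        robustnessSetting(0), fx$spots, maxIter = 60)
  expect_identical(spotWeights(p1), spotWeights(p2))

  n <- length(spotWeights(p1))
  w0 <- rep(0.4, n)
  p3 <- optimizeWeights(list(fx$nominal), fx$structures, fx$objectives,
                        robustnessSetting(0), fx$spots, w0 = w0, maxIter = 25)
  start <- evaluateObjective(computeDose(fx$nominal, w0), fx$structures,
                             fx$objectives)
  expect_lte(p3@objectiveValue, start)
  expect_true(all(spotWeights(p3) >= 0))
})

test_that("the robust plan wins the worst case over the 3 mm scenario set", {
  fx <- smallPatientFixture()
  shifts <- robustnessSetting(3, twoD = TRUE)@scenarioShifts
  infl <- lapply(seq_len(nrow(shifts)), function(i)
    if (i == 1) fx$nominal else
      computeInfluence(fx$phantom, fx$spots, setupShiftMm = shifts[i, ]))
  worstOf <- function(w) max(vapply(infl, function(D)
    evaluateObjective(computeDose(D, w), fx$structures, fx$objectives),
    numeric(1)))
  wRob <- worstOf(spotWeights(fx$plans$robust))
  wNon <- worstOf(spotWeights(fx$plans$nonrobust))
  expect_lte(wRob, wNon + 1e-9)
  # the stored objective value is the true worst case of the stored weights
  expect_equal(fx$plans$robust@objectiveValue, wRob, tolerance = 1e-8)
  # mismatched scenario/influence counts are rejected
  expect_error(optimizeWeights(infl[1:2], fx$structures, fx$objectives,
                               robustnessSetting(0), fx$spots))
})
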