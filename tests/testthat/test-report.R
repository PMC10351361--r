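mkScenario <- function(p, label = "S", evaluable = rep(TRUE, length(p))) {
  new("ScenarioNTCP", label = label, results = data.frame(
    endpoint = names(p), family = "test", input1 = NA_real_,
    input2 = NA_real_, ntcp = unname(p), evaluable = evaluable,
    reason = ifelse(evaluable, "", "structure absent")))
}

fourEp <- c("xerostomia", "dysphagia", "oral_mucositis", "aspiration")

test_that("any-of-four total follows the independence complement product", {
  expect_equal(totalAnyToxicity(c(0.5, 0.5, 0, 0)), 0.75, tolerance = 1e-12)
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(totalAnyToxicity(p), 1 - prod(1 - p), tolerance = 1e-12)
  expect_gte(totalAnyToxicity(p), max(p))
  expect_lte(totalAnyToxicity(p), sum(p))
  expect_error(totalAnyToxicity(c(0.1, NA)), "available")
  expect_error(totalAnyToxicity(c(0.1, 1.2)), "probabilities")
})

test_that("delta report reproduces the attribution arithmetic", {
  a <- setNames(c(0.35, 0.30, 0.20, 0.10), fourEp)
  b <- setNames(c(0.30, 0.28, 0.18, 0.10), fourEp)
  c3 <- setNames(c(0.20, 0.20, 0.15, 0.08), fourEp)
  rep1 <- deltaNTCP(mkScenario(a), mkScenario(b), mkScenario(c3),
                    patientId = "p1")
  e <- deltaTable(rep1)
  xe <- e[e$endpoint == "xerostomia", ]
  expect_equal(xe$dSUR, -5, tolerance = 1e-12)    # B - A in pp
  expect_equal(xe$dAGC, -10, tolerance = 1e-12)   # C - B
  expect_equal(xe$dBOTH, -15, tolerance = 1e-12)  # C - A
  expect_equal(e$dSUR + e$dAGC, e$dBOTH, tolerance = 1e-12)

  t <- totalsTable(rep1)
  any4 <- t[t$quantity == "any_of_four", ]
  expect_equal(any4$valueA, 100 * (1 - prod(1 - a)), tolerance = 1e-12)
  expect_equal(any4$dBOTH,
               100 * ((1 - prod(1 - c3)) - (1 - prod(1 - a))),
               tolerance = 1e-12)
  sums <- t[t$quantity == "sum_of_deltas", ]
  expect_equal(sums$dBOTH, sum(e$dBOTH), tolerance = 1e-12)
  expect_identical(rep1@patientId, "p1")
})

test_that("inconsistent evaluability is excluded with a warning", {
  a <- setNames(c(0.35, 0.30, 0.20, 0.10), fourEp)
  snA <- mkScenario(a)
  snB <- mkScenario(a, evaluable = c(FALSE, TRUE, TRUE, TRUE))
  expect_warning(r <- deltaNTCP(snA, snB, snA), "excluded")
  e <- deltaTable(r)
  expect_false(e$evaluable[e$endpoint == "xerostomia"])
  # totals need all four endpoints, so they are empty here
  expect_equal(nrow(totalsTable(r)), 0)
})

test_that("significance classification fires the documented branches", {
  mk <- function(dB, dC) {
    a <- setNames(rep(0.30, 4), fourEp)
    deltaNTCP(mkScenario(a), mkScenario(a + dB), mkScenario(a + dC))
  }
  # one endpoint reduced by 12 pp under SUR -> single branch
  d <- rep(0, 4); d[1] <- -0.12
  v <- classifySignificance(mk(d, d))
  expect_true(v$significant[v$mechanism == "SUR"])
  expect_identical(v$branch[v$mechanism == "SUR"], "single")
  # four endpoints reduced 4 pp each: sum 16 pp -> sum branch
  v2 <- classifySignificance(mk(rep(-0.04, 4), rep(-0.04, 4)))
  expect_identical(v2$branch[v2$mechanism == "SUR"], "sum")
  # small reductions -> not significant
  v3 <- classifySignificance(mk(rep(-0.01, 4), rep(-0.02, 4)))
  expect_false(any(v3$significant))
  # thresholds are configurable (AGC stays at zero reduction here)
  v4 <- classifySignificance(mk(rep(-0.01, 4), rep(-0.01, 4)),
                             significanceRule(singleThresholdPp = 1))
  expect_true(all(v4$significant[v4$mechanism %in% c("SUR", "SUR&AGC")]))
  expect_false(v4$significant[v4$mechanism == "AGC"])
})

test_that("cohort report averages evaluable patients and counts verdicts", {
  a <- setNames(rep(0.30, 4), fourEp)
  r1 <- deltaNTCP(mkScenario(a), mkScenario(a - 0.02), mkScenario(a - 0.02),
                  patientId = "1")
  r2 <- deltaNTCP(mkScenario(a), mkScenario(a - 0.04), mkScenario(a - 0.04),
                  patientId = "2")
  co <- cohortReport(list(r1, r2))
  em <- co$endpointMeans
  expect_equal(em$meanDSUR, rep(-3, 4), tolerance = 1e-12)
  expect_equal(em$meanDAGC, rep(0, 4), tolerance = 1e-12)
  expect_identical(em$n, rep(2L, 4))
  # each patient's summed SUR reduction is 8 or 16 pp; only patient 2
  # crosses the 15 pp sum threshold
  counts <- co$significanceCounts
  expect_identical(counts$nSignificant[counts$mechanism == "SUR"], 1L)
  expect_identical(co$nPatients, 2L)
  expect_error(cohortReport(list()), "empty")
})

test_that("cohort CSV exports round-trip and keep the additivity identity", {
  fx <- smallPatientFixture()
  co <- cohortReport(list(fx$report))
  dir <- file.path(tempdir(), "adaptntcp-csv-test")
  paths <- writeCohortCSV(co, list(fx$report), dir)
  expect_true(all(file.exists(paths)))
  hdr <- readLines(paths[2], n = 1)
  expect_match(hdr, "independence")
  e <- read.csv(paths[2], skip = 1)
  ok <- e$evaluable
  expect_true(all(abs(e$dSUR[ok] + e$dAGC[ok] - e$dBOTH[ok]) < 1e-9))
  v <- jsonlite::read_json(paths[4])
  expect_identical(v$combination, "independence")
  unlink(dir, recursive = TRUE)
})

test_that("cohort figures build as ggplot objects", {
  fx <- smallPatientFixture()
  co <- cohortReport(list(fx$report))
  for (p in list(plotDeltaByEndpoint(co), plotTotalReductions(co),
                 plotSignificanceCounts(co))) {
    expect_s3_class(p, "ggplot")
    built <- ggplot2::ggplot_build(p)
    expect_gt(nrow(built$data[[1]]), 0)
  }
})
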