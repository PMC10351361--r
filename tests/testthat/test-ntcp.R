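test_that("logistic dose-response reproduces closed-form values", {
  expect_equal(ntcpLogisticD50k(51, 51, 1), 0.5, tolerance = 1e-12)
  # D = 2 * D50: 1 / (1 + 51/102) = 2/3
  expect_equal(ntcpLogisticD50k(102, 51, 1), 2 / 3, tolerance = 1e-12)
  expect_identical(ntcpLogisticD50k(0, 51, 1), 0)
  # steepness: k = 2 at half D50 gives 1/5
  expect_equal(ntcpLogisticD50k(25.5, 51, 2), 0.2, tolerance = 1e-12)
  expect_error(ntcpLogisticD50k(-1, 51, 1), "non-negative")
})

test_that("probit gEUD model reproduces closed-form values", {
  expect_equal(ntcpProbitGeud(39.9, 39.9, 0.4), 0.5, tolerance = 1e-12)
  expect_equal(ntcpProbitGeud(39.9 * 1.4, 39.9, 0.4), pnorm(1),
               tolerance = 1e-12)
  expect_equal(ntcpProbitGeud(39.9 * 0.2, 39.9, 0.4), pnorm(-2),
               tolerance = 1e-12)
  expect_equal(ntcpProbitGeud(46.5, 46.5, 0.5), 0.5, tolerance = 1e-12)
  expect_equal(ntcpProbitGeud(0, 39.9, 0.4), pnorm(-2.5), tolerance = 1e-12)
})

test_that("multivariable logistic model reproduces closed-form values", {
  expect_equal(ntcpMultivarLogistic(0, 0, 6.09, 0.057, 0.037),
               1 / (1 + exp(6.09)), tolerance = 1e-12)
  expect_equal(ntcpMultivarLogistic(0, 0, 6.89, 0.049, 0.048),
               1 / (1 + exp(6.89)), tolerance = 1e-12)
  # solids model at its X1 midpoint (constant X2 = 1):
  # 0.074 * X1 - 1.209 - 5.98 = 0  =>  X1 = 7.189 / 0.074
  expect_equal(ntcpMultivarLogistic(7.189 / 0.074, 1, 5.98, 0.074, -1.209),
               0.5, tolerance = 1e-12)
  expect_error(ntcpMultivarLogistic(NA, 1, 6, 0.1, 0.1))
})

test_that("NTCP is monotone in its dose input", {
  d <- seq(1, 120, by = 0.5)
  expect_true(all(diff(ntcpLogisticD50k(d, 51, 1)) > 0))
  expect_true(all(diff(ntcpProbitGeud(d, 39.9, 0.4)) > 0))
  expect_true(all(diff(ntcpMultivarLogistic(d, 30, 6.09, 0.057, 0.037)) > 0))
})

test_that("gEUD with n = 1 equals the mean dose and handles edge cases", {
  gs <- c(5, 5, 1)
  set.seed(42)
  for (i in 1:25) {
    dose <- array(runif(prod(gs), 0, 80), gs)
    mask <- array(runif(prod(gs)) > 0.4, gs)
    if (!any(mask)) next
    v <- dose[mask]
    expect_equal(geud(dose, mask, n = 1), mean(v), tolerance = 1e-12)
    expect_equal(geud(dose, mask, n = 0.5), oracleGeud(v, 0.5),
                 tolerance = 1e-12)
  }
  uni <- array(43.7, gs); all <- array(TRUE, gs)
  expect_equal(geud(uni, all, n = 0.25), 43.7, tolerance = 1e-12)
  expect_identical(geud(array(0, gs), all, n = 1), 0)
  expect_error(geud(uni, all, n = 0), "non-zero")
  expect_error(geud(uni, array(FALSE, gs), n = 1), "empty")
})

test_that("DVH percentile metrics match the sort-based oracle exactly", {
  # the canonical example: doses 1..100, D98 = 3, D2 = 99
  v <- as.numeric(1:100)
  expect_identical(doseAtVolume(v, 98), 3)
  expect_identical(doseAtVolume(v, 2), 99)
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:60, 1)
    v <- if (i %% 3 == 0) sample(round(runif(5, 0, 70), 1), n, replace = TRUE)
         else runif(n, 0, 75)             # every third draw has heavy ties
    for (p in c(2, 50, 98, runif(1, 0, 100)))
      expect_identical(doseAtVolume(v, p), oracleDoseAtVolume(v, p))
  }
})

test_that("dvhMetrics summarizes a structure and flags empty masks", {
  gs <- c(10, 10, 1)
  dose <- array(as.numeric(1:100), gs)
  m <- dvhMetrics(dose, array(TRUE, gs))
  expect_equal(m$Dmean, 50.5)
  expect_equal(m$Dmax, 100)
  expect_identical(m$D98, 3)
  expect_identical(m$D2, 99)
  expect_true(all(diff(m$curve$volumeFrac) <= 0))
  expect_null(dvhMetrics(dose, array(FALSE, gs)))
})

test_that("the shipped registry holds the six endpoint models", {
  reg <- defaultNTCPRegistry()
  eps <- vapply(reg, function(m) m@endpoint, character(1))
  expect_setequal(eps, c("oral_mucositis", "xerostomia", "dysphagia_solids",
                         "dysphagia_liquids", "dysphagia", "aspiration"))
  byName <- setNames(reg, eps)
  expect_equal(byName$oral_mucositis@params[["D50"]], 51)
  expect_equal(byName$oral_mucositis@params[["k"]], 1)
  expect_equal(byName$xerostomia@params[["D50"]], 39.9)
  expect_equal(byName$xerostomia@params[["m"]], 0.4)
  expect_equal(byName$xerostomia@params[["n"]], 1)
  expect_equal(unname(byName$dysphagia@params[c("a", "b", "c")]),
               c(6.09, 0.057, 0.037))
  expect_equal(unname(byName$dysphagia_solids@params[c("a", "b", "c")]),
               c(5.98, 0.074, -1.209))
  expect_equal(unname(byName$dysphagia_liquids@params[c("a", "b", "c")]),
               c(6.89, 0.049, 0.048))
  expect_equal(byName$aspiration@params[["D50"]], 46.5)
  expect_equal(byName$aspiration@params[["m"]], 0.5)
})

test_that("evaluateNTCP computes from dose metrics and labels scenarios", {
  gs <- c(48, 48, 1)
  cfg <- cohortConfig(nPatients = 1, gridShape = gs, seed = 2)
  anat <- generatePhantom(cfg, 1)
  dose <- array(30, gs)
  sn <- evaluateNTCP(dose, anat$structures, label = "uniform30")
  tab <- ntcpTable(sn)
  expect_identical(sn@label, "uniform30")
  expect_true(all(tab$evaluable))
  # uniform dose: every mean/gEUD input is exactly 30
  expect_equal(tab$input1, rep(30, 6), tolerance = 1e-12)
  om <- tab[tab$endpoint == "oral_mucositis", ]
  expect_equal(om$ntcp, ntcpLogisticD50k(30, 51, 1), tolerance = 1e-12)
  xe <- tab[tab$endpoint == "xerostomia", ]
  expect_equal(xe$ntcp, ntcpProbitGeud(30, 39.9, 0.4), tolerance = 1e-12)
})

test_that("missing or target-swallowed structures are not evaluable", {
  gs <- c(48, 48, 1)
  cfg <- cohortConfig(nPatients = 1, gridShape = gs, seed = 2)
  anat <- generatePhantom(cfg, 1)
  dose <- array(10, gs)

  masks <- anat$structures@masks
  masks$PAROTID_CONTRA <- NULL
  s2 <- new("StructureSet", masks = masks, gridShape = anat$structures@gridShape)
  tab <- ntcpTable(evaluateNTCP(dose, s2))
  xe <- tab[tab$endpoint == "xerostomia", ]
  expect_false(xe$evaluable)
  expect_true(is.na(xe$ntcp))
  expect_match(xe$reason, "absent")

  masks2 <- anat$structures@masks
  ctv <- masks2$CTV_HIGH
  inside <- which(as.vector(ctv))[1:4]
  masks2$LARYNX <- maskFromIdx(gs, inside)   # entirely inside the boost CTV
  s3 <- new("StructureSet", masks = masks2, gridShape = as.integer(gs))
  tab3 <- ntcpTable(evaluateNTCP(dose, s3))
  asp <- tab3[tab3$endpoint == "aspiration", ]
  expect_false(asp$evaluable)
  expect_match(asp$reason, "within target")

  bogus <- new("NTCPModel", endpoint = "x", family = "logistic_d50k",
               structures = c(D = "NOT_A_ROLE"), params = c(D50 = 50, k = 1))
  expect_error(evaluateNTCP(dose, anat$structures, registry = list(bogus)),
               "unknown role")
})
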