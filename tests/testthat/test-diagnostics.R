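test_that("confusion counts keep the published bookkeeping style", {
  allOk <- confusionCounts(rep(c(0, 1), c(52, 30)), rep(c(0, 1), c(52, 30)))
  expect_equal(correctTotalStrings(allOk),
               c(controls = "52/52", cases = "30/30"))

  # validation row: 50 of 52 controls and 30 of 30 cases correct
  truth <- rep(c(0, 1), c(52, 30))
  pred <- truth
  pred[1:2] <- 1
  cc <- confusionCounts(truth, pred)
  expect_equal(c(cc@tn, cc@fp, cc@tp, cc@fn), c(50L, 2L, 30L, 0L))

  flipped <- confusionCounts(truth, 1 - pred)
  expect_equal(c(flipped@tp, flipped@fn), c(cc@fn, cc@tp))
  expect_equal(c(flipped@tn, flipped@fp), c(cc@fp, cc@tn))
  expect_error(confusionCounts(c(0, 2), c(0, 1)), "binary")
})

test_that("the accuracy panel follows the predictive-value formulas", {
  rep1 <- accuracyPanelFromRates(1, 50 / 52, 30 / 82)
  expect_equal(rep1@ppv, (30 / 82) / (30 / 82 + (2 / 52) * (52 / 82)))
  expect_equal(rep1@npv, 1)
  expect_equal(rep1@plr, 26)
  expect_equal(rep1@nlr, 0)

  # perfect test: PPV = NPV = 1, -LR = 0, +LR undefined, any prevalence
  perfect <- accuracyPanelFromRates(1, 1, 0.2)
  expect_equal(c(perfect@ppv, perfect@npv, perfect@nlr), c(1, 1, 0))
  expect_true(is.na(perfect@plr))
  expect_identical(unname(formatDiagnosticReport(perfect)["plr"]), "N/A")

  # monotonicity in prevalence: PPV increases, NPV decreases
  grid <- seq(0.05, 0.95, by = 0.05)
  panels <- lapply(grid, function(p) accuracyPanelFromRates(0.9, 0.85, p))
  ppvs <- vapply(panels, function(r) r@ppv, numeric(1))
  npvs <- vapply(panels, function(r) r@npv, numeric(1))
  expect_true(all(diff(ppvs) > 0))
  expect_true(all(diff(npvs) < 0))

  # posterior-odds identity: PPV/(1-PPV) = +LR x prev/(1-prev)
  for (r in panels)
    expect_equal(r@ppv / (1 - r@ppv), r@plr * r@prevalence /
                   (1 - r@prevalence))

  expect_error(accuracyPanelFromRates(0.9, 0.9, 0), "prevalence")
  cc <- confusionCounts(c(0, 0, 1, 1), c(0, 1, 1, 1))
  fromCounts <- accuracyPanel(cc)
  expect_equal(fromCounts@sensitivity, 1)
  expect_equal(fromCounts@specificity, 0.5)
  expect_equal(fromCounts@prevalence, 0.5)
  external <- accuracyPanel(cc, prevalence = 0.1)
  expect_equal(external@prevalence, 0.1)
})

test_that("marker-count arithmetic reports exact and truncated rates", {
  p <- markerPanelFromCounts(2, 32, 1, 156)
  expect_equal(p$sensitivity, 2 / 32)
  expect_equal(p$specificity, 155 / 156)
  expect_equal(p$sensitivityPct, 6.2)
  expect_equal(p$specificityPct, 99.3)
  expect_equal(markerPanelFromCounts(0, 10, 0, 10)$sensitivityPct, 0)
  expect_equal(markerPanelFromCounts(0, 10, 0, 10)$specificityPct, 100)
  expect_equal(markerPanelFromCounts(10, 10, 10, 10)$sensitivityPct, 100)
  expect_equal(markerPanelFromCounts(10, 10, 10, 10)$specificityPct, 0)
  expect_error(markerPanelFromCounts(1, 0, 0, 5), "positive")
})

test_that("half-up rounding follows the printed-table convention", {
  expect_equal(roundHalfUp(93.75, 1), 93.8)
  expect_equal(roundHalfUp(18.75, 1), 18.8)
  expect_equal(roundHalfUp(0.045, 2), 0.05)
  expect_equal(roundHalfUp(-0.045, 2), -0.05)
  expect_equal(roundHalfUp(2.5), 3)
})

test_that("ROC/AUC equals the pair-count oracle, including ties", {
  perfect <- rocCurve(c(1, 2, 3, 11, 12, 13), rep(c(0, 1), each = 3))
  expect_equal(perfect@auc, 1)

  set.seed(301)
  for (i in 1:15) {
    n <- sample(5:12, 1)
    scores <- sample(1:4, n, replace = TRUE)  # forces ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    rc <- rocCurve(scores, labels)
    expect_equal(rc@auc, pairCountAuc(scores, labels), info = i)
    neg <- rocCurve(-scores, labels)
    expect_equal(neg@auc, 1 - rc@auc, info = i)
    expect_true(validObject(rc))
  }
  expect_error(rocCurve(1:4, rep(1, 4)), "both classes")
})

test_that("multi-ROC ranking orients AUCs and ranks real effects first", {
  set.seed(302)
  n <- 60
  labels <- rep(c(0, 1), each = n / 2)
  strong <- rnorm(n) + 2 * labels
  weakDown <- rnorm(n) - 0.8 * labels
  nulls <- matrix(rnorm(n * 3), n)
  lv <- cbind(strong = strong, weakDown = weakDown, nulls)
  colnames(lv)[3:5] <- paste0("null", 1:3)
  rk <- multiRocRanking(lv, labels)
  expect_identical(rk$metabolite[1], "strong")
  expect_identical(rk$direction[rk$metabolite == "strong"], "increased")
  expect_identical(rk$direction[rk$metabolite == "weakDown"], "decreased")
  expect_true(all(rk$auc >= 0.5))
  expect_equal(rk$auc[rk$metabolite == "weakDown"],
               1 - rk$rawAuc[rk$metabolite == "weakDown"])

  # all-null levels cluster near 0.5
  aucs <- unlist(lapply(1:5, function(s) {
    set.seed(400 + s)
    multiRocRanking(matrix(rnorm(n * 4), n), labels)$auc
  }))
  expect_lt(mean(aucs), 0.62)
})

test_that("metabolite levels integrate signature windows linearly", {
  cfg <- tinyConfig(noiseSd = 0, waterAmplitude = 0, dilutionLogSd = 0)
  lib <- signatureLibrary()
  one <- simulateSpectrum(c(taurine = 1), cfg)
  two <- simulateSpectrum(c(taurine = 2), cfg)
  none <- simulateSpectrum(c(taurine = 0), cfg)
  # linearity is exact on raw intensities (normalization couples samples
  # through metabolite tails inside the reference window)
  lv <- metaboliteLevels(SpectrumSet(specPpm(one),
    cbind(one = intensities(one)[, 1], two = intensities(two)[, 1],
          none = intensities(none)[, 1])), lib, normalize = FALSE)
  base <- lv["none", "taurine"]  # baseline window integral
  expect_equal(lv["two", "taurine"] - base,
               2 * (lv["one", "taurine"] - base))
  # zero concentration: level collapses to the baseline integral
  expect_lt(base / lv["one", "taurine"], 0.2)

  # taurine level draws on windows at both 3.27 and 3.45 ppm
  ppm <- specPpm(one)
  ints <- intensities(normalizeToReference(one))[, 1]
  manual <- sum(ints[abs(ppm - 3.27) <= 0.02]) +
    sum(ints[abs(ppm - 3.45) <= 0.02])
  expect_equal(unname(metaboliteLevels(one, lib)[1, "taurine"]), manual)

  shortAxis <- SpectrumSet(seq(0, 3, length.out = 512),
                           matrix(1, 512, 1))
  expect_error(metaboliteLevels(shortAxis, lib, normalize = FALSE),
               "outside the axis")
})
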