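test_that("signature library carries the eleven urinary markers", {
  lib <- signatureLibrary()
  expect_length(lib, 11L)

  # shifts, multiplicities and directions of the published marker table
  expected <- list(
    "3-aminoisobutyrate" = list(ppm = 1.18, mult = "d", dir = "up"),
    alanine    = list(ppm = 1.48, mult = "d", dir = "up"),
    ascorbate  = list(ppm = c(3.75, 4.53), mult = c("m", "m"), dir = "down"),
    citrate    = list(ppm = c(2.54, 2.71), mult = c("d", "d"), dir = "down"),
    creatinine = list(ppm = c(3.05, 4.07), mult = c("s", "s"), dir = "down"),
    glycerol   = list(ppm = c(3.58, 3.66, 3.78), mult = c("m", "m", "m"),
                      dir = "down"),
    hippurate  = list(ppm = c(3.98, 7.56, 7.64, 7.83),
                      mult = c("d", "t", "t", "m"), dir = "down"),
    taurine    = list(ppm = c(3.27, 3.45), mult = c("t", "t"), dir = "up"),
    threonine  = list(ppm = c(1.31, 3.58), mult = c("d", "d"), dir = "down"),
    urea       = list(ppm = 5.80, mult = "s", dir = "up"),
    valine     = list(ppm = 0.99, mult = "d", dir = "up"))
  expect_setequal(names(lib), names(expected))
  for (nm in names(expected)) {
    expect_equal(lib[[nm]]@peaks$ppm, expected[[nm]]$ppm, info = nm)
    expect_equal(lib[[nm]]@peaks$multiplicity, expected[[nm]]$mult,
                 info = nm)
    expect_identical(lib[[nm]]@direction, expected[[nm]]$dir, info = nm)
    expect_true(all(lib[[nm]]@peaks$relIntensity > 0), info = nm)
  }
  cfg <- simConfig()
  expect_true(all(unlist(lapply(lib, function(s) s@peaks$ppm)) >=
                    cfg@ppmMin))
  expect_true(all(unlist(lapply(lib, function(s) s@peaks$ppm)) <=
                    cfg@ppmMax))
})

test_that("multiplet rendering follows first-order splitting arithmetic", {
  cfg <- simConfig(fieldMHz = 500, jHz = 7)
  s <- renderMultiplet(0, "s", 1, cfg)
  expect_equal(s$ppm, 0)
  expect_equal(s$weight, 1)

  # doublet splitting: J/(2 x field) = 7/500/2 = 0.007 ppm
  d <- renderMultiplet(1.18, "d", 1, cfg)
  expect_equal(d$ppm, c(1.18 - 0.007, 1.18 + 0.007))
  expect_equal(d$weight, c(0.5, 0.5))

  for (mult in c("s", "d", "t", "m")) {
    lines <- renderMultiplet(2, mult, 1, cfg)
    expect_equal(sum(lines$weight), 1, info = mult)
  }
  tr <- renderMultiplet(3.27, "t", 2, cfg)
  expect_equal(diff(tr$ppm), rep(7 / 500, 2))
  expect_equal(sum(tr$weight), 2)
  expect_error(renderMultiplet(1, "q", 1, cfg), "unknown multiplicity")
})

test_that("single-spectrum simulation is linear, seeded and TSP-anchored", {
  cfg <- tinyConfig(noiseSd = 0, waterAmplitude = 0)
  empty <- simulateSpectrum(c(taurine = 0), cfg)
  tspOnly <- simulateSpectrum(setNames(numeric(0), character(0)), cfg)
  expect_equal(intensities(empty), intensities(tspOnly))
  # TSP singlet alone: unit peak height at 0.00 ppm
  expect_equal(max(intensities(empty)),
               unname(intensities(empty)[which.min(abs(specPpm(empty))), 1]))

  one <- simulateSpectrum(c(taurine = 1), cfg)
  two <- simulateSpectrum(c(taurine = 2), cfg)
  ppm <- specPpm(one)
  reg <- ppm > 3.2 & ppm < 3.5
  tsp <- abs(ppm) <= 0.05
  base <- intensities(empty)
  expect_equal(sum(intensities(two)[reg, 1] - base[reg]),
               2 * sum(intensities(one)[reg, 1] - base[reg]))
  # TSP region unchanged up to the (tiny) Lorentzian tail of the taurine
  # lines reaching 0 ppm
  expect_equal(intensities(two)[tsp, 1], intensities(one)[tsp, 1],
               tolerance = 1e-4)

  expect_error(simulateSpectrum(c(taurine = -1), cfg), "negative")
  expect_error(simulateSpectrum(c(nonexistent = 1), cfg), "unknown")

  cfgSeeded <- tinyConfig(seed = 42)
  a <- simulateSpectrum(c(alanine = 1), cfgSeeded)
  b <- simulateSpectrum(c(alanine = 1), cfgSeeded)
  expect_identical(intensities(a), intensities(b))
})

test_that("cohorts honor design, directions and the dilution contract", {
  cfg <- tinyConfig(seed = 7, noiseSd = 1e-4)
  design <- cohortDesign(50, 50, foldChange = 2, withinGroupCv = 0.1)
  ss <- simulateCohort(design, cfg)
  lab <- classLabels(ss)
  expect_equal(sum(lab == 1), 50L)
  expect_equal(sum(lab == 0), 50L)
  expect_identical(intensities(ss),
                   intensities(simulateCohort(design, cfg)))

  # direction fidelity needs dilution removed: use normalized spectra
  norm <- normalizeToReference(ss)
  ppm <- specPpm(norm)
  meanIn <- function(lo, hi, grp) {
    reg <- ppm > lo & ppm < hi
    mean(colSums(intensities(norm)[reg, lab == grp, drop = FALSE]))
  }
  expect_gt(meanIn(3.25, 3.29, 1), meanIn(3.25, 3.29, 0))  # taurine up
  expect_lt(meanIn(2.52, 2.56, 1), meanIn(2.52, 2.56, 0))  # citrate down

  # TSP integral ignores the per-subject dilution factor (noiseless check)
  cfg0 <- tinyConfig(seed = 8, noiseSd = 0, dilutionLogSd = 0.5)
  ss0 <- simulateCohort(cohortDesign(6, 6), cfg0)
  tspInt <- apply(intensities(ss0)[abs(specPpm(ss0)) <= 0.05, ], 2, sum)
  # invariant up to metabolite tails reaching the reference window; the
  # dilution factors themselves spread over ~3x
  expect_lt(diff(range(tspInt)) / mean(tspInt), 0.005)
  expect_gt(diff(range(colData(ss0)$dilution)), 0.5)

  # null design: group mean bins indistinguishable beyond noise
  ssNull <- simulateCohort(cohortDesign(10, 10, foldChange = 1),
                           tinyConfig(seed = 9))
  bNull <- binSpectra(normalizeToReference(ssNull))
  g <- classLabels(bNull)
  fm <- featureMatrix(bNull)
  delta <- abs(colMeans(fm[g == 1, ]) - colMeans(fm[g == 0, ]))
  pooled <- apply(fm, 2, sd)
  expect_lt(max(delta / (pooled + 1e-12)), 2.5)
})

test_that("direction fidelity holds at every marker's peaks at low noise", {
  cfg <- tinyConfig(seed = 13, noiseSd = 0)
  ss <- simulateCohort(cohortDesign(40, 40, withinGroupCv = 0.05), cfg)
  norm <- normalizeToReference(ss)
  ppm <- specPpm(norm)
  lab <- classLabels(norm)
  for (s in signatureLibrary()) {
    for (p0 in s@peaks$ppm) {
      reg <- abs(ppm - p0) <= 0.02
      d <- mean(colSums(intensities(norm)[reg, lab == 1, drop = FALSE])) -
        mean(colSums(intensities(norm)[reg, lab == 0, drop = FALSE]))
      expect_equal(sign(d), if (s@direction == "up") 1 else -1,
                   info = paste(s@name, p0))
    }
  }
})

test_that("spectra round-trip through the wide-CSV format", {
  cfg <- tinyConfig(seed = 3)
  ss <- simulateCohort(cohortDesign(3, 2), cfg)
  f <- tempfile(fileext = ".csv")
  writeSpectraCsv(ss, f, config = cfg)
  back <- readSpectraCsv(f)
  expect_equal(specPpm(back), specPpm(ss))
  expect_equal(unname(intensities(back)), unname(intensities(ss)),
               tolerance = 1e-12)
  expect_equal(classLabels(back), classLabels(ss))
  meta <- yaml::read_yaml(sub("\\.csv$", "_meta.yaml", f))
  expect_equal(meta$seed, 3)
})
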