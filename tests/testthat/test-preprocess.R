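test_that("reference normalization scales, is idempotent, rejects zeros", {
  ppm <- seq(0, 9.5, length.out = 1024)
  flat <- rep(1, 1024)  # reference integral over [0, 0.05] is 0.05 * 1
  ss <- SpectrumSet(ppm, cbind(a = 2 * flat, b = 5 * flat))
  norm <- normalizeToReference(ss)
  refInt <- function(x, j) {
    keep <- specPpm(x) >= -0.05 & specPpm(x) <= 0.05
    pracma::trapz(specPpm(x)[keep], intensities(x)[keep, j])
  }
  expect_equal(refInt(norm, 1), 1)
  expect_equal(refInt(norm, 2), 1)
  # samples with reference integral r are divided by exactly r
  expect_equal(intensities(norm)[, 1],
               intensities(ss)[, 1] / refInt(ss, 1))
  expect_equal(unname(intensities(normalizeToReference(norm))),
               unname(intensities(norm)))

  zero <- SpectrumSet(ppm, cbind(ok = flat, dead = 0 * flat))
  expect_error(normalizeToReference(zero), "dead")
})

test_that("bin layout matches an independent enumeration", {
  width <- 0.0092
  oracle <- enumerateBins(0, 9.5, width, exclude = c(4.6, 5.2))
  ppm <- seq(0, 9.5, length.out = 4096)
  b <- binSpectrum(ppm, rep(1, 4096), width = width, exclude = c(4.6, 5.2))
  expect_equal(nrow(b$edges), nrow(oracle))
  expect_equal(b$edges$right, oracle[, 2])
  expect_equal(b$edges$left, oracle[, 1])
  # no retained bin intersects the open water window
  expect_false(any(b$edges$left < 5.2 & b$edges$right > 4.6))
  # dropped + retained = full grid
  expect_equal(nrow(b$edges) + nrow(b$droppedEdges),
               ceiling(9.5 / width - 1e-9))
})

test_that("binning sums intensities and conserves the total", {
  # exact-integer axis commensurate with the width: interior full bins
  # [l, r) hold width points each, the top bin keeps the closed max point,
  # the trailing partial bin holds the remainder
  ppm <- as.numeric(0:99)
  y <- rep(1, 100)
  b <- binSpectrum(ppm, y, width = 5, exclude = NULL)
  v <- b$values[, 1]
  expect_equal(v, c(6, rep(5, 18), 4))
  expect_true(length(unique(v[2:19])) == 1L)
  expect_equal(sum(b$values), sum(y))  # every point lands in some bin

  ppm <- seq(0, 9.5, length.out = 2048)

  # with exclusion: retained sum = total - points in dropped bins
  set.seed(1)
  y2 <- runif(2048)
  b2 <- binSpectrum(ppm, y2, width = 0.0092, exclude = c(4.6, 5.2))
  droppedPts <- mapply(function(l, r) sum(y2[ppm >= l & ppm < r]),
                       b2$droppedEdges$left, b2$droppedEdges$right)
  expect_equal(sum(b2$values) + sum(droppedPts), sum(y2))
  expect_error(binSpectrum(ppm, y, width = 20), "span")
})

test_that("binSpectra equals per-spectrum binning and keeps sample order", {
  cfg <- tinyConfig(seed = 5)
  ss <- simulateCohort(cohortDesign(3, 3), cfg)
  b <- binSpectra(ss)
  for (j in seq_len(ncol(ss))) {
    single <- binSpectrum(specPpm(ss), intensities(ss)[, j])
    expect_equal(unname(assay(b, "binned")[, j]), single$values[, 1])
  }
  # column order follows descending bin-center ppm
  expect_true(all(diff(binCenters(b)) < 0))
  # identical spectra give identical rows
  same <- SpectrumSet(specPpm(ss),
                      intensities(ss)[, c(1, 1, 1)])
  fb <- featureMatrix(binSpectra(same))
  expect_equal(fb[1, ], fb[3, ])

  # row permutation in = row permutation out
  perm <- c(4, 1, 6, 2, 5, 3)
  bPerm <- binSpectra(ss[, perm])
  expect_equal(unname(featureMatrix(bPerm)),
               unname(featureMatrix(b)[perm, ]))
})

test_that("Pareto scaling matches hand arithmetic and stores parameters", {
  expect_equal(paretoScale(cbind(c(1, 2, 3)))$scaled[, 1], c(-1, 0, 1))
  expect_equal(paretoScale(cbind(c(5, 5, 5)))$scaled[, 1], c(0, 0, 0))

  # brute-force recomputation for column [0, 0, 4]
  x <- c(0, 0, 4)
  mu <- sum(x) / 3
  sdev <- sqrt(sum((x - mu)^2) / 2)
  expect_equal(paretoScale(cbind(x))$scaled[, 1], (x - mu) / sqrt(sdev))

  set.seed(2)
  m <- matrix(rnorm(60), nrow = 10)
  ps <- paretoScale(m)
  expect_equal(colMeans(ps$scaled), rep(0, 6))
  # Pareto property: post-scaling sd equals sqrt of pre-scaling sd
  expect_equal(apply(ps$scaled, 2, sd), sqrt(apply(m, 2, sd)))
  expect_error(paretoScale(m[1, , drop = FALSE]), "two samples")
})

test_that("stored scaling applies unchanged to new samples", {
  set.seed(3)
  m <- matrix(rnorm(40), nrow = 8)
  ps <- paretoScale(m)
  expect_equal(applyScaling(m, ps$params), ps$scaled)
  one <- applyScaling(m[3, , drop = FALSE], ps$params)
  expect_equal(dim(one), c(1L, 5L))
  # a new value equal to a training column mean scales to zero
  atMean <- matrix(ps$params@colMeans, nrow = 1)
  expect_equal(unname(applyScaling(atMean, ps$params)), matrix(0, 1, 5))
  expect_error(applyScaling(m[, 1:3], ps$params), "column count")
})
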