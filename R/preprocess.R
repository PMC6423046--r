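# TSP normalization, fixed-width binning with water exclusion, Pareto scaling.

#' Normalize spectra to the internal reference integral
#'
#' Divides each spectrum by the trapezoidal integral of the TSP reference
#' window (default 0.00 +/- 0.05 ppm), so that after the call the reference
#' integral equals 1. This removes the per-subject urine dilution factor,
#' which scales every metabolite but not the added reference.
#'
#' @param x a [SpectrumSet-class].
#' @param refWindow numeric length 2, reference window in ppm.
#' @return the normalized [SpectrumSet-class].
#' @export
#' @examples
#' ss <- simulateCohort(cohortDesign(2, 2), simConfig(nPoints = 2048, seed = 1))
#' norm <- normalizeToReference(ss)
normalizeToReference <- function(x, refWindow = c(-0.05, 0.05)) {
  ppm <- specPpm(x)
  # the axis may start right at the reference (0.00 ppm); integrate over the
  # part of the window the axis covers
  refWindow <- c(max(refWindow[1], min(ppm)), min(refWindow[2], max(ppm)))
  if (refWindow[1] >= refWindow[2])
    stop("reference window lies outside the ppm axis")
  ints <- intensities(x)
  ref <- apply(ints, 2, function(y) windowIntegral(ppm, y, refWindow))
  bad <- which(!(ref > 0))
  if (length(bad))
    stop("non-positive reference integral for sample(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  assay(x, "intensity") <- sweep(ints, 2, ref, `/`)
  x
}

# Bin-edge layout: half-open bins [left, right) laid from ppmMax toward
# ppmMin; the trailing bin at ppmMin may be partial and is kept. The single
# topmost axis point (ppm == ppmMax) is assigned to the first bin.
binLayout <- function(ppmMin, ppmMax, width) {
  span <- ppmMax - ppmMin
  if (width <= 0) stop("bin width must be positive")
  if (width > span) stop("bin width exceeds the axis span")
  nb <- ceiling(span / width - 1e-9)
  right <- ppmMax - (seq_len(nb) - 1) * width
  left <- pmax(right - width, ppmMin)
  list(left = left, right = right, n = nb)
}

#' Bin one spectrum to fixed-width buckets with water exclusion
#'
#' Bins of `width` ppm are laid down from the top of the axis toward the
#' bottom as half-open intervals `[left, right)` (the topmost axis point is
#' assigned to the first bin; a trailing partial bin at the bottom is kept).
#' Each bin value is the SUM of point intensities falling in the interval.
#' Any bin overlapping the open exclusion window (default the residual-water
#' region 4.6-5.2 ppm) is dropped entirely.
#'
#' @param ppm numeric axis (any monotone order).
#' @param intensity numeric vector (or matrix, points x samples).
#' @param width bin width in ppm (default 0.0092).
#' @param exclude numeric length 2 exclusion window in ppm, or NULL.
#' @return list with `values` (retained bins, descending ppm; a matrix when
#'   `intensity` is a matrix), `edges` (data.frame `left`, `right`),
#'   `droppedEdges` (edges of excluded bins).
#' @export
binSpectrum <- function(ppm, intensity, width = 0.0092,
                        exclude = c(4.6, 5.2)) {
  o <- order(ppm)
  ppm <- ppm[o]
  intensity <- if (is.matrix(intensity)) intensity[o, , drop = FALSE]
    else matrix(intensity[o], ncol = 1)
  lay <- binLayout(min(ppm), max(ppm), width)
  # ascending breakpoints; findInterval puts p in [b_i, b_{i+1}), and
  # rightmost.closed keeps the topmost point in the top bin
  breaks <- c(lay$left[lay$n], lay$right[lay$n:1])
  idxAsc <- findInterval(ppm, breaks, rightmost.closed = TRUE)
  binIdx <- lay$n + 1L - idxAsc                 # descending-ppm bin index
  sums <- rowsum(intensity, binIdx)             # sorted by bin index
  values <- matrix(0, nrow = lay$n, ncol = ncol(intensity))
  values[as.integer(rownames(sums)), ] <- sums
  keep <- rep(TRUE, lay$n)
  dropped <- data.frame(left = numeric(0), right = numeric(0))
  if (!is.null(exclude)) {
    if (exclude[1] >= exclude[2]) stop("invalid exclusion window")
    keep <- !(lay$left < exclude[2] & lay$right > exclude[1])
    dropped <- data.frame(left = lay$left[!keep], right = lay$right[!keep])
  }
  list(values = values[keep, , drop = FALSE],
       edges = data.frame(left = lay$left[keep], right = lay$right[keep]),
       droppedEdges = dropped)
}

#' Bin a SpectrumSet into a BinnedSpectra feature object
#'
#' Applies [binSpectrum()] to every sample of a shared-axis spectrum set and
#' assembles the retained bins (descending ppm) into a
#' [BinnedSpectra-class]. Binning each spectrum separately and stacking
#' gives the identical matrix.
#'
#' @param x a [SpectrumSet-class].
#' @inheritParams binSpectrum
#' @return a [BinnedSpectra-class]; class labels are carried over.
#' @export
binSpectra <- function(x, width = 0.0092, exclude = c(4.6, 5.2)) {
  b <- binSpectrum(specPpm(x), intensities(x), width = width,
                   exclude = exclude)
  rd <- DataFrame(left = b$edges$left, right = b$edges$right,
                  center = (b$edges$left + b$edges$right) / 2)
  colnames(b$values) <- colnames(x)
  se <- SummarizedExperiment(assays = list(binned = b$values),
                             rowData = rd, colData = colData(x))
  metadata(se) <- list(width = width, exclude = exclude,
                       droppedEdges = b$droppedEdges)
  new("BinnedSpectra", se)
}

#' Pareto scaling with stored parameters
#'
#' Mean-centers each column and divides by the square root of its sample
#' standard deviation (denominator n - 1) — the Pareto compromise between
#' plain centering and unit-variance scaling. Zero-variance columns are set
#' to all zeros (not dropped). The returned parameters reproduce the exact
#' transform on new samples via [applyScaling()], as required when scoring a
#' blinded holdout with training-set scaling.
#'
#' @param x numeric matrix (samples x bins) or a [BinnedSpectra-class].
#' @param kind `"pareto"` (default) or `"center_only"`.
#' @return list with `scaled` (matrix) and `params`
#'   ([ScalingParams-class]).
#' @export
#' @examples
#' paretoScale(cbind(a = c(1, 2, 3)))$scaled  # -1, 0, 1
paretoScale <- function(x, kind = c("pareto", "center_only")) {
  kind <- match.arg(kind)
  if (is(x, "BinnedSpectra")) x <- featureMatrix(x)
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop("at least two samples are required to estimate scaling")
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  params <- new("ScalingParams", colMeans = mu, colSds = sds, kind = kind)
  list(scaled = applyScaling(x, params), params = params)
}

#' Apply stored scaling parameters to new samples
#'
#' Uses the training means and standard deviations verbatim; never
#' re-estimates from the new data. Columns with zero training variance map
#' to 0.
#'
#' @param x numeric matrix (samples x bins) or a [BinnedSpectra-class];
#'   column count must match the parameters.
#' @param params a [ScalingParams-class] from [paretoScale()].
#' @return scaled numeric matrix.
#' @export
applyScaling <- function(x, params) {
  if (is(x, "BinnedSpectra")) x <- featureMatrix(x)
  x <- as.matrix(x)
  if (ncol(x) != length(params@colMeans))
    stop("column count (", ncol(x), ") does not match scaling parameters (",
         length(params@colMeans), ")")
  denom <- if (params@kind == "pareto") sqrt(params@colSds) else
    rep(1, length(params@colSds))
  centered <- sweep(x, 2, params@colMeans)
  zero <- params@colSds == 0 | denom == 0
  denom[zero] <- 1
  out <- sweep(centered, 2, denom, `/`)
  out[, zero] <- 0
  out
}
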