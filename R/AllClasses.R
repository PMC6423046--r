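#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# Spectral containers (SummarizedExperiment-backed)
# ---------------------------------------------------------------------------

#' SpectrumSet: a set of 1D NMR spectra on a shared ppm axis
#'
#' Thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `"intensity"` assay (axis points x samples), the chemical-shift axis in
#' `rowData()$ppm` (strictly monotone), and optional class labels
#' (0 = control, 1 = case) in `colData()$label`.
#'
#' @seealso [SpectrumSet()], [simulateCohort()], [normalizeToReference()]
#' @name SpectrumSet-class
#' @aliases SpectrumSet-class
#' @exportClass SpectrumSet
setClass("SpectrumSet", contains = "SummarizedExperiment")

setValidity("SpectrumSet", function(object) {
  msg <- character()
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  p <- rowData(object)$ppm
  if (is.null(p)) {
    msg <- c(msg, "rowData()$ppm is required")
  } else {
    if (length(p) != nrow(object))
      msg <- c(msg, "ppm axis length must equal the number of rows")
    d <- diff(p)
    if (length(d) && !(all(d > 0) || all(d < 0)))
      msg <- c(msg, "ppm axis must be strictly monotone")
  }
  lab <- colData(object)$label
  if (!is.null(lab) && !all(lab %in% c(0, 1) | is.na(lab)))
    msg <- c(msg, "labels must be 0 (control) or 1 (case)")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrumSet
#'
#' @param ppm numeric, strictly monotone chemical-shift axis (ppm).
#' @param intensities numeric matrix, axis points x samples.
#' @param labels optional numeric/integer vector of class labels
#'   (0 = control, 1 = case), one per sample.
#' @param sampleIds optional character vector of sample identifiers; defaults
#'   to the column names of `intensities` or `S1, S2, ...`.
#' @return a [SpectrumSet-class] object.
#' @export
#' @examples
#' ppm <- seq(0, 9.5, length.out = 64)
#' ss <- SpectrumSet(ppm, cbind(a = ppm * 0 + 1, b = ppm))
#' specPpm(ss)[1:3]
SpectrumSet <- function(ppm, intensities, labels = NULL, sampleIds = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(sampleIds)) {
    sampleIds <- colnames(intensities)
    if (is.null(sampleIds))
      sampleIds <- paste0("S", seq_len(ncol(intensities)))
  }
  colnames(intensities) <- sampleIds
  cd <- DataFrame(row.names = sampleIds)
  if (!is.null(labels)) cd$label <- as.numeric(labels)
  se <- SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = DataFrame(ppm = as.numeric(ppm)),
    colData = cd)
  new("SpectrumSet", se)
}

#' BinnedSpectra: binned feature matrix with bin bookkeeping
#'
#' [SummarizedExperiment::SummarizedExperiment] subclass produced by
#' [binSpectra()]. Rows are retained spectral bins in descending-ppm order
#' with `rowData()` columns `left`, `right`, `center`; the `"binned"` assay is
#' bins x samples. `metadata()` records the bin `width`, the excluded window,
#' and the edges of bins dropped for overlapping it.
#'
#' @name BinnedSpectra-class
#' @aliases BinnedSpectra-class
#' @exportClass BinnedSpectra
setClass("BinnedSpectra", contains = "SummarizedExperiment")

setValidity("BinnedSpectra", function(object) {
  msg <- character()
  rd <- rowData(object)
  if (!all(c("left", "right", "center") %in% colnames(rd)))
    msg <- c(msg, "rowData must have 'left', 'right', 'center'")
  if (!"binned" %in% assayNames(object))
    msg <- c(msg, "assay 'binned' is required")
  ex <- metadata(object)$exclude
  if (!is.null(ex) && length(ex) == 2L && nrow(object) > 0) {
    if (any(rd$left < ex[2] & rd$right > ex[1]))
      msg <- c(msg, "a retained bin overlaps the excluded region")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Simulation parameter classes
# ---------------------------------------------------------------------------

#' MetaboliteSignature: one metabolite's multiplet pattern and direction
#'
#' Describes a urinary metabolite for the spectrum simulator and for peak
#' annotation: a peak table (chemical shift in ppm, multiplicity code
#' `s`/`d`/`t`/`m`, strictly positive relative intensity), the expected
#' case-vs-control direction (`up`, `down`, `flat`), and a baseline (control
#' group mean) concentration in arbitrary units.
#'
#' @name MetaboliteSignature-class
#' @aliases MetaboliteSignature-class
#' @exportClass MetaboliteSignature
setClass("MetaboliteSignature",
  representation(name = "character", peaks = "data.frame",
                 direction = "character", baseConc = "numeric"))

setValidity("MetaboliteSignature", function(object) {
  msg <- character()
  pk <- object@peaks
  if (!all(c("ppm", "multiplicity", "relIntensity") %in% colnames(pk)))
    msg <- c(msg, "peaks needs columns ppm, multiplicity, relIntensity")
  else {
    if (!all(pk$multiplicity %in% c("s", "d", "t", "m")))
      msg <- c(msg, "multiplicity must be one of s, d, t, m")
    if (!all(pk$relIntensity > 0))
      msg <- c(msg, "relIntensity values must be strictly positive")
  }
  if (!object@direction %in% c("up", "down", "flat"))
    msg <- c(msg, "direction must be 'up', 'down' or 'flat'")
  if (length(object@baseConc) != 1L || object@baseConc < 0)
    msg <- c(msg, "baseConc must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Construct a MetaboliteSignature
#'
#' @param name metabolite name.
#' @param peaks data.frame with columns `ppm`, `multiplicity` (one of
#'   `"s"`, `"d"`, `"t"`, `"m"`) and `relIntensity` (> 0).
#' @param direction `"up"`, `"down"` or `"flat"`: case-vs-control change.
#' @param baseConc control-group mean concentration (arbitrary units).
#' @return a [MetaboliteSignature-class].
#' @export
#' @examples
#' metaboliteSignature("taurine",
#'   data.frame(ppm = c(3.27, 3.45), multiplicity = "t", relIntensity = 2),
#'   direction = "up", baseConc = 2)
metaboliteSignature <- function(name, peaks, direction = "flat",
                                baseConc = 1) {
  new("MetaboliteSignature", name = name,
      peaks = as.data.frame(peaks), direction = direction,
      baseConc = as.numeric(baseConc))
}

setMethod("show", "MetaboliteSignature", function(object) {
  cat(sprintf("MetaboliteSignature '%s' (%s, base %.3g): %s\n",
              object@name, object@direction, object@baseConc,
              paste0(sprintf("%.2f(%s)", object@peaks$ppm,
                             object@peaks$multiplicity), collapse = ", ")))
})

#' SimConfig: spectral simulation parameters
#'
#' Axis range and resolution, spectrometer field, Lorentzian line width,
#' J-coupling, additive noise, per-subject dilution spread (log scale),
#' residual-water amplitude, TSP reference concentration and RNG seed.
#'
#' @name SimConfig-class
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  representation(ppmMin = "numeric", ppmMax = "numeric", nPoints = "integer",
                 fieldMHz = "numeric", linewidthHz = "numeric", jHz = "numeric",
                 noiseSd = "numeric", dilutionLogSd = "numeric",
                 waterAmplitude = "numeric", tspConc = "numeric",
                 seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@ppmMin >= object@ppmMax) msg <- c(msg, "ppmMin must be < ppmMax")
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  for (s in c("fieldMHz", "linewidthHz", "jHz", "noiseSd", "dilutionLogSd",
              "waterAmplitude", "tspConc")) {
    if (slot(object, s) < 0) msg <- c(msg, paste0(s, " must be >= 0"))
  }
  if (object@fieldMHz == 0) msg <- c(msg, "fieldMHz must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults emulate 500 MHz 1D proton urine spectra: 0-9.5 ppm on 16384
#' points, 1 Hz Lorentzian line width, 7 Hz first-order J-coupling, a fixed
#' TSP reference at 0.00 ppm and a broad residual-water hump at 4.9 ppm.
#'
#' @param ppmMin,ppmMax axis range (ppm).
#' @param nPoints number of axis points.
#' @param fieldMHz spectrometer proton frequency (MHz).
#' @param linewidthHz Lorentzian half-width at half-maximum (Hz).
#' @param jHz scalar J-coupling used for multiplet splitting (Hz).
#' @param noiseSd additive white-noise standard deviation (intensity units).
#' @param dilutionLogSd standard deviation of the per-subject log-normal
#'   dilution factor (log scale); the dilution scales every metabolite but
#'   not the TSP reference.
#' @param waterAmplitude amplitude of the residual-water Gaussian at 4.9 ppm.
#' @param tspConc concentration of the TSP reference singlet at 0.00 ppm.
#' @param seed RNG seed (NA = do not touch the RNG).
#' @return a [SimConfig-class].
#' @export
simConfig <- function(ppmMin = 0, ppmMax = 9.5, nPoints = 16384L,
                      fieldMHz = 500, linewidthHz = 1, jHz = 7,
                      noiseSd = 0.005, dilutionLogSd = 0.3,
                      waterAmplitude = 10, tspConc = 1, seed = NA_real_) {
  new("SimConfig", ppmMin = ppmMin, ppmMax = ppmMax,
      nPoints = as.integer(nPoints), fieldMHz = fieldMHz,
      linewidthHz = linewidthHz, jHz = jHz, noiseSd = noiseSd,
      dilutionLogSd = dilutionLogSd, waterAmplitude = waterAmplitude,
      tspConc = tspConc, seed = as.numeric(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %g-%g ppm / %d pts, %g MHz, lw %g Hz, J %g Hz,\n",
    object@ppmMin, object@ppmMax, object@nPoints, object@fieldMHz,
    object@linewidthHz, object@jHz))
  cat(sprintf("  noiseSd %g, dilutionLogSd %g, water %g, TSP %g, seed %s\n",
              object@noiseSd, object@dilutionLogSd, object@waterAmplitude,
              object@tspConc, ifelse(is.na(object@seed), "NA",
                                     format(object@seed))))
})

#' CohortDesign: case/control cohort layout
#'
#' Group sizes, the concentration fold change applied per signature direction
#' (case mean = control mean x `foldChange` for `up`, / `foldChange` for
#' `down`), and the within-group coefficient of variation of per-subject
#' concentrations. Default sizes mirror a screening cohort of 156 healthy
#' controls and 92 colorectal-neoplasia cases.
#'
#' @name CohortDesign-class
#' @aliases CohortDesign-class
#' @exportClass CohortDesign
setClass("CohortDesign",
  representation(nControl = "integer", nCase = "integer",
                 foldChange = "numeric", withinGroupCv = "numeric"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (object@nControl < 0L || object@nCase < 0L)
    msg <- c(msg, "group sizes must be >= 0")
  if (object@nControl + object@nCase < 1L)
    msg <- c(msg, "at least one sample is required")
  if (object@foldChange <= 0) msg <- c(msg, "foldChange must be > 0")
  if (object@withinGroupCv < 0) msg <- c(msg, "withinGroupCv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortDesign
#'
#' @param nControl,nCase group sizes.
#' @param foldChange case-vs-control concentration multiplier (> 0), applied
#'   along each signature's direction.
#' @param withinGroupCv per-subject concentration coefficient of variation.
#' @return a [CohortDesign-class].
#' @export
cohortDesign <- function(nControl = 156L, nCase = 92L, foldChange = 2,
                         withinGroupCv = 0.2) {
  new("CohortDesign", nControl = as.integer(nControl),
      nCase = as.integer(nCase), foldChange = foldChange,
      withinGroupCv = withinGroupCv)
}

# ---------------------------------------------------------------------------
# Scaling / model / result classes
# ---------------------------------------------------------------------------

#' ScalingParams: column centering/scaling parameters
#'
#' Column means and sample standard deviations (denominator n - 1) estimated
#' by [paretoScale()] on a training matrix, reusable on new samples via
#' [applyScaling()]. `kind` is `"pareto"` (divide by sqrt(sd)) or
#' `"center_only"`.
#'
#' @name ScalingParams-class
#' @aliases ScalingParams-class
#' @exportClass ScalingParams
setClass("ScalingParams",
  representation(colMeans = "numeric", colSds = "numeric", kind = "character"))

setValidity("ScalingParams", function(object) {
  msg <- character()
  if (length(object@colMeans) != length(object@colSds))
    msg <- c(msg, "colMeans and colSds lengths differ")
  if (any(object@colSds < 0)) msg <- c(msg, "colSds must be >= 0")
  if (!object@kind %in% c("pareto", "center_only"))
    msg <- c(msg, "kind must be 'pareto' or 'center_only'")
  if (length(msg)) msg else TRUE
})

#' OplsModel: fitted OPLS-DA model
#'
#' One predictive component (weights `w`, loadings `pP`, training scores
#' `tP`, y-loading `q`) plus `nOrth` orthogonal components (`Wo`, `Po`, `To`).
#' `yMean` un-centers predictions; `r2y` is the training explained class
#' variance and `q2` the cross-validated analogue (NA until computed).
#'
#' @name OplsModel-class
#' @aliases OplsModel-class
#' @exportClass OplsModel
setClass("OplsModel",
  representation(w = "numeric", pP = "numeric", tP = "numeric", q = "numeric",
                 Wo = "matrix", Po = "matrix", To = "matrix",
                 nOrth = "integer", yMean = "numeric", r2y = "numeric",
                 q2 = "numeric", scaling = "ANY"))

setValidity("OplsModel", function(object) {
  msg <- character()
  tol <- 1e-6
  if (abs(sqrt(sum(object@w^2)) - 1) > tol)
    msg <- c(msg, "predictive weight vector must have unit norm")
  if (object@nOrth != ncol(object@Wo))
    msg <- c(msg, "nOrth must equal the number of stored orthogonal components")
  if (ncol(object@Wo) > 0) {
    wn <- sqrt(colSums(object@Wo^2))
    if (any(abs(wn - 1) > tol))
      msg <- c(msg, "orthogonal weight vectors must have unit norm")
    ortho <- abs(crossprod(object@To, object@tP)) /
      (sqrt(colSums(object@To^2)) * sqrt(sum(object@tP^2)) + 1e-300)
    if (any(ortho > 1e-6))
      msg <- c(msg, "predictive scores must be orthogonal to orthogonal scores")
  }
  if (!is.na(object@q2) && object@q2 > 1 + 1e-12)
    msg <- c(msg, "q2 cannot exceed 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OplsModel", function(object) {
  cat(sprintf(
    "OplsModel: 1 predictive + %d orthogonal component(s), %d variables\n",
    object@nOrth, length(object@w)))
  cat(sprintf("  R2Y = %.3f, Q2 = %s, training n = %d\n", object@r2y,
              ifelse(is.na(object@q2), "NA", sprintf("%.3f", object@q2)),
              length(object@tP)))
})

#' StocsyResult: per-bin correlation/covariance with a driver
#'
#' Per-bin Pearson correlation and covariance (denominator n - 1) between a
#' driver variable (by default the OPLS predictive score) and every spectral
#' bin; the classical STOCSY display plots `cov` colored by `corr`.
#'
#' @name StocsyResult-class
#' @aliases StocsyResult-class
#' @exportClass StocsyResult
setClass("StocsyResult",
  representation(corr = "numeric", cov = "numeric", binCenters = "numeric",
                 annotations = "data.frame", constantBins = "integer"))

setValidity("StocsyResult", function(object) {
  msg <- character()
  n <- length(object@binCenters)
  if (length(object@corr) != n || length(object@cov) != n)
    msg <- c(msg, "corr/cov/binCenters lengths differ")
  if (any(abs(object@corr) > 1 + 1e-9))
    msg <- c(msg, "|corr| must be <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StocsyResult", function(object) {
  cat(sprintf("StocsyResult: %d bins, max |corr| = %.3f",
              length(object@corr), max(abs(object@corr))))
  if (length(object@constantBins))
    cat(sprintf(" (%d constant bins set to corr 0)",
                length(object@constantBins)))
  cat("\n")
  if (nrow(object@annotations))
    cat("  annotated metabolites:",
        paste(unique(object@annotations$metabolite), collapse = ", "), "\n")
})

#' ConfusionCounts: binary confusion-table counts
#'
#' @name ConfusionCounts-class
#' @aliases ConfusionCounts-class
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(tp = "integer", fn = "integer", tn = "integer",
                 fp = "integer"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tp, object@fn, object@tn, object@fp) < 0L))
    "counts must be non-negative" else TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: controls %d/%d correct, cases %d/%d correct\n",
              object@tn, object@tn + object@fp,
              object@tp, object@tp + object@fn))
})

#' DiagnosticReport: the diagnostic-accuracy panel
#'
#' Sensitivity, specificity, prevalence, positive/negative predictive values
#' and likelihood ratios. `plr` is NA when specificity = 1 (reported as
#' "N/A"); `nlr` is NA when specificity = 0.
#'
#' @name DiagnosticReport-class
#' @aliases DiagnosticReport-class
#' @exportClass DiagnosticReport
setClass("DiagnosticReport",
  representation(sensitivity = "numeric", specificity = "numeric",
                 prevalence = "numeric", ppv = "numeric", npv = "numeric",
                 plr = "numeric", nlr = "numeric"))

setValidity("DiagnosticReport", function(object) {
  msg <- character()
  for (s in c("sensitivity", "specificity", "prevalence", "ppv", "npv")) {
    v <- slot(object, s)
    if (!is.na(v) && (v < 0 || v > 1))
      msg <- c(msg, paste0(s, " must lie in [0, 1]"))
  }
  if (is.na(object@plr) != (object@specificity == 1))
    msg <- c(msg, "plr must be NA exactly when specificity = 1")
  if (is.na(object@nlr) != (object@specificity == 0))
    msg <- c(msg, "nlr must be NA exactly when specificity = 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiagnosticReport", function(object) {
  f <- formatDiagnosticReport(object)
  cat("DiagnosticReport:\n")
  for (n in names(f)) cat(sprintf("  %-12s %s\n", n, f[[n]]))
})

#' RocCurve: ROC curve with trapezoidal AUC
#'
#' @name RocCurve-class
#' @aliases RocCurve-class
#' @exportClass RocCurve
setClass("RocCurve",
  representation(thresholds = "numeric", fpr = "numeric", tpr = "numeric",
                 auc = "numeric"))

setValidity("RocCurve", function(object) {
  msg <- character()
  if (length(object@fpr) != length(object@tpr))
    msg <- c(msg, "fpr/tpr lengths differ")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    msg <- c(msg, "fpr and tpr must be non-decreasing along the curve")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: AUC = %.3f over %d threshold(s)\n",
              object@auc, length(object@thresholds)))
})
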