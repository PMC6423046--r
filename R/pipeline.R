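# End-to-end study replica and printed-table verification.

#' Assemble a run configuration
#'
#' Defaults are the study settings: 0.0092-ppm bins, 4.6-5.2 ppm water
#' exclusion, 1 predictive + 3 orthogonal components, 7 cross-validation
#' folds, a stratified 1/3 blinded holdout and a 0.5 class cut-off. Either
#' provide `spectraFile` (wide CSV, see [readSpectraCsv()]) or a simulation
#' block (`design`, `simConfig`).
#'
#' @param spectraFile optional path to a wide spectra CSV.
#' @param labelsFile optional labels CSV path.
#' @param design [CohortDesign-class] for simulation (used when no
#'   `spectraFile`).
#' @param sim [SimConfig-class] for simulation.
#' @param binWidth bin width in ppm.
#' @param exclude water exclusion window (ppm).
#' @param nOrth orthogonal components.
#' @param nFolds cross-validation folds.
#' @param holdoutFraction blinded fraction per class.
#' @param cutoff class cut-off.
#' @param rThreshold STOCSY annotation correlation threshold.
#' @param seed master seed; also used for the simulation when `sim` carries
#'   no seed.
#' @return a named list of class `"urinmrConfig"`.
#' @export
runConfig <- function(spectraFile = NULL, labelsFile = NULL,
                      design = cohortDesign(), sim = simConfig(),
                      binWidth = 0.0092, exclude = c(4.6, 5.2),
                      nOrth = 3L, nFolds = 7L, holdoutFraction = 1 / 3,
                      cutoff = 0.5, rThreshold = 0.6, seed = 1L) {
  if (is.na(sim@seed)) sim@seed <- as.numeric(seed)
  structure(list(spectraFile = spectraFile, labelsFile = labelsFile,
                 design = design, sim = sim, binWidth = binWidth,
                 exclude = exclude, nOrth = as.integer(nOrth),
                 nFolds = as.integer(nFolds),
                 holdoutFraction = holdoutFraction, cutoff = cutoff,
                 rThreshold = rThreshold, seed = as.integer(seed)),
            class = "urinmrConfig")
}

configAsList <- function(config) {
  list(spectraFile = config$spectraFile, labelsFile = config$labelsFile,
       design = list(nControl = config$design@nControl,
                     nCase = config$design@nCase,
                     foldChange = config$design@foldChange,
                     withinGroupCv = config$design@withinGroupCv),
       sim = list(ppmMin = config$sim@ppmMin, ppmMax = config$sim@ppmMax,
                  nPoints = config$sim@nPoints,
                  fieldMHz = config$sim@fieldMHz,
                  linewidthHz = config$sim@linewidthHz, jHz = config$sim@jHz,
                  noiseSd = config$sim@noiseSd,
                  dilutionLogSd = config$sim@dilutionLogSd,
                  waterAmplitude = config$sim@waterAmplitude,
                  tspConc = config$sim@tspConc, seed = config$sim@seed),
       binWidth = config$binWidth, exclude = config$exclude,
       nOrth = config$nOrth, nFolds = config$nFolds,
       holdoutFraction = config$holdoutFraction, cutoff = config$cutoff,
       rThreshold = config$rThreshold, seed = config$seed)
}

stageLog <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the end-to-end study replica
#'
#' Sequences the full analysis: simulate (or load) the cohort, TSP
#' normalization, binning with water exclusion, Pareto scaling, OPLS-DA fit
#' with training Q2, stratified blinded-holdout validation with the
#' diagnostic-accuracy panel, STOCSY against the predictive score with
#' metabolite annotation, and oriented per-metabolite ROC ranking. All
#' outputs land in `dir` together with the resolved configuration and
#' provenance (seed, config hash, package version); two runs with the same
#' seed produce byte-identical numeric outputs.
#'
#' @param config a configuration from [runConfig()].
#' @param dir output directory (created if missing).
#' @param library signature library (default [signatureLibrary()]).
#' @param verbose log each stage with sample counts (default TRUE).
#' @return invisibly, a list with `dir`, `spectra`, `binned`, `holdout`,
#'   `stocsy`, `annotations`, `roc`, `files`.
#' @export
runStudyReplica <- function(config = runConfig(), dir = tempfile("urinmr_"),
                            library = signatureLibrary(), verbose = TRUE) {
  stopifnot(inherits(config, "urinmrConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(config = file.path(dir, "config.yaml"),
                spectra = file.path(dir, "spectra.csv"),
                binned = file.path(dir, "binned.csv"),
                binnedMeta = file.path(dir, "binned_meta.json"),
                model = file.path(dir, "model.json"),
                holdout = file.path(dir, "holdout_report.json"),
                stocsy = file.path(dir, "stocsy.csv"),
                roc = file.path(dir, "roc.csv"),
                provenance = file.path(dir, "provenance.json"))
  yaml::write_yaml(configAsList(config), files$config)

  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  spectra <- runStage("cohort", {
    if (!is.null(config$spectraFile)) {
      s <- readSpectraCsv(config$spectraFile, config$labelsFile)
      stageLog(verbose, "cohort", "loaded %d spectra from %s", ncol(s),
               config$spectraFile)
      s
    } else {
      s <- simulateCohort(config$design, config$sim, library)
      stageLog(verbose, "cohort", "simulated %d controls + %d cases",
               config$design@nControl, config$design@nCase)
      s
    }
  })
  writeSpectraCsv(spectra, files$spectra, config = config$sim)

  normalized <- runStage("normalize", normalizeToReference(spectra))
  binned <- runStage("bin",
    binSpectra(normalized, width = config$binWidth,
               exclude = config$exclude))
  stageLog(verbose, "bin", "%d retained bins (%d dropped in water window)",
           nrow(binned), nrow(metadata(binned)$droppedEdges))
  utils::write.csv(
    data.frame(bin_center = binCenters(binned), featureMatrixT(binned)),
    files$binned, row.names = FALSE)
  jsonlite::write_json(
    list(width = metadata(binned)$width, exclude = metadata(binned)$exclude,
         edges = binEdges(binned),
         droppedEdges = metadata(binned)$droppedEdges),
    files$binnedMeta, digits = NA)

  y <- classLabels(binned)
  if (is.null(y)) stop("stage 'model' failed: spectra carry no class labels")
  hv <- runStage("validate",
    holdoutValidate(binned, y, holdoutFraction = config$holdoutFraction,
                    nOrth = config$nOrth, nFolds = config$nFolds,
                    cutoff = config$cutoff, seed = config$seed))
  stageLog(verbose, "validate",
           "train %d / holdout %d; R2Y %.3f Q2 %.3f; holdout %s controls, %s cases",
           length(hv$split$train), length(hv$split$holdout),
           hv$model@r2y, hv$model@q2,
           correctTotalStrings(hv$confusion)["controls"],
           correctTotalStrings(hv$confusion)["cases"])
  writeOplsModelJson(hv$model, files$model,
                     provenance = list(seed = config$seed,
                                       nOrth = config$nOrth,
                                       nFolds = config$nFolds,
                                       holdoutFraction = config$holdoutFraction))
  rep <- hv$report
  jsonlite::write_json(
    list(confusion = list(tp = hv$confusion@tp, fn = hv$confusion@fn,
                          tn = hv$confusion@tn, fp = hv$confusion@fp),
         correctTotal = as.list(correctTotalStrings(hv$confusion)),
         panel = list(sensitivity = rep@sensitivity,
                      specificity = rep@specificity,
                      prevalence = rep@prevalence, ppv = rep@ppv,
                      npv = rep@npv, plr = rep@plr, nlr = rep@nlr),
         formatted = as.list(formatDiagnosticReport(rep)),
         r2y = hv$model@r2y, q2 = hv$model@q2),
    files$holdout, digits = NA, auto_unbox = TRUE)

  st <- runStage("stocsy", {
    trainBinned <- featureMatrix(binned)[hv$split$train, , drop = FALSE]
    res <- runStocsy(trainBinned, hv$model@tP)
    res@binCenters <- binCenters(binned)
    res
  })
  ann <- annotatePeaks(st, library, rThreshold = config$rThreshold)
  stageLog(verbose, "stocsy", "%d annotated bins, metabolites: %s",
           nrow(ann), paste(unique(ann$metabolite), collapse = ", "))
  writeStocsyCsv(st, files$stocsy)

  roc <- runStage("roc", {
    lv <- metaboliteLevels(spectra, library)
    multiRocRanking(lv, y)
  })
  stageLog(verbose, "roc", "top metabolite: %s (AUC %.3f)",
           roc$metabolite[1], roc$auc[1])
  utils::write.csv(roc, files$roc, row.names = FALSE)

  jsonlite::write_json(
    list(seed = config$seed,
         configMd5 = unname(tools::md5sum(files$config)),
         package = "urinmr",
         version = as.character(utils::packageVersion("urinmr"))),
    files$provenance, auto_unbox = TRUE)

  invisible(list(dir = dir, spectra = spectra, binned = binned,
                 holdout = hv, stocsy = st, annotations = ann, roc = roc,
                 files = files))
}

# bins x samples data.frame helper for CSV export
featureMatrixT <- function(binned) {
  m <- assay(binned, "binned")
  as.data.frame(m)
}

#' Recompute the published accuracy tables from their printed counts
#'
#' Desk check of the diagnostic-accuracy arithmetic: from the printed
#' validation counts of the four class models (blinded controls/cases and
#' the numbers predicted correctly) it recomputes prevalence, sensitivity,
#' specificity, PPV, NPV and both likelihood ratios, and from the serum
#' tumor-marker counts (2/32 patients, 1/156 controls above the cut-off)
#' the corresponding sensitivity/specificity. Computed values are printed
#' next to the published ones. Two published predictive-value cells
#' (stage-0 PPV 87.6%, advanced-adenoma NPV 94.6%) differ from their own
#' defining formulas by one unit in the last decimal (exact arithmetic
#' gives 87.5% and 94.5%); `exactMatch` is FALSE there while
#' `withinPrintedPrecision` remains TRUE.
#'
#' @return data.frame with one row per checked cell: `table`, `row`,
#'   `quantity`, `computed`, `published`, `exactMatch`,
#'   `withinPrintedPrecision`.
#' @export
verifyReferenceTables <- function() {
  rows <- list(
    list(row = "All CRN", nNeg = 52, okNeg = 50, nPos = 30, okPos = 30,
         pub = c(prevalence = 36.6, sensitivity = 100, specificity = 96.2,
                 ppv = 93.8, npv = 100, plr = 26.0, nlr = 0.00)),
    list(row = "Pre-invasive CRN", nNeg = 52, okNeg = 50, nPos = 20,
         okPos = 19,
         pub = c(prevalence = 27.8, sensitivity = 95, specificity = 96.2,
                 ppv = 90.5, npv = 98.0, plr = 24.7, nlr = 0.05)),
    list(row = "Stage 0 CRN", nNeg = 52, okNeg = 51, nPos = 7, okPos = 7,
         pub = c(prevalence = 11.9, sensitivity = 100, specificity = 98.1,
                 ppv = 87.6, npv = 100, plr = 52.0, nlr = 0.00)),
    list(row = "Advanced adenoma", nNeg = 52, okNeg = 52, nPos = 12,
         okPos = 9,
         pub = c(prevalence = 18.8, sensitivity = 75, specificity = 100,
                 ppv = 100, npv = 94.6, plr = NA, nlr = 0.25)))
  out <- do.call(rbind, lapply(rows, function(r) {
    rep <- accuracyPanelFromRates(r$okPos / r$nPos, r$okNeg / r$nNeg,
                                  r$nPos / (r$nPos + r$nNeg))
    comp <- c(prevalence = roundHalfUp(100 * rep@prevalence, 1),
              sensitivity = roundHalfUp(100 * rep@sensitivity, 1),
              specificity = roundHalfUp(100 * rep@specificity, 1),
              ppv = roundHalfUp(100 * rep@ppv, 1),
              npv = roundHalfUp(100 * rep@npv, 1),
              plr = if (is.na(rep@plr)) NA_real_ else
                roundHalfUp(rep@plr, 1),
              nlr = roundHalfUp(rep@nlr, 2))
    data.frame(table = "accuracy", row = r$row, quantity = names(comp),
               computed = unname(comp), published = unname(r$pub))
  }))
  serum <- markerPanelFromCounts(2, 32, 1, 156)
  out <- rbind(out, data.frame(
    table = "serum-marker", row = "CEA / CA 19-9",
    quantity = c("sensitivity", "specificity"),
    computed = c(serum$sensitivityPct, serum$specificityPct),
    published = c(6.2, 99.3)))
  out$exactMatch <- ifelse(is.na(out$computed) & is.na(out$published), TRUE,
                           out$computed == out$published)
  tolUnit <- ifelse(out$quantity == "nlr", 0.01, 0.1)
  diff <- abs(out$computed - out$published)
  out$withinPrintedPrecision <- ifelse(is.na(diff), out$exactMatch,
                                       diff <= tolUnit + 1e-9)
  rownames(out) <- NULL
  out
}
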