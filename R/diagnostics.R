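# Diagnostic accuracy: confusion counts, predictive values, likelihood
# ratios, ROC/AUC and metabolite-level quantification.

#' Confusion counts from true and predicted labels
#'
#' @param truth,pred equal-length binary (0/1) label vectors.
#' @return a [ConfusionCounts-class].
#' @export
#' @examples
#' confusionCounts(c(0, 0, 1, 1), c(0, 1, 1, 1))
confusionCounts <- function(truth, pred) {
  truth <- as.numeric(truth)
  pred <- as.numeric(pred)
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  if (!all(c(truth, pred) %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  new("ConfusionCounts",
      tp = sum(truth == 1 & pred == 1), fn = sum(truth == 1 & pred == 0),
      tn = sum(truth == 0 & pred == 0), fp = sum(truth == 0 & pred == 1))
}

#' Per-class correct/total strings
#'
#' The bookkeeping style of a validation table: `"50/52"` controls,
#' `"30/30"` cases.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named character vector (`controls`, `cases`).
#' @export
correctTotalStrings <- function(counts) {
  c(controls = sprintf("%d/%d", counts@tn, counts@tn + counts@fp),
    cases = sprintf("%d/%d", counts@tp, counts@tp + counts@fn))
}

#' Diagnostic-accuracy panel from confusion counts
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), prevalence =
#' (tp+fn)/total unless supplied, then PPV, NPV and likelihood ratios by
#' the standard prevalence formulas (see [accuracyPanelFromRates()]).
#'
#' @param counts a [ConfusionCounts-class].
#' @param prevalence optional prevalence in (0, 1) overriding the evaluated
#'   set's composition, for projection to an external population.
#' @return a [DiagnosticReport-class].
#' @export
accuracyPanel <- function(counts, prevalence = NULL) {
  pos <- counts@tp + counts@fn
  neg <- counts@tn + counts@fp
  if (pos == 0L || neg == 0L)
    stop("both classes must be present to compute the panel")
  if (is.null(prevalence)) prevalence <- pos / (pos + neg)
  accuracyPanelFromRates(counts@tp / pos, counts@tn / neg, prevalence)
}

#' Diagnostic-accuracy panel from rates
#'
#' PPV = (sens x prev) / (sens x prev + (1 - spec)(1 - prev));
#' NPV = spec (1 - prev) / ((1 - sens) prev + spec (1 - prev));
#' +LR = sens / (1 - spec); -LR = (1 - sens) / spec. At specificity 1 the
#' positive likelihood ratio is undefined and reported as the "N/A"
#' sentinel (NA) rather than infinity; at specificity 0 the negative one
#' is NA.
#'
#' @param sensitivity,specificity,prevalence proportions; prevalence must
#'   lie in (0, 1) for the predictive values.
#' @return a [DiagnosticReport-class].
#' @export
#' @examples
#' accuracyPanelFromRates(30 / 30, 50 / 52, 30 / 82)
accuracyPanelFromRates <- function(sensitivity, specificity, prevalence) {
  for (v in c(sensitivity, specificity, prevalence))
    stopifnotScalarNumber(v, "rate")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly inside (0, 1)")
  se <- sensitivity; sp <- specificity; pr <- prevalence
  ppv <- (se * pr) / (se * pr + (1 - sp) * (1 - pr))
  npv <- (sp * (1 - pr)) / ((1 - se) * pr + sp * (1 - pr))
  plr <- if (sp == 1) NA_real_ else se / (1 - sp)
  nlr <- if (sp == 0) NA_real_ else (1 - se) / sp
  new("DiagnosticReport", sensitivity = se, specificity = sp,
      prevalence = pr, ppv = ppv, npv = npv, plr = plr, nlr = nlr)
}

#' Format a diagnostic report the way accuracy tables print it
#'
#' Percentages half-up to one decimal, positive likelihood ratio to one
#' decimal ("N/A" when specificity = 1), negative likelihood ratio to two
#' decimals.
#'
#' @param report a [DiagnosticReport-class].
#' @return named character vector.
#' @export
formatDiagnosticReport <- function(report) {
  pct <- function(p) sprintf("%.1f%%", roundHalfUp(100 * p, 1))
  c(prevalence = pct(report@prevalence),
    sensitivity = pct(report@sensitivity),
    specificity = pct(report@specificity),
    ppv = pct(report@ppv), npv = pct(report@npv),
    plr = if (is.na(report@plr)) "N/A" else
      sprintf("%.1f", roundHalfUp(report@plr, 1)),
    nlr = if (is.na(report@nlr)) "N/A" else
      sprintf("%.2f", roundHalfUp(report@nlr, 2)))
}

#' Sensitivity/specificity from above-cut-off counts
#'
#' Serum tumor-marker style arithmetic: sensitivity = patients above the
#' cut-off / patients; specificity = 1 - controls above the cut-off /
#' controls. The percent strings are truncated (not rounded) to one
#' decimal, the convention of the source rates (2/32 prints as 6.2%,
#' 155/156 as 99.3%).
#'
#' @param posAbove,posTotal patients above the cut-off and total patients.
#' @param negAbove,negTotal controls above the cut-off and total controls.
#' @return list with `sensitivity`, `specificity` (exact proportions) and
#'   `sensitivityPct`, `specificityPct` (numeric, one truncated decimal).
#' @export
#' @examples
#' markerPanelFromCounts(2, 32, 1, 156)
markerPanelFromCounts <- function(posAbove, posTotal, negAbove, negTotal) {
  if (posTotal <= 0 || negTotal <= 0) stop("totals must be positive")
  if (posAbove > posTotal || negAbove > negTotal)
    stop("counts above the cut-off exceed the totals")
  se <- posAbove / posTotal
  sp <- 1 - negAbove / negTotal
  list(sensitivity = se, specificity = sp,
       sensitivityPct = truncDecimals(100 * se, 1),
       specificityPct = truncDecimals(100 * sp, 1))
}

#' ROC curve and area under the curve
#'
#' Curve over all distinct score thresholds with trapezoidal AUC, equal to
#' the normalized Mann-Whitney U statistic (ties counted 1/2): the
#' probability that a random case scores above a random control. Higher
#' scores are treated as more case-like.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return a [RocCurve-class].
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present for a ROC curve")
  r <- pROC::roc(response = factor(labels, levels = c(0, 1)),
                 predictor = as.numeric(scores),
                 direction = "<", quiet = TRUE)
  o <- order(1 - r$specificities, r$sensitivities)
  new("RocCurve", thresholds = r$thresholds[o],
      fpr = (1 - r$specificities)[o], tpr = r$sensitivities[o],
      auc = as.numeric(r$auc))
}

#' Oriented per-metabolite ROC ranking
#'
#' Computes each metabolite's AUC with the orientation chosen so that
#' AUC >= 0.5, records whether the metabolite is increased or decreased in
#' cases (raw AUC below 0.5 means cases score lower, i.e. decreased), and
#' sorts descending by oriented AUC.
#'
#' @param levels numeric matrix, samples x metabolites.
#' @param labels 0/1 class labels.
#' @return data.frame with `metabolite`, `auc` (oriented), `rawAuc`,
#'   `direction`, sorted by decreasing `auc`.
#' @export
multiRocRanking <- function(levels, labels) {
  levels <- as.matrix(levels)
  nm <- colnames(levels)
  if (is.null(nm)) nm <- paste0("M", seq_len(ncol(levels)))
  raw <- vapply(seq_len(ncol(levels)),
                function(j) rocCurve(levels[, j], labels)@auc, numeric(1))
  oriented <- pmax(raw, 1 - raw)
  out <- data.frame(metabolite = nm, auc = oriented, rawAuc = raw,
                    direction = ifelse(raw >= 0.5, "increased", "decreased"))
  out <- out[order(-out$auc), ]
  rownames(out) <- NULL
  out
}

#' Per-sample metabolite levels by signature-window integration
#'
#' Transparent replacement for database fitting: each metabolite's level is
#' the summed reference-normalized intensity over windows of +/- `window`
#' ppm around each of its signature peaks. Spectra are TSP-normalized
#' first (idempotent if already normalized).
#'
#' @param x a [SpectrumSet-class].
#' @param library signature library, default [signatureLibrary()].
#' @param window half-width of each integration window in ppm
#'   (default 0.02).
#' @param normalize normalize to the reference first (default TRUE).
#' @return numeric matrix, samples x metabolites.
#' @export
metaboliteLevels <- function(x, library = signatureLibrary(), window = 0.02,
                             normalize = TRUE) {
  if (normalize) x <- normalizeToReference(x)
  ppm <- specPpm(x)
  ints <- intensities(x)
  out <- vapply(library, function(s) {
    keep <- rep(FALSE, length(ppm))
    for (p0 in s@peaks$ppm) {
      if (p0 - window < min(ppm) - 1e-9 || p0 + window > max(ppm) + 1e-9)
        stop("integration window around ", p0,
             " ppm falls outside the axis")
      keep <- keep | (ppm >= p0 - window & ppm <= p0 + window)
    }
    colSums(ints[keep, , drop = FALSE])
  }, numeric(ncol(ints)))
  if (is.null(dim(out)))  # single-sample set: vapply returns a bare vector
    out <- matrix(out, nrow = 1, dimnames = list(NULL, names(out)))
  rownames(out) <- colnames(x)
  out
}
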