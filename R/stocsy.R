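# Statistical total correlation spectroscopy (STOCSY) and univariate
# group-difference testing.

#' Run STOCSY against a driver variable
#'
#' Correlates a driver (by default the OPLS-DA predictive score; any bin
#' gives classical STOCSY) with every spectral bin: per-bin Pearson
#' correlation and covariance (denominator n - 1). The usual display plots
#' the covariance profile colored by correlation; both vectors are returned
#' for export. Constant bins get correlation 0 by convention and are
#' flagged in `@constantBins`.
#'
#' @param x numeric feature matrix (samples x bins) or a
#'   [BinnedSpectra-class].
#' @param driver numeric vector, one value per sample; must not be constant.
#' @return a [StocsyResult-class].
#' @export
runStocsy <- function(x, driver) {
  centers <- NULL
  if (is(x, "BinnedSpectra")) {
    centers <- binCenters(x)
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  driver <- as.numeric(driver)
  if (length(driver) != nrow(x))
    stop("driver length (", length(driver),
         ") must equal the sample count (", nrow(x), ")")
  if (stats::sd(driver) == 0) stop("driver is constant")
  if (is.null(centers)) {
    centers <- if (is.null(colnames(x))) rep(NA_real_, ncol(x)) else
      suppressWarnings(as.numeric(colnames(x)))
    if (anyNA(centers)) centers <- as.numeric(seq_len(ncol(x)))
  }
  cv <- drop(stats::cov(driver, x))
  cr <- drop(suppressWarnings(stats::cor(driver, x)))
  constant <- which(is.na(cr))
  cr[constant] <- 0
  new("StocsyResult", corr = unname(cr), cov = unname(cv),
      binCenters = centers, annotations = data.frame(),
      constantBins = as.integer(constant))
}

#' Annotate high-correlation STOCSY bins with library metabolites
#'
#' Bins whose absolute correlation reaches `rThreshold` are matched to any
#' signature with a peak within `ppmTol` of the bin center; unmatched
#' high-correlation bins are reported as `"unassigned"`. The default
#' tolerance of 0.02 ppm spans about two 0.0092-ppm bins plus lineshape
#' spread.
#'
#' @param result a [StocsyResult-class].
#' @param library signature library (non-empty list of
#'   [MetaboliteSignature-class]).
#' @param rThreshold absolute-correlation threshold (default 0.6).
#' @param ppmTol match tolerance in ppm (default 0.02).
#' @return data.frame with columns `metabolite`, `binCenter`, `corr`,
#'   `cov`; zero rows when no bin passes the threshold.
#' @export
annotatePeaks <- function(result, library, rThreshold = 0.6, ppmTol = 0.02) {
  if (length(library) == 0L) stop("signature library is empty")
  hits <- which(abs(result@corr) >= rThreshold)
  out <- data.frame(metabolite = character(0), binCenter = numeric(0),
                    corr = numeric(0), cov = numeric(0))
  for (i in hits) {
    bc <- result@binCenters[i]
    matched <- character(0)
    for (s in library) {
      if (any(abs(s@peaks$ppm - bc) <= ppmTol))
        matched <- c(matched, s@name)
    }
    if (!length(matched)) matched <- "unassigned"
    out <- rbind(out, data.frame(metabolite = matched, binCenter = bc,
                                 corr = result@corr[i], cov = result@cov[i]))
  }
  rownames(out) <- NULL
  out
}

#' Summarize annotations per metabolite with a direction call
#'
#' Aggregates [annotatePeaks()] output: per metabolite, the number of
#' matched bins and the direction implied by the sign of the mean
#' correlation with the driver (`"increased"` when the mean is positive —
#' with the predictive score as driver this means higher in cases).
#'
#' @param annotations data.frame from [annotatePeaks()].
#' @return data.frame with `metabolite`, `nBins`, `meanCorr`, `direction`.
#' @export
markerDirections <- function(annotations) {
  if (!nrow(annotations))
    return(data.frame(metabolite = character(0), nBins = integer(0),
                      meanCorr = numeric(0), direction = character(0)))
  sp <- split(annotations, annotations$metabolite)
  out <- do.call(rbind, lapply(sp, function(d) {
    mc <- mean(d$corr)
    data.frame(metabolite = d$metabolite[1], nBins = nrow(d), meanCorr = mc,
               direction = ifelse(mc > 0, "increased", "decreased"))
  }))
  rownames(out) <- NULL
  out
}

#' Rank-sum group-difference test per metabolite
#'
#' Two-sided Wilcoxon rank-sum test of each metabolite level between
#' cases and controls, with the direction read from the group medians.
#'
#' @param levels numeric matrix, samples x metabolites (see
#'   [metaboliteLevels()]).
#' @param labels 0/1 class labels.
#' @return data.frame with `metabolite`, `p`, `direction`
#'   (`"increased"`/`"decreased"`/`"unchanged"` in cases).
#' @export
groupDifferenceTest <- function(levels, labels) {
  levels <- as.matrix(levels)
  labels <- as.numeric(labels)
  if (sum(labels == 0) < 2L || sum(labels == 1) < 2L)
    stop("each group needs at least two samples")
  nm <- colnames(levels)
  if (is.null(nm)) nm <- paste0("M", seq_len(ncol(levels)))
  res <- lapply(seq_len(ncol(levels)), function(j) {
    x1 <- levels[labels == 1, j]
    x0 <- levels[labels == 0, j]
    p <- stats::wilcox.test(x1, x0, alternative = "two.sided")$p.value
    d <- stats::median(x1) - stats::median(x0)
    data.frame(metabolite = nm[j], p = p,
               direction = if (d > 0) "increased" else if (d < 0)
                 "decreased" else "unchanged")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export a STOCSY result as CSV
#'
#' @param result a [StocsyResult-class].
#' @param file output CSV path (`bin_center`, `cov`, `corr`).
#' @return invisibly, `file`.
#' @export
writeStocsyCsv <- function(result, file) {
  utils::write.csv(data.frame(bin_center = result@binCenters,
                              cov = result@cov, corr = result@corr),
                   file, row.names = FALSE)
  invisible(file)
}
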