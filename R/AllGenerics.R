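# Accessor generics. Slot access from user code goes through these.

#' Chemical-shift axis of a SpectrumSet
#' @param x a [SpectrumSet-class].
#' @return numeric ppm axis.
#' @export
setGeneric("specPpm", function(x) standardGeneric("specPpm"))

#' @rdname specPpm
setMethod("specPpm", "SpectrumSet", function(x) rowData(x)$ppm)

#' Intensity matrix (axis points x samples)
#' @param x a [SpectrumSet-class].
#' @return numeric matrix.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname intensities
setMethod("intensities", "SpectrumSet", function(x) assay(x, "intensity"))

#' Class labels (0 = control, 1 = case)
#' @param x a [SpectrumSet-class] or [BinnedSpectra-class].
#' @return numeric vector or NULL when unlabeled.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname classLabels
setMethod("classLabels", "SummarizedExperiment",
          function(x) colData(x)$label)

#' Bin centers of a BinnedSpectra object (descending ppm)
#' @param x a [BinnedSpectra-class].
#' @return numeric vector of bin centers (ppm).
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname binCenters
setMethod("binCenters", "BinnedSpectra", function(x) rowData(x)$center)

#' Bin edges of a BinnedSpectra object
#' @param x a [BinnedSpectra-class].
#' @return data.frame with columns `left` and `right` (ppm).
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname binEdges
setMethod("binEdges", "BinnedSpectra", function(x)
  data.frame(left = rowData(x)$left, right = rowData(x)$right))

#' Feature matrix in modeling orientation (samples x bins)
#'
#' Transpose of the `"binned"` assay: one row per sample, one column per
#' retained bin, columns ordered by descending bin-center ppm and named by
#' bin center.
#'
#' @param x a [BinnedSpectra-class].
#' @return numeric matrix, samples x bins.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
setMethod("featureMatrix", "BinnedSpectra", function(x) {
  m <- t(assay(x, "binned"))
  colnames(m) <- format(rowData(x)$center, trim = TRUE)
  m
})
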