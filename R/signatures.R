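#' Built-in urinary metabolite signature library
#'
#' The eleven urinary metabolites that discriminate colorectal neoplasia
#' from healthy controls, each with its proton chemical shifts and
#' multiplicities and its case-vs-control direction: 3-aminoisobutyrate,
#' alanine, taurine, urea and valine increase in cases; ascorbate, citrate,
#' creatinine, glycerol, hippurate and threonine decrease.
#'
#' Relative peak intensities are approximate relative proton weights and the
#' baseline concentrations are plausible urinary levels in arbitrary units
#' (creatinine dominant, urea and citrate high, branched amino acids low);
#' neither is a measured quantity — they set the scale of the simulator.
#'
#' @return named list of [MetaboliteSignature-class] objects (length 11).
#' @export
#' @examples
#' lib <- signatureLibrary()
#' names(lib)
#' lib$taurine
signatureLibrary <- function() {
  sig <- function(name, ppm, mult, rel, direction, base) {
    metaboliteSignature(name,
      data.frame(ppm = ppm, multiplicity = mult, relIntensity = rel),
      direction = direction, baseConc = base)
  }
  lst <- list(
    sig("3-aminoisobutyrate", 1.18, "d", 3, "up", 0.8),
    sig("alanine",            1.48, "d", 3, "up", 1.5),
    sig("ascorbate",          c(3.75, 4.53), c("m", "m"), c(2, 1),
        "down", 1.0),
    sig("citrate",            c(2.54, 2.71), c("d", "d"), c(2, 2),
        "down", 4.0),
    sig("creatinine",         c(3.05, 4.07), c("s", "s"), c(3, 2),
        "down", 10.0),
    sig("glycerol",           c(3.58, 3.66, 3.78), c("m", "m", "m"),
        c(2, 2, 1), "down", 1.0),
    sig("hippurate",          c(3.98, 7.56, 7.64, 7.83),
        c("d", "t", "t", "m"), c(2, 2, 1, 2), "down", 3.0),
    sig("taurine",            c(3.27, 3.45), c("t", "t"), c(2, 2),
        "up", 2.0),
    sig("threonine",          c(1.31, 3.58), c("d", "d"), c(3, 1),
        "down", 1.0),
    sig("urea",               5.80, "s", 2, "up", 8.0),
    sig("valine",             0.99, "d", 3, "up", 0.5))
  names(lst) <- vapply(lst, function(s) s@name, character(1))
  lst
}

#' Baseline (control-group mean) concentrations of a signature library
#'
#' @param library a list of [MetaboliteSignature-class] objects.
#' @return named numeric vector of baseline concentrations.
#' @export
baseConcentrations <- function(library) {
  vapply(library, function(s) s@baseConc, numeric(1))
}

#' Case/control directions of a signature library
#'
#' @param library a list of [MetaboliteSignature-class] objects.
#' @return named character vector (`"up"`, `"down"`, `"flat"`).
#' @export
signatureDirections <- function(library) {
  vapply(library, function(s) s@direction, character(1))
}
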