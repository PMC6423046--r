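# Synthetic urine 1H-NMR cohort simulation.

#' Render a first-order multiplet as a line list
#'
#' Splits one resonance into its first-order multiplet lines. With
#' J-coupling `J` Hz on a `F` MHz spectrometer the splitting is `J / F` ppm:
#' a singlet is one line at the center; a doublet two lines at center
#' +/- J/(2F) with weights 1/2, 1/2; a triplet three lines spaced J/F with
#' weights 1/4, 1/2, 1/4; an unresolved multiplet is approximated as a
#' binomial quintet (five lines spaced J/F, weights 1,4,6,4,1 over 16).
#' Line weights sum to 1 before scaling by `relIntensity`.
#'
#' @param centerPpm multiplet center (ppm).
#' @param multiplicity `"s"`, `"d"`, `"t"` or `"m"`.
#' @param relIntensity total intensity of the multiplet (> 0).
#' @param config a [SimConfig-class] supplying `jHz` and `fieldMHz`.
#' @return data.frame with columns `ppm` and `weight`.
#' @export
#' @examples
#' renderMultiplet(1.18, "d", 1, simConfig())  # lines at 1.18 +/- 0.007
renderMultiplet <- function(centerPpm, multiplicity, relIntensity = 1,
                            config = simConfig()) {
  j <- config@jHz / config@fieldMHz
  pat <- switch(multiplicity,
    s = list(off = 0, w = 1),
    d = list(off = c(-j / 2, j / 2), w = c(1, 1) / 2),
    t = list(off = c(-j, 0, j), w = c(1, 2, 1) / 4),
    m = list(off = (-2:2) * j, w = c(1, 4, 6, 4, 1) / 16),
    stop("unknown multiplicity code '", multiplicity,
         "' (expected one of s, d, t, m)"))
  data.frame(ppm = centerPpm + pat$off, weight = pat$w * relIntensity)
}

# line list for a whole signature (all peaks expanded into multiplet lines)
signatureLines <- function(signature, config) {
  pk <- signature@peaks
  do.call(rbind, lapply(seq_len(nrow(pk)), function(i)
    renderMultiplet(pk$ppm[i], pk$multiplicity[i], pk$relIntensity[i],
                    config)))
}

ppmAxis <- function(config) {
  seq(config@ppmMin, config@ppmMax, length.out = config@nPoints)
}

# Lorentzian basis: nPoints x nLines, unit peak height per line
lorentzianBasis <- function(linePpm, config) {
  ppm <- ppmAxis(config)
  hw <- config@linewidthHz / config@fieldMHz   # half-width in ppm
  vapply(linePpm, function(c0) hw^2 / ((ppm - c0)^2 + hw^2),
         numeric(config@nPoints))
}

waterHump <- function(config, waterCenter = 4.9, waterSd = 0.12) {
  ppm <- ppmAxis(config)
  config@waterAmplitude * exp(-(ppm - waterCenter)^2 / (2 * waterSd^2))
}

# line table for a library: one row per Lorentzian line, with the metabolite
# it belongs to; the TSP reference singlet at 0.00 ppm is appended last
libraryLineTable <- function(library, config) {
  tab <- do.call(rbind, lapply(library, function(s) {
    ln <- signatureLines(s, config)
    data.frame(metabolite = s@name, ppm = ln$ppm, weight = ln$weight)
  }))
  rownames(tab) <- NULL
  rbind(tab, data.frame(metabolite = ".tsp", ppm = 0, weight = 1))
}

#' Simulate a single urine 1H-NMR spectrum
#'
#' Sums Lorentzian multiplet lines (concentration x line weight, unit peak
#' height per line), the TSP reference singlet at 0.00 ppm at the fixed
#' reference concentration `config@tspConc`, a broad residual-water Gaussian
#' at 4.9 ppm, and additive white noise. Deterministic for a given
#' `config@seed`.
#'
#' @param concentrations named non-negative numeric vector; names must be
#'   metabolites of `library`. Omitted metabolites are absent (0).
#' @param config a [SimConfig-class].
#' @param library signature library, default [signatureLibrary()].
#' @return a one-sample [SpectrumSet-class].
#' @export
#' @examples
#' sp <- simulateSpectrum(c(taurine = 2), simConfig(nPoints = 2048, seed = 1))
simulateSpectrum <- function(concentrations, config = simConfig(),
                             library = signatureLibrary()) {
  if (length(concentrations) && is.null(names(concentrations)))
    stop("'concentrations' must be a named vector")
  if (any(concentrations < 0))
    stop("negative concentration for: ",
         paste(names(concentrations)[concentrations < 0], collapse = ", "))
  unknown <- setdiff(names(concentrations), names(library))
  if (length(unknown))
    stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
  withSeed(config@seed, {
    tab <- libraryLineTable(library[names(library) %in%
                                      names(concentrations)], config)
    conc <- c(concentrations, .tsp = config@tspConc)
    amp <- tab$weight * conc[tab$metabolite]
    basis <- lorentzianBasis(tab$ppm, config)
    y <- as.numeric(basis %*% amp) + waterHump(config)
    if (config@noiseSd > 0)
      y <- y + stats::rnorm(config@nPoints, 0, config@noiseSd)
    SpectrumSet(ppmAxis(config), matrix(y, ncol = 1,
                                        dimnames = list(NULL, "S1")))
  })
}

#' Simulate a labeled case/control cohort of urine spectra
#'
#' Control-group concentration means are the library baselines; case means
#' are multiplied by `foldChange` for `up` signatures and divided by it for
#' `down` ones (`flat` unchanged). Per-subject concentrations are log-normal
#' around the group mean with coefficient of variation `withinGroupCv`, and a
#' per-subject log-normal dilution factor (sd `config@dilutionLogSd` on the
#' log scale) scales every metabolite but NOT the TSP reference — so
#' reference normalization is genuinely exercised downstream. The
#' residual-water hump is class-independent. Deterministic for a given
#' `config@seed`.
#'
#' @param design a [CohortDesign-class].
#' @param config a [SimConfig-class].
#' @param library signature library, default [signatureLibrary()].
#' @return a [SpectrumSet-class] with `colData` columns `label`
#'   (0 = control, 1 = case) and `dilution` (the applied factor).
#' @export
#' @examples
#' ss <- simulateCohort(cohortDesign(5, 5), simConfig(nPoints = 2048, seed = 7))
#' table(classLabels(ss))
simulateCohort <- function(design, config = simConfig(),
                           library = signatureLibrary()) {
  validObject(design)
  validObject(config)
  withSeed(config@seed, {
    nTot <- design@nControl + design@nCase
    labels <- rep(c(0, 1), c(design@nControl, design@nCase))
    base <- baseConcentrations(library)
    dirs <- signatureDirections(library)
    caseMean <- base *
      ifelse(dirs == "up", design@foldChange,
             ifelse(dirs == "down", 1 / design@foldChange, 1))
    meanMat <- rbind(control = base, case = caseMean)

    sdlog <- sqrt(log(1 + design@withinGroupCv^2))
    # per-subject concentrations: nMet x nSamples
    conc <- vapply(seq_len(nTot), function(i) {
      mu <- meanMat[labels[i] + 1L, ]
      mu * exp(stats::rnorm(length(mu), 0, sdlog))
    }, numeric(length(base)))
    dilution <- exp(stats::rnorm(nTot, 0, config@dilutionLogSd))

    tab <- libraryLineTable(library, config)
    concFull <- rbind(sweep(conc, 2, dilution, `*`),
                      .tsp = rep(config@tspConc, nTot))
    rownames(concFull) <- c(names(base), ".tsp")
    amps <- concFull[tab$metabolite, , drop = FALSE] * tab$weight
    basis <- lorentzianBasis(tab$ppm, config)
    ints <- basis %*% amps + waterHump(config)
    if (config@noiseSd > 0)
      ints <- ints + matrix(stats::rnorm(length(ints), 0, config@noiseSd),
                            nrow = nrow(ints))
    ids <- c(sprintf("ctrl_%03d", seq_len(design@nControl)),
             sprintf("case_%03d", seq_len(design@nCase)))
    out <- SpectrumSet(ppmAxis(config), ints, labels = labels,
                       sampleIds = ids)
    colData(out)$dilution <- dilution
    out
  })
}

#' Write / read spectra as wide CSV
#'
#' Wide layout: first column `ppm`, one intensity column per sample. A
#' companion labels CSV (`sample_id`, `label`) is written when labels are
#' present, and a YAML metadata sidecar records the seed when a config is
#' given.
#'
#' @param x a [SpectrumSet-class].
#' @param file output CSV path.
#' @param labelsFile optional labels CSV path (default `<file>_labels.csv`
#'   next to `file` when labels exist).
#' @param config optional [SimConfig-class]; when given, a
#'   `<file>_meta.yaml` sidecar with the simulation parameters is written.
#' @return invisibly, the main file path.
#' @export
writeSpectraCsv <- function(x, file, labelsFile = NULL, config = NULL) {
  df <- data.frame(ppm = specPpm(x), intensities(x), check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  lab <- classLabels(x)
  if (!is.null(lab)) {
    if (is.null(labelsFile))
      labelsFile <- sub("\\.csv$", "_labels.csv", file)
    utils::write.csv(data.frame(sample_id = colnames(x), label = lab),
                     labelsFile, row.names = FALSE)
  }
  if (!is.null(config)) {
    meta <- list(ppm_min = config@ppmMin, ppm_max = config@ppmMax,
                 n_points = config@nPoints, field_MHz = config@fieldMHz,
                 linewidth_hz = config@linewidthHz, j_hz = config@jHz,
                 noise_sd = config@noiseSd,
                 dilution_log_sd = config@dilutionLogSd,
                 water_amplitude = config@waterAmplitude,
                 tsp_conc = config@tspConc, seed = config@seed)
    yaml::write_yaml(meta, sub("\\.csv$", "_meta.yaml", file))
  }
  invisible(file)
}

#' @rdname writeSpectraCsv
#' @param labels optional numeric label vector overriding `labelsFile`.
#' @export
readSpectraCsv <- function(file, labelsFile = NULL, labels = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (is.null(labels)) {
    if (is.null(labelsFile)) {
      cand <- sub("\\.csv$", "_labels.csv", file)
      if (file.exists(cand)) labelsFile <- cand
    }
    if (!is.null(labelsFile)) {
      ldf <- utils::read.csv(labelsFile)
      labels <- ldf$label[match(colnames(df)[-1], ldf$sample_id)]
    }
  }
  SpectrumSet(df[[1]], as.matrix(df[, -1, drop = FALSE]), labels = labels)
}
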