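# OPLS-DA: single-y NIPALS with sequential orthogonal signal deflation,
# cross-validated Q2, class cut-off prediction and stratified holdout
# validation.

unitNorm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate (zero-norm) weight vector; the matrix ",
                      "rank is too low for the requested components")
  v / n
}

#' Fit an OPLS-DA model
#'
#' Single-response orthogonal projections to latent structures, NIPALS
#' style. For each of `nOrth` rounds on the current matrix `X`: the
#' predictive weight `w` is the unit-normalized `X'y`; `t = Xw`;
#' `p = X't / t't`; the orthogonal weight is the part of `p` orthogonal to
#' `w` (unit-normalized), giving orthogonal scores/loadings `t_o`, `p_o`;
#' then `X` is deflated by `t_o p_o'`. After the last round the predictive
#' component (`w`, `t_p`, `p_p`, `q = y't_p / t_p't_p`) is taken from the
#' deflated matrix. `y` is centered internally (the mean is stored), so 0/1
#' class encoding keeps the 0.5 cut-off meaningful on the prediction scale.
#'
#' @param X numeric matrix (samples x variables), already centered/scaled
#'   (see [paretoScale()]).
#' @param y numeric response; for discriminant use, 0 = control, 1 = case.
#'   Must not be constant.
#' @param nOrth number of orthogonal components (default 3).
#' @return an [OplsModel-class] with training scores and `r2y`
#'   (`q2` is NA until [crossValidateQ2()] fills it).
#' @export
fitOpls <- function(X, y, nOrth = 3L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (stats::sd(y) == 0) stop("y is constant; a class model needs both classes")
  nOrth <- as.integer(nOrth)
  if (nOrth < 0L) stop("nOrth must be >= 0")
  if (nOrth > 0L && nOrth >= qr(X)$rank)
    stop("nOrth (", nOrth, ") must be smaller than rank(X)")
  yMean <- mean(y)
  yc <- y - yMean
  Xd <- X
  p <- ncol(X)
  Wo <- matrix(0, p, 0)
  Po <- matrix(0, p, 0)
  To <- matrix(0, nrow(X), 0)
  for (k in seq_len(nOrth)) {
    w <- unitNorm(drop(crossprod(Xd, yc)))
    t <- drop(Xd %*% w)
    pl <- drop(crossprod(Xd, t)) / sum(t * t)
    wo <- pl - sum(w * pl) * w
    wo <- unitNorm(wo)
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to * to)
    Xd <- Xd - tcrossprod(to, po)
    Wo <- cbind(Wo, wo)
    Po <- cbind(Po, po)
    To <- cbind(To, to)
  }
  dimnames(Wo) <- dimnames(Po) <- dimnames(To) <- NULL
  w <- unitNorm(drop(crossprod(Xd, yc)))
  tP <- drop(Xd %*% w)
  pP <- drop(crossprod(Xd, tP)) / sum(tP * tP)
  q <- sum(yc * tP) / sum(tP * tP)
  yHat <- q * tP + yMean
  r2y <- 1 - sum((y - yHat)^2) / sum(yc^2)
  new("OplsModel", w = w, pP = pP, tP = tP, q = q,
      Wo = Wo, Po = Po, To = To, nOrth = nOrth, yMean = yMean,
      r2y = r2y, q2 = NA_real_, scaling = NULL)
}

#' Predict from an OPLS-DA model
#'
#' Removes the stored orthogonal variation sequentially (`t_o = X w_o`;
#' `X <- X - t_o p_o'` per component), then projects onto the predictive
#' weight and un-centers: `yHat = q * tP + yMean`.
#'
#' @param object an [OplsModel-class].
#' @param newdata numeric matrix (samples x variables) scaled with the
#'   TRAINING parameters (see [applyScaling()]).
#' @param ... ignored.
#' @return list with `yHat`, predictive scores `tP`, and orthogonal scores
#'   `To` (samples x nOrth).
#' @export
setMethod("predict", "OplsModel", function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != length(object@w))
    stop("newdata has ", ncol(Xn), " columns; the model was trained on ",
         length(object@w))
  To <- matrix(0, nrow(Xn), object@nOrth)
  for (k in seq_len(object@nOrth)) {
    to <- drop(Xn %*% object@Wo[, k])
    Xn <- Xn - tcrossprod(to, object@Po[, k])
    To[, k] <- to
  }
  tP <- drop(Xn %*% object@w)
  list(yHat = object@q * tP + object@yMean, tP = tP, To = To)
})

#' Classify continuous predictions at a cut-off
#'
#' An a priori cut-off of 0.5 on the 0/1 prediction scale; a value exactly
#' at the cut-off is classified as case (documented tie-break).
#'
#' @param yHat numeric predictions.
#' @param cutoff decision threshold (default 0.5).
#' @return integer vector of 0/1 labels.
#' @export
#' @examples
#' classifyScores(c(0.49, 0.5, 0.51))
classifyScores <- function(yHat, cutoff = 0.5) {
  as.integer(yHat >= cutoff)
}

stratifiedFolds <- function(y, nFolds, maxAttempts = 10L) {
  classes <- unique(y)
  for (attempt in seq_len(maxAttempts)) {
    fold <- integer(length(y))
    for (cl in classes) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    # every fold must leave both classes in the training part; heldout
    # folds missing a class (or empty) are tolerated only when a class is
    # smaller than the fold count
    ok <- vapply(seq_len(nFolds), function(f)
      length(unique(y[fold != f])) == length(classes), logical(1))
    both <- vapply(seq_len(nFolds), function(f)
      length(unique(y[fold == f])) == length(classes), logical(1))
    feasible <- all(table(y) >= nFolds)
    if (all(ok) && (!feasible || all(both))) return(fold)
    if (feasible && !all(both))
      warning("a fold lacked both classes; refolding (attempt ",
              attempt, ")")
  }
  stop("could not build class-balanced folds in ", maxAttempts, " attempts")
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Q2 = 1 - PRESS/SS with PRESS the sum over folds of the squared held-out
#' prediction errors and SS the total centered sum of squares of `y`. Folds
#' are stratified by class and the assignment is seeded. Can be negative;
#' never exceeds 1.
#'
#' @inheritParams fitOpls
#' @param nFolds number of cross-validation folds (default 7).
#' @param seed RNG seed for the fold assignment (NULL = current RNG state).
#' @return numeric Q2.
#' @export
crossValidateQ2 <- function(X, y, nOrth = 3L, nFolds = 7L, seed = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nFolds < 2L) stop("nFolds must be >= 2")
  withSeed(seed, {
    fold <- stratifiedFolds(y, nFolds)
    press <- 0
    for (f in seq_len(nFolds)) {
      if (!any(fold == f)) next
      tr <- fold != f
      m <- fitOpls(X[tr, , drop = FALSE], y[tr], nOrth = nOrth)
      pr <- predict(m, X[!tr, , drop = FALSE])
      press <- press + sum((y[!tr] - pr$yHat)^2)
    }
    1 - press / sum((y - mean(y))^2)
  })
}

#' Stratified holdout split indices
#'
#' Per class, `floor(n * fraction)` samples go to the holdout (blinded) set;
#' the rest form the training set. A 1/3 split of 156 controls + 92 cases
#' yields 52 + 30 blinded and 104 + 62 training samples.
#'
#' @param y 0/1 class labels.
#' @param fraction holdout fraction (default 1/3).
#' @param seed RNG seed for the within-class sampling.
#' @return list with integer index vectors `train` and `holdout`.
#' @export
stratifiedHoldoutSplit <- function(y, fraction = 1 / 3, seed = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  withSeed(seed, {
    holdout <- integer(0)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      nh <- floor(length(idx) * fraction)
      if (nh < 1L || nh >= length(idx))
        stop("class ", cl, " is too small to split at fraction ", fraction)
      holdout <- c(holdout, sample(idx, nh))
    }
    holdout <- sort(holdout)
    list(train = setdiff(seq_along(y), holdout), holdout = holdout)
  })
}

#' Holdout validation of the OPLS-DA class prediction
#'
#' Blinds a stratified per-class fraction of the samples, fits scaling
#' ([paretoScale()]) and the OPLS-DA model on the remaining training
#' samples only, scores the blinded samples with the training scaling, and
#' classifies at the cut-off.
#'
#' @param X numeric feature matrix (samples x bins), UNSCALED, or a
#'   [BinnedSpectra-class].
#' @param y 0/1 class labels.
#' @param holdoutFraction blinded fraction per class (default 1/3).
#' @param nOrth orthogonal components (default 3).
#' @param nFolds folds for the training-set Q2 (default 7).
#' @param cutoff class cut-off (default 0.5).
#' @param seed RNG seed (drives split and Q2 folds).
#' @return list with `model` ([OplsModel-class], `q2` filled in),
#'   `confusion` ([ConfusionCounts-class]) on the blinded samples, `report`
#'   ([DiagnosticReport-class]), `split` (train/holdout indices), `yHat`
#'   (holdout predictions) and `scaling`.
#' @export
holdoutValidate <- function(X, y, holdoutFraction = 1 / 3, nOrth = 3L,
                            nFolds = 7L, cutoff = 0.5, seed = NULL) {
  if (is(X, "BinnedSpectra")) {
    if (is.null(y)) y <- classLabels(X)
    X <- featureMatrix(X)
  }
  y <- as.numeric(y)
  withSeed(seed, {
    split <- stratifiedHoldoutSplit(y, holdoutFraction)
    sc <- paretoScale(X[split$train, , drop = FALSE])
    model <- fitOpls(sc$scaled, y[split$train], nOrth = nOrth)
    model@q2 <- crossValidateQ2(sc$scaled, y[split$train], nOrth = nOrth,
                                nFolds = nFolds)
    model@scaling <- sc$params
    Xh <- applyScaling(X[split$holdout, , drop = FALSE], sc$params)
    pr <- predict(model, Xh)
    pred <- classifyScores(pr$yHat, cutoff)
    conf <- confusionCounts(y[split$holdout], pred)
    list(model = model, confusion = conf, report = accuracyPanel(conf),
         split = split, yHat = pr$yHat, scaling = sc$params)
  })
}

#' Score-plot table (predictive vs first orthogonal score)
#'
#' @param model an [OplsModel-class].
#' @param labels optional 0/1 labels for the training samples.
#' @return data.frame with `tP`, `to1` (NA when `nOrth` = 0) and `label`.
#' @export
scorePlotTable <- function(model, labels = NULL) {
  data.frame(tP = model@tP,
             to1 = if (model@nOrth > 0) model@To[, 1] else NA_real_,
             label = if (is.null(labels)) NA_real_ else as.numeric(labels))
}

#' Serialize an OPLS model to JSON
#'
#' @param model an [OplsModel-class].
#' @param file output path.
#' @param provenance optional named list (seed, fold scheme, ...) stored
#'   alongside the model.
#' @return invisibly, `file`.
#' @export
writeOplsModelJson <- function(model, file, provenance = list()) {
  obj <- list(w = model@w, pP = model@pP, tP = model@tP, q = model@q,
              Wo = model@Wo, Po = model@Po, To = model@To,
              nOrth = model@nOrth, yMean = model@yMean,
              r2y = model@r2y, q2 = model@q2, provenance = provenance)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}
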