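# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic half-up rounding (0.05 -> 0.1 at one digit), the convention
#' used when formatting diagnostic-accuracy percentages. Base `round()` uses
#' banker's rounding, which maps 0.45 to 0.4.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(93.75, 1)  # 93.8
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  # pre-round at 9 digits to absorb binary representation error before the
  # floor; e.g. 0.285 stored as 0.28499999... must still round up
  sign(x) * floor(round(abs(x) * m, 9) + 0.5) / m
}

# truncate (toward zero) at `digits` decimals; used where a source table was
# evidently truncated rather than rounded
truncDecimals <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(round(abs(x) * m, 9)) / m
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL or NA leaves the RNG untouched.
withSeed <- function(seed, expr) {
  if (!is.null(seed) && length(seed) == 1L && !is.na(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# trapezoidal integral of y over the subset of x inside [window[1], window[2]]
windowIntegral <- function(x, y, window) {
  keep <- x >= window[1] & x <= window[2]
  if (sum(keep) < 2L) {
    stop("window [", window[1], ", ", window[2],
         "] covers fewer than two axis points")
  }
  pracma::trapz(x[keep], y[keep])
}

stopifnotScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number")
  }
  invisible(x)
}
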