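#' Frequency band specification
#'
#' A named frequency interval used for band-pass filtering, relative power
#' and band-limited connectivity. Band edges are half-open `[lo, hi)` so that
#' adjacent bands never share a spectral bin.
#'
#' @param name band label, e.g. `"theta"`.
#' @param lo lower edge in Hz (inclusive); must be positive.
#' @param hi upper edge in Hz (exclusive); must exceed `lo`.
#'
#' @return An object of class `band_spec`: a list with elements `name`,
#'   `lo`, `hi`.
#' @examples
#' theta <- band_spec("theta", 4, 8)
#' @export
band_spec <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(lo) || !is.numeric(hi) || !is.finite(lo) || !is.finite(hi))
    stop("band edges must be finite numbers")
  if (lo <= 0 || hi <= lo)
    stop(sprintf("band edges must satisfy 0 < lo < hi; got [%g, %g)", lo, hi))
  structure(list(name = name, lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s [%g, %g) Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Canonical EEG analysis bands
#'
#' The four bands used throughout the workflow: delta `[0.5, 4)`,
#' theta `[4, 8)`, alpha `[8, 13)` and beta `[13, 30)` Hz.
#'
#' @return Named list of [band_spec] objects.
#' @export
default_bands <- function() {
  list(
    delta = band_spec("delta", 0.5, 4),
    theta = band_spec("theta", 4, 8),
    alpha = band_spec("alpha", 8, 13),
    beta  = band_spec("beta", 13, 30)
  )
}
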