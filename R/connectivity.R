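# one-sided spectral weights for the analytic signal: zero the negative
# frequencies, double the positive ones, keep DC (and Nyquist for even n)
analytic_weights <- function(n) {
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

analytic_signal <- function(x) {
  n <- length(x)
  stats::fft(stats::fft(x) * analytic_weights(n), inverse = TRUE) / n
}

# analytic signal of every channel at once; e is channels x samples,
# returns samples x channels (complex)
analytic_matrix <- function(e) {
  x <- t(e)
  n <- nrow(x)
  stats::mvfft(stats::mvfft(x) * analytic_weights(n), inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic signal (Hilbert transform), wrapped to
#' `(-pi, pi]`. The input should already be band-filtered so the analytic
#' phase is interpretable.
#'
#' @param x numeric vector, one channel of one epoch.
#' @param fs sampling rate (Hz).
#' @return Object of class `phase_series`: list with `phases` (radians) and
#'   `fs`.
#' @export
instantaneous_phase <- function(x, fs) {
  if (all(x == 0)) stop("degenerate all-zero signal has no phase")
  z <- analytic_signal(as.numeric(x))
  structure(list(phases = Arg(z), fs = fs), class = "phase_series")
}

#' Unwrap a wrapped phase sequence
#'
#' Removes the 2*pi jumps of a phase time series wrapped to `(-pi, pi]`,
#' giving a continuous phase whose slope is the instantaneous frequency.
#'
#' @param phases numeric vector of wrapped phases (radians).
#' @return unwrapped phases (radians).
#' @export
unwrap_phase <- function(phases) {
  d <- diff(phases)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phases[1], d))
}

#' Phase Lag Index between two phase series
#'
#' `PLI = | mean over samples of sign(sin(delta_phi)) |`, where `delta_phi`
#' is the instantaneous phase difference. `sign(0)` contributes 0, so two
#' identical channels give exactly 0. A PLI of 0 means no coupling, or
#' coupling with a phase difference centred on 0 (mod pi) — the zero-lag
#' pattern volume conduction produces; 1 means perfect locking at a non-zero
#' (mod pi) lag.
#'
#' @param a,b [instantaneous_phase] objects (or plain phase vectors) of equal
#'   length.
#' @return PLI in `[0, 1]`.
#' @export
pli_pair <- function(a, b) {
  pa <- if (inherits(a, "phase_series")) a$phases else as.numeric(a)
  pb <- if (inherits(b, "phase_series")) b$phases else as.numeric(b)
  if (length(pa) != length(pb))
    stop(sprintf("phase series lengths differ: %d vs %d", length(pa), length(pb)))
  abs(mean(sign(sin(pa - pb))))
}

#' PLI connectivity matrix for one epoch
#'
#' Computes the PLI between every pair of channels of one (band-filtered)
#' epoch. The result is symmetric with a zero diagonal, entries in `[0, 1]`.
#'
#' @param rec_band a band-filtered [eeg_recording] (>= 2 channels).
#' @param epoch_index which epoch to use (default 1).
#' @return channels x channels numeric matrix with `band` and `epoch_index`
#'   attributes, dimnames = channel labels.
#' @export
pli_matrix <- function(rec_band, epoch_index = 1L) {
  stopifnot(inherits(rec_band, "eeg_recording"))
  nc <- n_channels(rec_band)
  if (nc < 2L) stop("PLI needs at least 2 channels")
  e <- rec_band$epochs[[epoch_index]]
  z <- analytic_matrix(e)                    # samples x channels
  # sign(sin(phi_i - phi_j)) == sign(Im(z_i conj(z_j))) -- the envelopes are
  # nonnegative, so the cross-term sign needs no phase extraction
  re <- Re(z); im <- Im(z)
  m <- matrix(0, nc, nc, dimnames = list(rec_band$channels, rec_band$channels))
  iu <- which(upper.tri(m), arr.ind = TRUE)  # column-major, matches m[upper.tri]
  d <- im[, iu[, 1], drop = FALSE] * re[, iu[, 2], drop = FALSE] -
    re[, iu[, 1], drop = FALSE] * im[, iu[, 2], drop = FALSE]
  m[upper.tri(m)] <- abs(.colMeans(sign(d), nrow(d), ncol(d)))
  m <- m + t(m)
  attr(m, "band") <- rec_band$band
  attr(m, "epoch_index") <- epoch_index
  m
}

#' Per-epoch PLI matrices for a whole recording
#' @param rec_band a band-filtered [eeg_recording].
#' @return list of PLI matrices, one per epoch.
#' @export
pli_epochs <- function(rec_band) {
  lapply(seq_len(n_epochs(rec_band)), function(k) pli_matrix(rec_band, k))
}

#' Mean total PLI
#'
#' The average of the PLI over all channel pairs (upper triangle), then over
#' epochs — the scalar whole-head connectivity summary.
#'
#' @param mats a single PLI matrix or a list of per-epoch matrices.
#' @return scalar mean total PLI.
#' @export
mean_total_pli <- function(mats) {
  if (is.matrix(mats)) mats <- list(mats)
  if (length(mats) == 0L) stop("need at least one connectivity matrix")
  mean(vapply(mats, function(m) mean(m[upper.tri(m)]), numeric(1)))
}

#' Chance-level PLI for independent channels
#'
#' For two channels with independent uniform phase differences over `t_len`
#' samples, `mean(sign(sin(delta_phi)))` is a mean of `t_len` fair signs, so
#' `E|PLI| = sqrt(2 / (pi * t_len))` by the half-normal limit. Useful as the
#' no-coupling reference level (narrowband filtering reduces the effective
#' sample count below `t_len`, raising the realised level; pass an effective
#' length in that case).
#'
#' @param t_len number of (effectively independent) samples.
#' @return expected PLI magnitude under independence.
#' @export
pli_chance_level <- function(t_len) sqrt(2 / (pi * t_len))
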