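#' Segment a continuous multichannel signal into fixed-length epochs
#'
#' Cuts non-overlapping consecutive epochs from the start of the recording and
#' keeps the first `n_keep` — a deterministic selection rule.
#'
#' @param continuous numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch duration in seconds (default 4).
#' @param n_keep number of epochs to retain; default all that fit.
#' @param ... passed to [eeg_recording] (labels, subject metadata).
#' @return An [eeg_recording] with `n_keep` epochs of `epoch_s * fs` samples.
#' @export
segment <- function(continuous, fs, epoch_s = 4, n_keep = NULL, ...) {
  continuous <- as.matrix(continuous)
  len <- round(epoch_s * fs)
  n_fit <- ncol(continuous) %/% len
  if (is.null(n_keep)) n_keep <- n_fit
  if (n_fit < n_keep)
    stop(sprintf("signal too short: %d epochs of %gs fit, %d requested",
                 n_fit, epoch_s, n_keep))
  epochs <- lapply(seq_len(n_keep), function(k)
    continuous[, ((k - 1L) * len + 1L):(k * len), drop = FALSE])
  eeg_recording(epochs, fs = fs, ...)
}

#' Re-reference every epoch to the instantaneous average of all channels
#'
#' Subtracts, at every sample, the mean across channels, so the referenced
#' data have zero channel-mean at every time point.
#'
#' @param rec an [eeg_recording] with at least two channels.
#' @return The re-referenced [eeg_recording].
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2L)
    stop("average reference needs at least 2 channels")
  rec$epochs <- lapply(rec$epochs, function(e)
    sweep(e, 2L, colMeans(e), "-"))
  rec
}

#' Design a linear-phase Hamming-window band-pass FIR filter
#'
#' Windowed-sinc design via [signal::fir1] with an odd number of taps (even
#' order) so the filter is exactly symmetric and its group delay is an
#' integer number of samples.
#'
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz); `hi` must be below Nyquist.
#' @param trans_hz transition width (Hz) controlling the filter order;
#'   default 2. Attenuation one octave outside the band exceeds 20 dB at the
#'   default for the theta, alpha and beta bands at EEG sampling rates.
#' @return Numeric vector of filter coefficients (class `fir_bandpass`).
#' @export
design_fir_bandpass <- function(fs, lo, hi, trans_hz = 2) {
  if (hi >= fs / 2)
    stop(sprintf("upper band edge %g Hz must be below Nyquist %g Hz", hi, fs / 2))
  if (lo <= 0) stop("lower band edge must be positive")
  # Hamming transition width ~ 3.3 / (order / fs); even order -> odd taps
  ord <- ceiling(3.3 * fs / trans_hz)
  if (ord %% 2L == 1L) ord <- ord + 1L
  w <- c(lo, hi) / (fs / 2)
  b <- signal::fir1(ord, w, type = "pass")
  structure(as.numeric(b), class = "fir_bandpass", fs = fs, lo = lo, hi = hi)
}

# Zero-phase application of a symmetric odd-length FIR: reflection-pad,
# convolve once, compensate the integer group delay (ntaps-1)/2 exactly.
zero_phase_filter <- function(x, b) {
  as.numeric(zero_phase_filter_matrix(matrix(x, nrow = 1L), b))
}

# same, for all channels of one epoch at once; e is channels x samples.
# The linear convolution runs in the frequency domain (overlap-free: one
# zero-padded FFT per epoch), which is exact and much faster than
# time-domain filtering for the filter lengths zero-phase banding needs.
zero_phase_filter_matrix <- function(e, b) {
  x <- t(e)                                  # samples x channels
  n <- nrow(x)
  nt <- length(b)
  delay <- (nt - 1L) %/% 2L
  if (delay > n - 1L)
    stop("signal shorter than the filter delay; widen trans_hz or lengthen epochs")
  left <- 2 * rep(x[1, ], each = delay) - x[seq(delay + 1L, 2L), , drop = FALSE]
  right <- 2 * rep(x[n, ], each = delay) - x[seq(n - 1L, n - delay), , drop = FALSE]
  dim(left) <- dim(right) <- c(delay, ncol(x))
  xi <- rbind(left, x, right)
  nfft <- stats::nextn(nrow(xi) + nt - 1L, 2)
  B <- stats::fft(c(b, numeric(nfft - nt)))
  X <- stats::mvfft(rbind(xi, matrix(0, nfft - nrow(xi), ncol(xi))))
  y <- Re(stats::mvfft(X * B, inverse = TRUE)) / nfft
  # causal convolution index k = sum_j b[j] xi[k-j+1]; sample t of x sits at
  # padded row delay+t, so the delay-compensated output is row 2*delay+t
  out <- t(y[(2L * delay + 1L):(2L * delay + n), , drop = FALSE])
  rownames(out) <- rownames(e)
  out
}

#' Zero-phase band-pass filter an epoched recording
#'
#' Each channel of each epoch is filtered with a symmetric (linear-phase)
#' Hamming windowed-sinc FIR applied once with exact group-delay
#' compensation, which leaves no phase distortion anywhere in the band.
#' Edges are handled by signal reflection. In-band sinusoids are preserved to
#' within a few percent; components one octave outside the band are
#' attenuated by more than 20 dB.
#'
#' @param rec an [eeg_recording] (broadband).
#' @param band a [band_spec]; `band$hi` must be below Nyquist.
#' @param trans_hz FIR transition width in Hz (see [design_fir_bandpass]).
#' @return The band-limited [eeg_recording], with `$band` set.
#' @export
bandpass <- function(rec, band, trans_hz = 2) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_spec"))
  b <- design_fir_bandpass(rec$fs, band$lo, band$hi, trans_hz = trans_hz)
  rec$epochs <- lapply(rec$epochs, zero_phase_filter_matrix, b = b)
  rec$band <- band
  rec
}

#' Per-epoch power spectral density of one recording
#'
#' Plain FFT periodogram per epoch and channel; for 4-s epochs the bin
#' spacing is 1/4 s = 0.25 Hz.
#'
#' @param rec an [eeg_recording].
#' @return list with `freq` (Hz, one-sided including DC) and `power`
#'   (channels x bins, averaged over epochs; units uV^2 per bin, scaled so the
#'   sum over all two-sided bins equals the time-domain mean square).
#' @export
epoch_spectra <- function(rec) {
  n <- n_samples(rec)
  freq_all <- (seq_len(n) - 1L) * rec$fs / n
  keep <- freq_all <= rec$fs / 2
  acc <- 0
  for (e in rec$epochs) {
    p <- t(Mod(stats::mvfft(t(e)))^2 / n^2)
    # fold negative frequencies onto positive (one-sided spectrum)
    folded <- p[, keep, drop = FALSE]
    neg <- p[, !keep, drop = FALSE]
    if (ncol(neg) > 0) {
      idx <- n - which(!keep) + 2L  # positive-bin index matching each negative bin
      for (j in seq_along(idx))
        folded[, idx[j]] <- folded[, idx[j]] + neg[, j]
    }
    acc <- acc + folded
  }
  power <- acc / n_epochs(rec)
  rownames(power) <- rec$channels
  list(freq = freq_all[keep], power = power)
}

#' Relative band power
#'
#' Band power is the area under the per-epoch FFT spectrum between the band
#' edges (half-open `[lo, hi)` bins); relative power is its ratio to the
#' total power in `[total_lo, total_hi)`. Spectra are averaged over epochs
#' first, then the ratio is averaged over channels.
#'
#' @param rec a broadband [eeg_recording]; a band-filtered input triggers a
#'   misuse warning since the total-power denominator would be meaningless.
#' @param band a [band_spec].
#' @param total_lo,total_hi total-power range (Hz), default 0.5-30, the union
#'   of the four canonical bands, so the four fractions sum to one.
#' @return list of class `power_summary`: `band`, `relative_power` (scalar in
#'   `[0, 1]`), `per_channel` (named vector of fractions).
#' @export
relative_power <- function(rec, band, total_lo = 0.5, total_hi = 30) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_spec"))
  if (!is.null(rec$band))
    warning("relative_power on band-filtered data: total-power denominator ",
            "no longer reflects the broadband signal", call. = FALSE)
  if (band$lo < total_lo || band$hi > total_hi)
    stop("band must lie within the total-power range")
  sp <- epoch_spectra(rec)
  in_band <- sp$freq >= band$lo & sp$freq < band$hi
  in_total <- sp$freq >= total_lo & sp$freq < total_hi
  bp <- rowSums(sp$power[, in_band, drop = FALSE])
  tp <- rowSums(sp$power[, in_total, drop = FALSE])
  frac <- ifelse(tp > 0, bp / tp, NA_real_)
  names(frac) <- rec$channels
  structure(list(band = band, relative_power = mean(frac, na.rm = TRUE),
                 per_channel = frac),
            class = "power_summary")
}
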