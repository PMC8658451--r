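# run code under a given seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# complex analytic band-limited Gaussian noise, one column per channel:
# nonzero coefficients only on the positive-frequency bins in [lo, hi);
# each column's Re() has unit standard deviation.
analytic_band_noise <- function(n, fs, lo, hi, ncols = 1L) {
  freq <- (seq_len(n) - 1) * fs / n
  sel <- freq >= lo & freq < hi & freq <= fs / 2 & freq > 0
  nb <- sum(sel)
  if (nb == 0L) stop("band contains no FFT bins at this length/rate")
  coef <- matrix(complex(real = 0, imaginary = 0), n, ncols)
  coef[sel, ] <- complex(real = stats::rnorm(nb * ncols),
                         imaginary = stats::rnorm(nb * ncols))
  z <- stats::mvfft(coef, inverse = TRUE) / sqrt(n)
  rms <- sqrt(colMeans(Re(z)^2))           # Re(z) has no DC component
  z / rep(rms, each = n)
}

# pink (1/f) noise via spectral shaping of white noise; unit sd per column
pink_noise <- function(n, fs, ncols = 1L) {
  x <- matrix(stats::rnorm(n * ncols), n, ncols)
  X <- stats::mvfft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n      # symmetric frequency magnitude
  scale <- ifelse(f > 0, 1 / sqrt(f), 0)
  y <- Re(stats::mvfft(X * scale, inverse = TRUE) / n)
  y <- y - rep(colMeans(y), each = n)
  y / rep(sqrt(colMeans(y^2)), each = n)
}

#' Parameters of the synthetic coupled-oscillator EEG generator
#'
#' The generator emulates the study geometry: 64 scalp channels sampled at
#' 1024 Hz, thirty 4-s epochs per recording. Each channel is a sum over the
#' four canonical bands of narrowband oscillations plus pink background
#' noise, then passed through a zero-lag "volume conduction" mixing:
#'
#' `x_i(t) = sum_b A_b * Re[ sqrt(c_b) z_b(t) e^{i delta_i} +
#'           sqrt(1 - c_b) z_{b,i}(t) ] + sigma * pink_i(t)`,
#' then `X <- ((1 - v) I + v J/N) X`.
#'
#' `z_b` is a shared analytic band-limited signal, `z_{b,i}` an independent
#' one per channel, so `c_b` in `[0, 1]` is a single coupling knob: `c_b = 0`
#' gives exactly independent channels (PLI at chance), `c_b = 1` a constant
#' non-zero phase lag `delta_i - delta_j` (PLI = 1). The channel offsets
#' `delta_i` are drawn away from 0 (mod pi) because PLI is blind to exactly
#' zero-lag coupling by construction. `v` is the uniform zero-lag mixing
#' strength, which raises inter-channel amplitude covariance but, being
#' instantaneous, should leave PLI at its unmixed level.
#'
#' @param n_channels number of channels (default 64).
#' @param fs sampling rate in Hz (default 1024).
#' @param epoch_s epoch duration in seconds (default 4).
#' @param n_epochs epochs per recording (default 30).
#' @param amplitudes named per-band oscillation amplitudes (uV).
#' @param coupling named per-band coupling `c_b` in `[0, 1]`.
#' @param mixing zero-lag mixing strength `v` in `[0, 1)`.
#' @param pink_amp pink-noise amplitude (uV).
#' @param offset_min minimum distance of `|delta_i|` from 0 and pi (radians).
#' @param seed integer seed; identical seeds give bit-identical recordings.
#' @return list of class `sim_params`.
#' @export
simulation_params <- function(n_channels = 64, fs = 1024, epoch_s = 4,
                              n_epochs = 30,
                              amplitudes = c(delta = 20, theta = 10,
                                             alpha = 15, beta = 5),
                              coupling = c(delta = 0.15, theta = 0.30,
                                           alpha = 0.40, beta = 0.15),
                              mixing = 0.25, pink_amp = 10,
                              offset_min = 0.3, seed = 1L) {
  if (any(coupling < 0 | coupling > 1))
    stop("coupling values must lie in [0, 1]")
  if (mixing < 0 || mixing >= 1) stop("mixing must lie in [0, 1)")
  if (any(amplitudes < 0) || pink_amp < 0) stop("amplitudes must be nonnegative")
  structure(list(n_channels = n_channels, fs = fs, epoch_s = epoch_s,
                 n_epochs = n_epochs, amplitudes = amplitudes,
                 coupling = coupling, mixing = mixing, pink_amp = pink_amp,
                 offset_min = offset_min, seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate one synthetic epoched recording
#'
#' See [simulation_params] for the signal model. Output is deterministic
#' given the seed in `params`.
#'
#' @param params a [simulation_params] object.
#' @param bands band definitions matching the names in `params$amplitudes`
#'   (default [default_bands]).
#' @param subject_id,group,condition metadata stamped on the recording.
#' @return An [eeg_recording] of `n_epochs` epochs, channels x samples.
#' @export
generate_recording <- function(params, bands = default_bands(),
                               subject_id = "sim", group = NA_character_,
                               condition = NA_character_) {
  stopifnot(inherits(params, "sim_params"))
  nch <- params$n_channels
  n <- params$n_epochs * round(params$epoch_s * params$fs)
  x <- with_seed(params$seed, {
    # channel phase offsets, |delta| in [offset_min, pi - offset_min]
    delta <- sample(c(-1, 1), nch, replace = TRUE) *
      stats::runif(nch, params$offset_min, pi - params$offset_min)
    acc <- matrix(0, n, nch)                 # samples x channels while building
    for (bn in names(params$amplitudes)) {
      band <- bands[[bn]]
      if (is.null(band)) stop("no band definition for amplitude '", bn, "'")
      a <- params$amplitudes[[bn]]
      if (a == 0) next
      cc <- params$coupling[[bn]]
      z_shared <- analytic_band_noise(n, params$fs, band$lo, band$hi)[, 1]
      z_ind <- analytic_band_noise(n, params$fs, band$lo, band$hi, ncols = nch)
      shared <- outer(z_shared, exp(1i * delta))
      acc <- acc + a * Re(sqrt(cc) * shared + sqrt(1 - cc) * z_ind)
    }
    if (params$pink_amp > 0)
      acc <- acc + params$pink_amp * pink_noise(n, params$fs, ncols = nch)
    acc <- t(acc)                            # channels x samples
    v <- params$mixing
    if (v > 0) {
      mix <- (1 - v) * diag(nch) + v * matrix(1 / nch, nch, nch)
      acc <- mix %*% acc
    }
    acc
  })
  segment(x, fs = params$fs, epoch_s = params$epoch_s,
          n_keep = params$n_epochs, subject_id = subject_id, group = group,
          condition = condition)
}

#' Group-by-condition coupling effect specification
#'
#' Multiplicative modifiers applied to a band's coupling for one group in one
#' condition — e.g. theta coupling x 0.8 for the dyslexic group during the
#' task, emulating a selective connectivity deficit.
#'
#' @param group,condition,band character vectors (recycled) naming the cells.
#' @param multiplier positive multipliers applied to the base coupling.
#' @return data.frame of class `effect_spec`.
#' @export
effect_spec <- function(group, condition, band, multiplier) {
  if (any(multiplier <= 0)) stop("effect multipliers must be positive")
  structure(data.frame(group = group, condition = condition, band = band,
                       multiplier = multiplier, stringsAsFactors = FALSE),
            class = c("effect_spec", "data.frame"))
}

# look up the combined multiplier for one cell
effect_multiplier <- function(effects, group, condition, band) {
  if (is.null(effects)) return(1)
  hit <- effects$group == group & effects$condition == condition &
    effects$band == band
  if (!any(hit)) 1 else prod(effects$multiplier[hit])
}

#' Generate a full synthetic two-group, two-condition study
#'
#' Builds a [study_design] with `n_per_group` subjects per group, each with a
#' baseline and a task recording. Per-subject heterogeneity enters as
#' log-normal jitter on the band couplings and amplitudes; programmed
#' group-by-condition effects multiply the jittered coupling. All randomness
#' descends from `seed` through a per-subject, per-condition splitting scheme,
#' so any single recording is reproducible in isolation.
#'
#' @param n_per_group named counts, e.g. `c(typical = 31, dyslexic = 24)`.
#' @param base a [simulation_params] giving the shared geometry and baseline
#'   coupling/amplitudes.
#' @param effects an [effect_spec] or `NULL` for a null study.
#' @param seed master integer seed.
#' @param coupling_jitter_sd log-scale SD of per-subject coupling jitter.
#' @param amplitude_jitter_sd log-scale SD of per-subject amplitude jitter.
#' @param conditions condition labels (default baseline, task).
#' @return A [study_design] with all recordings in memory.
#' @export
generate_study <- function(n_per_group = c(typical = 31, dyslexic = 24),
                           base = simulation_params(), effects = NULL,
                           seed = 1L, coupling_jitter_sd = 0.10,
                           amplitude_jitter_sd = 0.10,
                           conditions = c("baseline", "task")) {
  if (any(n_per_group < 2)) stop("need at least 2 subjects per group")
  groups <- rep(names(n_per_group), n_per_group)
  ids <- sprintf("S%02d", seq_along(groups))
  subjects <- data.frame(subject_id = ids, group = groups,
                         stringsAsFactors = FALSE)
  # per-subject jitters drawn under the master seed
  n_sub <- length(ids)
  nb <- length(base$coupling)
  jit <- with_seed(seed, list(
    coup = matrix(exp(stats::rnorm(n_sub * nb, 0, coupling_jitter_sd)),
                  n_sub, nb, dimnames = list(ids, names(base$coupling))),
    amp = matrix(exp(stats::rnorm(n_sub * nb, 0, amplitude_jitter_sd)),
                 n_sub, nb, dimnames = list(ids, names(base$amplitudes)))))
  recordings <- list()
  for (s in seq_len(n_sub)) {
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      p <- base
      p$coupling <- pmin(base$coupling * jit$coup[s, ], 1)
      p$amplitudes <- base$amplitudes * jit$amp[s, ]
      for (bn in names(p$coupling))
        p$coupling[[bn]] <- min(1, p$coupling[[bn]] *
          effect_multiplier(effects, groups[s], cond, bn))
      # deterministic per-recording seed below 2^31
      p$seed <- as.integer((as.numeric(seed) * 1000003 + s * 2053 + ci) %%
                             2147483647)
      recordings[[paste(ids[s], cond, sep = ".")]] <-
        generate_recording(p, subject_id = ids[s], group = groups[s],
                           condition = cond)
    }
  }
  study_design(subjects, recordings, conditions = conditions)
}

#' Generate per-subject learning curves over time-on-task bins
#'
#' Accuracy rises exponentially toward an asymptote across bins (probability
#' learning), with additive Gaussian noise — the shape a repeated-measures
#' ANOVA with a within-subject bin factor is meant to detect.
#'
#' @param n_subjects number of subjects.
#' @param bins number of time-on-task bins (default 4).
#' @param start,asymptote expected accuracy (%) at bin 1 and at saturation.
#' @param rate exponential approach rate per bin; 0 gives flat curves.
#' @param noise SD of additive accuracy noise (%).
#' @param seed integer seed.
#' @return numeric matrix, subjects x bins, of accuracies.
#' @export
generate_learning_curves <- function(n_subjects, bins = 4, start = 76,
                                     asymptote = 88, rate = 1.2, noise = 9,
                                     seed = 1L) {
  if (bins < 2L) stop("need at least 2 bins")
  mu <- asymptote - (asymptote - start) * exp(-rate * (seq_len(bins) - 1))
  with_seed(seed, {
    y <- matrix(rep(mu, each = n_subjects), n_subjects, bins) +
      matrix(stats::rnorm(n_subjects * bins, 0, noise), n_subjects, bins)
    dimnames(y) <- list(sprintf("S%02d", seq_len(n_subjects)),
                        paste0("bin", seq_len(bins)))
    y
  })
}
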