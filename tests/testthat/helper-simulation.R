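# Reduced simulation geometries used by the simulation-based checks.
# 16 channels; the sampling rate, epoch count and duration are scaled down
# from the recording geometry because PLI sampling noise is governed by
# band bandwidth x epoch duration, not by the sampling rate.

theta_band <- band_spec("theta", 4, 8)

# geometry for type-I-error calibration (null studies)
null_sim_params <- function(seed) {
  simulation_params(n_channels = 16, fs = 64, epoch_s = 2, n_epochs = 2,
                    seed = seed)
}

# calibrated geometry for the effect-recovery (power) studies: base theta
# coupling 0.35 and between-subject coupling jitter 0.05 were fixed once by
# pilot simulation so that a 20% task-coupling reduction is detectable
power_sim_params <- function(seed) {
  p <- simulation_params(n_channels = 16, fs = 64, epoch_s = 4, n_epochs = 4,
                         seed = seed)
  p$coupling["theta"] <- 0.35
  p
}
power_jitter_sd <- 0.05

# per-subject mean total theta PLI for every recording of a study
theta_pli_table <- function(design, trans_hz = 6) {
  rows <- lapply(names(design$recordings), function(k) {
    rec <- design$recordings[[k]]
    rb <- bandpass(average_reference(rec), theta_band, trans_hz = trans_hz)
    data.frame(subject_id = rec$subject_id, condition = rec$condition,
               value = mean_total_pli(pli_epochs(rb)))
  })
  do.call(rbind, rows)
}

# mixed-ANOVA p-values (condition, interaction, group) for one study
study_anova_p <- function(design) {
  vals <- theta_pli_table(design)
  groups <- stats::setNames(design$subjects$group, design$subjects$subject_id)
  an <- mixed_anova_2x2(vals, groups)
  stats::setNames(an$p, an$effect)
}
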