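test_that("identical seeds give bit-identical recordings and studies", {
  p <- simulation_params(n_channels = 4, fs = 64, epoch_s = 2, n_epochs = 2,
                         seed = 123)
  expect_identical(generate_recording(p)$epochs, generate_recording(p)$epochs)
  d1 <- generate_study(c(typical = 2, dyslexic = 2), base = p, seed = 3)
  d2 <- generate_study(c(typical = 2, dyslexic = 2), base = p, seed = 3)
  expect_identical(lapply(d1$recordings, `[[`, "epochs"),
                   lapply(d2$recordings, `[[`, "epochs"))
})

test_that("parameter validation rejects out-of-range coupling and mixing", {
  expect_error(simulation_params(coupling = c(delta = 0, theta = 1.2,
                                              alpha = 0, beta = 0)),
               "coupling")
  expect_error(simulation_params(mixing = 1), "mixing")
  expect_error(effect_spec("dyslexic", "task", "theta", 0), "positive")
})

test_that("zero coupling sits at the band-limited independence chance level", {
  # Monte-Carlo oracle: PLI between independent band-limited channels built
  # directly from white noise + filtering, outside the generator under test
  theta <- band_spec("theta", 4, 8)
  fs <- 256; n <- 4 * fs
  set.seed(61)
  oracle <- replicate(60, {
    e <- matrix(rnorm(2 * n), 2)
    rb <- bandpass(eeg_recording(list(e), fs = fs), theta, trans_hz = 4)
    pli_matrix(rb)[1, 2]
  })

  p <- simulation_params(n_channels = 2, fs = fs, epoch_s = 4, n_epochs = 1,
                         amplitudes = c(theta = 10),
                         coupling = c(theta = 0), mixing = 0, pink_amp = 0,
                         seed = 1)
  got <- sapply(1:60, function(s) {
    p$seed <- s
    rec <- bandpass(generate_recording(p), theta, trans_hz = 4)
    pli_matrix(rec)[1, 2]
  })
  se <- sqrt(var(oracle) / 60 + var(got) / 60)
  expect_lt(abs(mean(got) - mean(oracle)), 3 * se)
})

test_that("full coupling with distinct offsets approaches perfect locking", {
  theta <- band_spec("theta", 4, 8)
  p <- simulation_params(n_channels = 8, fs = 256, epoch_s = 4, n_epochs = 2,
                         amplitudes = c(theta = 10),
                         coupling = c(theta = 1), mixing = 0, pink_amp = 0,
                         seed = 17)
  rec <- bandpass(generate_recording(p), theta, trans_hz = 4)
  expect_gte(mean_total_pli(pli_epochs(rec)), 0.95)
})

test_that("subject-mean PLI is nondecreasing in the coupling knob", {
  theta <- band_spec("theta", 4, 8)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  mean_pli_at <- function(cc, seeds) {
    sapply(seeds, function(s) {
      p <- simulation_params(n_channels = 6, fs = 128, epoch_s = 4,
                             n_epochs = 2, amplitudes = c(theta = 10),
                             coupling = c(theta = cc), mixing = 0,
                             pink_amp = 2, seed = s)
      mean_total_pli(pli_epochs(bandpass(generate_recording(p), theta,
                                         trans_hz = 4)))
    })
  }
  vals <- lapply(grid, mean_pli_at, seeds = 1:12)
  mu <- sapply(vals, mean)
  se <- sapply(vals, function(v) sd(v) / sqrt(length(v)))
  for (i in seq_len(length(grid) - 1))
    expect_gt(mu[i + 1] - mu[i], -2 * sqrt(se[i]^2 + se[i + 1]^2))
  expect_gt(mu[5], mu[1] + 0.3)  # and strongly increasing overall
})

test_that("band amplitude drives relative power; coupling does not", {
  theta <- band_spec("theta", 4, 8)
  rp_at <- function(a_theta, c_theta, seed) {
    p <- simulation_params(n_channels = 4, fs = 128, epoch_s = 4, n_epochs = 2,
                           amplitudes = c(delta = 10, theta = a_theta,
                                          alpha = 10, beta = 5),
                           coupling = c(delta = 0.2, theta = c_theta,
                                        alpha = 0.2, beta = 0.2),
                           seed = seed)
    relative_power(generate_recording(p), theta)$relative_power
  }
  lo <- sapply(1:10, function(s) rp_at(5, 0.3, s))
  hi <- sapply(1:10, function(s) rp_at(15, 0.3, s))
  expect_gt(mean(hi), mean(lo) + 0.1)

  c_lo <- sapply(1:10, function(s) rp_at(10, 0.05, s))
  c_hi <- sapply(1:10, function(s) rp_at(10, 0.95, s))
  se <- sqrt(var(c_lo) / 10 + var(c_hi) / 10)
  expect_lt(abs(mean(c_hi) - mean(c_lo)), 4 * se)
})

test_that("zero-lag mixing inflates amplitude covariance but not PLI", {
  theta <- band_spec("theta", 4, 8)
  run <- function(v, seed) {
    p <- simulation_params(n_channels = 8, fs = 128, epoch_s = 4, n_epochs = 2,
                           amplitudes = c(theta = 10),
                           coupling = c(theta = 0), mixing = v, pink_amp = 3,
                           seed = seed)
    rec <- generate_recording(p)
    rb <- bandpass(rec, theta, trans_hz = 4)
    e <- rec$epochs[[1]]
    cv <- cor(t(e))
    c(pli = mean_total_pli(pli_epochs(rb)),
      amp_cor = mean(cv[upper.tri(cv)]))
  }
  seeds <- 1:12
  unmixed <- t(sapply(seeds, function(s) run(0, s)))
  mixed <- t(sapply(seeds, function(s) run(0.6, s)))
  # amplitude covariance rises sharply
  expect_gt(mean(mixed[, "amp_cor"]), mean(unmixed[, "amp_cor"]) + 0.3)
  # PLI stays at chance: difference within Monte-Carlo variability
  se <- sqrt(var(mixed[, "pli"]) / 12 + var(unmixed[, "pli"]) / 12)
  expect_lt(abs(mean(mixed[, "pli"]) - mean(unmixed[, "pli"])), 3 * se)
})

test_that("programmed group-by-condition effects shift the right cell", {
  theta <- band_spec("theta", 4, 8)
  eff <- effect_spec("dyslexic", "task", "theta", 0.5)  # strong, few subjects
  p <- simulation_params(n_channels = 8, fs = 64, epoch_s = 4, n_epochs = 2,
                         seed = 2)
  p$coupling["theta"] <- 0.5
  des <- generate_study(c(typical = 4, dyslexic = 4), base = p, effects = eff,
                        seed = 2, coupling_jitter_sd = 0.02)
  tab <- theta_pli_table(des)
  tab$group <- des$subjects$group[match(tab$subject_id,
                                        des$subjects$subject_id)]
  cell <- tapply(tab$value, list(tab$group, tab$condition), mean)
  # only dyslexic-task is reduced
  expect_lt(cell["dyslexic", "task"], cell["dyslexic", "baseline"] - 0.02)
  expect_lt(cell["dyslexic", "task"], cell["typical", "task"] - 0.02)
  # no programmed effect for typical readers; allow small-sample wobble
  expect_lt(abs(cell["typical", "task"] - cell["typical", "baseline"]), 0.08)
})

test_that("learning curves behave as programmed", {
  # zero noise reproduces the deterministic curve
  y0 <- generate_learning_curves(5, bins = 4, start = 76, asymptote = 88,
                                 rate = 1.2, noise = 0, seed = 1)
  mu <- 88 - (88 - 76) * exp(-1.2 * (0:3))
  for (i in 1:5) expect_equal(unname(y0[i, ]), mu, tolerance = 1e-12)

  # rate 0: flat curves, bin effect at null levels across simulations
  set.seed(10)
  ps <- sapply(1:200, function(s)
    rm_anova_gg(generate_learning_curves(20, rate = 0, noise = 5,
                                         seed = s))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)

  # positive rate: bin effect detected with high power
  det <- sapply(1:50, function(s)
    rm_anova_gg(generate_learning_curves(30, rate = 1.2, noise = 9,
                                         seed = 1000 + s))$p < 0.05)
  expect_gt(mean(det), 0.9)
})
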