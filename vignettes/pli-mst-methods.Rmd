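---
title: "Band-limited EEG connectivity with PLI and minimum spanning trees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-limited EEG connectivity with PLI and minimum spanning trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plimst)
```

## The analysis in one paragraph

`plimst` implements a group-comparison workflow for multichannel EEG:
epoched recordings are average-referenced and band-pass filtered into the
canonical delta/theta/alpha/beta bands; functional connectivity between every
channel pair is quantified per epoch with the Phase Lag Index (PLI); each
epoch's connectivity matrix is reduced to its minimum spanning tree (MST)
using `1 - PLI` link distances, and the tree's topology is summarised by the
standard MST metrics; finally, subject-level measures (relative band power,
mean total PLI, epoch-averaged tree metrics) enter 2x2 mixed-design ANOVAs
(within-subject *condition*: baseline vs task; between-subject *group*) with
partial eta squared, Benjamini-Hochberg FDR control, per-condition follow-up
contrasts, PLI-on-power regressions, and p-value stepwise regressions against
behavioural outcomes. A synthetic coupled-oscillator generator reproduces the
statistical structure this pipeline assumes, so every stage is testable
without recorded data.

## Signal model and preprocessing

Recordings are epoched (4-s epochs by default; `segment()` keeps the first
`n_keep` epochs — a deterministic rule, preferred to an arbitrary selection
the analysis cannot justify). `average_reference()` subtracts the
instantaneous mean across channels, so the referenced data have exactly zero
channel-mean at every sample.

**Band-pass filtering.** Each band is isolated with a Hamming windowed-sinc
FIR (`signal::fir1`) of even order, applied *once* with exact integer
group-delay compensation and reflection padding. A symmetric FIR has
precisely linear phase, so delay compensation makes the filter zero-phase
without the forward-backward pass; this matters because PLI is a pure phase
statistic, and it avoids the signal-length restrictions a forward-backward
implementation imposes on 4-s epochs at the filter orders needed. The
convolution itself runs in the frequency domain (zero-padded FFT), which is
exact. The transition width `trans_hz` (default 2 Hz) sets the order as
`ceiling(3.3 * fs / trans_hz)`; at the default, in-band sinusoids pass within
a few percent and components one octave outside the theta/alpha/beta bands
are attenuated by well over 20 dB. The delta band's lower edge (0.5 Hz)
cannot meet a 20 dB spec one octave down (0.25 Hz) at any order a 4-s epoch
supports; delta is therefore computed and reported but excluded from the
statistical family by default (`analysis_config(stats_bands = ...)`).

**Relative power.** Per-epoch FFT periodograms (bin spacing `1/epoch_s`,
i.e. 0.25 Hz for 4-s epochs) are averaged over epochs; band power is the sum
of bins in the half-open interval `[lo, hi)` — half-open so adjacent bands
never double-count an edge bin — and relative power divides by the total in
`[0.5, 30)` Hz, the union of the four bands, which makes the four fractions
sum to one (an assertable invariant). Bin summation rather than trapezoidal
integration is used; the difference is a boundary-bin effect far below the
other approximations involved.

## Phase Lag Index

Instantaneous phases come from the analytic signal (FFT implementation of
the Hilbert transform; no installed package provides one). For two phase
series the PLI is

    PLI = | < sign( sin( phi_1(t) - phi_2(t) ) ) > |

with `sign(0)` contributing zero, so two identical channels give exactly 0.
PLI is 0 for no coupling *or* for coupling at a phase difference centred on
0 (mod pi) — the signature of instantaneous volume conduction — and 1 for
perfect locking at any non-zero lag. PLI is computed per epoch and averaged
(never on concatenated epochs); no edge samples are trimmed by default — the
zero-phase filter and reflection padding keep edge phase distortion small,
and trimming is a user-level choice (shorten epochs) rather than a hidden
default. "Mean total PLI" is the average over all channel pairs and epochs.

For independent channels with `T` effectively independent samples,
`E[PLI] = sqrt(2 / (pi T))` (half-normal limit of a mean of fair signs);
`pli_chance_level()` exposes this. Band-limited signals have far fewer
effective samples than time points (roughly bandwidth x duration), so the
realised chance level of filtered EEG is well above `sqrt(2/(pi * n))` —
tests against "no coupling" therefore use Monte-Carlo references built from
independently filtered noise, not the i.i.d. formula.

## Minimum spanning tree and its metrics

With link distance `1 - PLI`, Kruskal's algorithm grows the unique
acyclic sub-graph connecting all `N` nodes with `m = N - 1` links of minimal
total distance — the maximum-connectivity backbone. Ties are broken
lexicographically by node pair so results are deterministic; a seeded
`1e-12` jitter is available where strict weight uniqueness is wanted.
MST comparisons avoid the bias that differences in overall connectivity
strength induce in thresholded graphs.

Per tree we report: maximum degree; leaf number `L` (degree-1 nodes, with
`2 <= L <= N - 1`) and leaf fraction `L/m`; diameter `d` in hops (bounded by
`d <= m - L + 2`) and mean eccentricity; betweenness centrality normalised
by the `(N-1)(N-2)/2` pairs not involving the node (computed by the
subtree-product identity that holds on trees, where paths are unique; leaves
have BC 0); tree hierarchy `T_H = L / (2 m BC_max)`, which balances short
paths against hub overload and equals 0.5 for a star; degree correlation
`R`, the Pearson correlation of link endpoint degrees counted in both
directions (the orientation-invariant convention — under it a star is
perfectly disassortative, `R = -1`); kappa `<k^2>/<k>`; and the MST mean,
the mean PLI of tree links. Hop-normalised variants divide by `m`. Metrics
are computed per epoch and averaged per subject, condition and band — never
from a tree of the averaged matrix, which would be a different (and
biased) estimator.

## Statistical layer

The 2x2 mixed ANOVA is computed from explicit split-plot sums of squares so
that each partial eta squared has an unambiguous error term: the
between-subject error for the group effect; the subject-by-condition error
for condition and the interaction. `rm_anova_gg()` generalises to `k`
within-subject levels and applies the Greenhouse-Geisser epsilon (from the
pooled covariance of orthonormalised contrasts) to the degrees of freedom
whenever `k > 2`; at `k = 2` sphericity is trivial and epsilon is 1. The
implementations are cross-checked in the tests against `aov()` with error
strata.

FDR control is Benjamini-Hochberg (`stats::p.adjust`), applied within each
band-by-effect family of measures at `q = 0.10` and `q = 0.05`; family
composition is configurable because pooling choices are a judgement call.
Follow-up per-condition group contrasts are one-way ANOVAs (identical to
squared pooled two-sample t). The stepwise regression is the classical
p-value procedure — forward entry by smallest partial-F p below `p_in =
0.05`, backward removal above `p_out = 0.10`, iterated to a fixed point —
implemented in-package because base `step()` selects by AIC. Stepwise
selection overfits at small n by construction (the worked example shows
adjusted R-squared near 1 with 8 predictors on 10 subjects); the tables
report every step so that readers can see it happening.

## The synthetic generator

Each channel is a sum over bands of narrowband oscillations plus pink
(1/f-shaped) noise:

    x_i(t) = sum_b A_b * Re[ sqrt(c_b) z_b(t) e^{i delta_i}
                             + sqrt(1 - c_b) z_{b,i}(t) ] + sigma * pink_i(t)

where `z_b` is a shared analytic band-limited Gaussian signal, `z_{b,i}`
an independent one per channel, and `delta_i` per-channel phase offsets
drawn away from 0 (mod pi) — PLI is blind to exactly-zero-lag coupling, so a
shared component must be lagged to be visible. The coupling knob `c_b` is a
*mixture weight on analytic signals* rather than a von-Mises phase-noise
concentration: the mixture form guarantees that `c_b = 0` yields exactly
independent channels (so chance-level checks are well-posed), that `c_b = 1`
yields a constant non-zero lag (PLI -> 1), and monotone behaviour in
between, none of which a slowly-varying phase-noise process delivers
exactly. Volume conduction is modelled as instantaneous uniform mixing
`X <- ((1-v) I + v J/N) X`, which raises inter-channel amplitude covariance
(for independent sources, pairwise correlation ~0.25 at `v = 0.6`, `N = 16`)
while leaving PLI at its unmixed level — the property PLI exists to exploit.

Defaults mirror the recording geometry the pipeline targets: 64 channels at
1024 Hz, thirty 4-s epochs, amplitudes (uV) delta 20 / theta 10 / alpha 15 /
beta 5 over pink noise 10, couplings delta 0.15 / theta 0.30 / alpha 0.40 /
beta 0.15, mixing 0.25 — band power descending from low frequencies and
alpha the most synchronised band, the usual resting adult scalp pattern.
Group studies add per-subject log-normal jitter on couplings and amplitudes
(SD 0.10 by default), and `effect_spec()` multiplies a band's coupling for
one group in one condition. All randomness descends from one seed through a
per-subject, per-condition splitting scheme, so any single recording is
reproducible in isolation.

What the generator does **not** emulate: biophysical head geometry and
realistic lead fields, artifacts (blinks, EMG, electrode movement),
non-stationarity within recordings, and realistic spatial correlation
structure of scalp EEG. Passing tests therefore demonstrate that the
*pipeline* recovers what it assumes — not that those assumptions hold for
any particular dataset.

## Simulation sizes and calibration

The simulation-based checks run at reduced geometry: 16 channels, with the
sampling rate lowered to 64 Hz and fewer/shorter epochs. PLI sampling noise
is governed by band bandwidth x epoch duration (not the sampling rate), so
these reductions change precision in known ways without changing the
statistical structure. Type-I calibration uses 2000 null studies of 8 + 8
subjects with two 2-s epochs per recording; every mixed-ANOVA effect is
required to reject at 5% +/- 1.5%. The effect-recovery study uses
realistic unequal group sizes (31 typical / 24 dyslexic readers) with four
4-s epochs, a base theta coupling of 0.35 and subject coupling jitter SD 0.05 —
values calibrated once by pilot simulation so that a 20% theta task-coupling
reduction in one group is detectable, then frozen. The test requires the
condition-by-group interaction plus the task-only follow-up contrast (in the
right direction) in at least 80% of 200 studies.

## Numerical choices and degenerate inputs

- Kruskal ties: lexicographic by `(i, j)` after sorting by distance;
  deterministic and permutation-equivariant up to relabeling.
- `sign(0) -> 0` in the PLI, so identical signals give exactly 0 rather than
  an arbitrary sign.
- Degree correlation is `NA` when endpoint degrees have zero variance
  (only possible for `N = 2`); undefined epochs are excluded from the
  subject average and counted in `r_defined`.
- Tree metrics require `N >= 3` (diameter and betweenness are degenerate
  below that); PLI requires two channels; the average reference requires two
  channels; an all-zero channel has no phase and is an error rather than a
  silent NaN.
- Band edges at 4, 8, 13 Hz belong to the upper band (half-open bins).
- ASCII epoch files round-trip exactly at the written precision (default 10
  significant digits); ragged rows and non-numeric cells fail with the line
  number.

## Known limitations

- PLI discards zero-lag coupling by design; genuinely instantaneous neural
  coupling is invisible to this pipeline.
- The delta band is reported with a filter that cannot meet the stopband
  spec at its lower edge (see above).
- EDF/BDF ingestion is not implemented; the plain-text epoch format is the
  interchange contract.
- The stepwise procedure is the classical p-entry/p-removal algorithm with
  its well-known selection-bias properties; it is provided because the
  analysis it reproduces uses it, not as a recommendation.
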