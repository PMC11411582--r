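---
title: "Models and methods behind eventseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eventseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

eventseg implements, end to end, the analysis chain of an EEG event-
segmentation experiment built on temporal community structure: a stimulus
sequence generator, a synthetic EEG and behaviour simulator with planted
effects, and the ERP, decoding, predictive-classification, and pattern-
similarity analyses that operate on the result. This vignette explains the
models, the defaults and their units, the numerical conventions, and the
design decisions taken where the design was genuinely open. Nothing here
states an empirical result that the package's tests do not themselves
compute.

## The community graph and its sequences

The paradigm's graph has 15 nodes in three communities of five. Each inner
node connects to its four community members; each of a community's two
boundary nodes connects to the three inner nodes and to one boundary node of
the adjacent community, closing the three communities into a ring. Every
node has degree 4, so community membership is invisible to local transition
statistics. `build_graph()` constructs exactly this graph; stimulus identity
is a uniform draw without replacement from a pool of 74 ids when a seed is
supplied.

Exposure sequences are plain random walks (default 1,400 trials, 1.25 s
stimulus onset asynchrony) with independent 25% rotation flags. Parsing
sequences (default 1,200 trials) alternate 15-trial pseudorandom-walk blocks
with 15-trial Hamiltonian-path blocks. The pseudorandom walk forces a
community exit at the next boundary-node visit once nine consecutive
same-community stimuli have occurred, with the counter reset at every
community change.

Two sequence-construction details deserve comment:

* **Hamiltonian origination.** A literal reading — the path's first node
  *is* the walk's final node — either re-displays that node or shortens the
  blocks, and cannot produce 40 + 40 blocks of 15 trials. We therefore let
  the walk take one further pseudorandom step; the landing node opens the
  Hamiltonian block (the path is drawn from the pre-generated pool among
  paths starting at a neighbour of the last displayed walk node). Every
  junction is then an ordinary graph step, no stimulus repeats, and the
  phase has exactly 1,200 trials. `origin = "same_node"` reproduces the
  literal reading; its junctions are labelled `seam`.
* **Path pool.** The pre-generated pool of 15 Hamiltonian paths is
  restricted to paths that traverse each community contiguously, i.e. with
  exactly two between-community transitions — the enumerated minimum on this
  graph (exhaustive search finds paths with two or three crossings). With
  this restriction the manipulated (novel) transitions settle near the design
  value of 4.6% of all stimulus transitions (about one third of all
  community transitions); with unrestricted pools the share drifts above 5%.

One of the three community transitions is manipulated per 200-trial block,
cycling so each is manipulated twice across the six blocks. Within a block,
each boundary node of the manipulated transition swaps stimuli
bidirectionally with a randomly chosen inner node of its own community
(constant within the block). Crossing the manipulated transition while the
swap is active is a `novel_boundary`; other community crossings are
`learned_boundary`; within-community steps are `nonboundary`.

The posttest pairs every stimulus as a cue with each of its four community
members as target (60 trials), lure drawn from a different community.

## The synthetic session

`generative_spec()` collects every planted parameter; `simulate_session()`
renders a continuous multi-channel recording (microvolts) on an extended
10–20 montage (default 64 scalp channels plus four EOG channels; reduced
channel counts always retain Pz and CP1). The planted components are:

* **Background.** 1/f^β noise (β = 1, RMS 10 µV per channel) plus 60 Hz
  line noise (2 µV).
* **Evoked P300-like deflection.** A Gaussian bump (peak 350 ms, SD 50 ms)
  with parietal topography centred on Pz and condition-dependent amplitude,
  default {novel 3, learned 5, nonboundary 2} µV. The experiment this
  emulates reports no effect sizes in microvolts; these defaults are chosen
  for testability and are labelled as such.
* **Community templates.** One posterior-weighted random channel pattern per
  community, carried by amplitude-modulated narrowband noise in the 5–7 Hz
  band plus a secondary broadband 15–40 Hz component at 20% of template
  power (`template_broadband = 0.5`). The multiband composition mirrors the
  empirical observation that latent spectral components span theta through
  gamma, and matters numerically: a purely 5–7 Hz template is blurred by
  roughly ±200 ms under 4-cycle wavelets, which would make sharp onset
  recovery impossible. Narrowband carriers rather than pure sinusoids avoid
  degenerate wavelet tests.
* **Predictive mixing.** Boundary-node epochs additionally receive the
  *adjacent* community's template scaled by
  `min(1, alpha0 + alpha1 * run_length)` (defaults α0 = 0, α1 = 0.08),
  where the run length counts consecutive same-community trials preceding
  the visit. The mixture switches on `mix_onset_s = 0.25` s after stimulus
  onset (50 ms cosine rise, sustained to the end of the presentation),
  emulating a retrieval-like latency in the window where the emulated
  experiment observed predictive evidence.
* **Artifacts.** Blinks as raised-cosine deflections (rate 0.1/s, 150 µV)
  coupled into the EOG channels with a frontally weighted scalp projection,
  and rare per-trial spikes (rate 0.02, 400 µV) that exceed the ±250 µV
  rejection criterion. Both are logged as ground truth.

Behaviour is generated per trial: parse decisions are Bernoulli with the
reported condition rates ({18.3, 19.0, 14.0}%), response times are truncated
normal with the reported means ({690, 648, 631} ms; the per-trial SD of
150 ms is our choice — only group SEs are reported), rotation-task responses
follow hit/false-alarm rates (0.85/0.15, giving d′ near the reported 2.03),
and posttest answers are Bernoulli(0.656). Both response modes
(respond-every-trial and parse-only) are supported.

What the simulator does **not** emulate: biophysical volume conduction (no
leadfields), eye-movement kinematics beyond blink templates, non-stationary
drowsiness or impedance drift, and item-specific neural codes (the
representation is community-level by construction, matching the emulated
null finding at boundary positions). Passing recovery tests therefore shows
the analysis chain is correct and calibrated — not that real scalp data
behave this simply.

## Preprocessing conventions

* **Filtering.** Butterworth filters applied forward and backward
  (zero-phase `filtfilt`): high-pass 0.5 Hz (order 2), low-pass 200 Hz
  (order 4, clipped below Nyquist with a warning when the sampling rate
  demands it), and order-2 band-stop notches of ±2 Hz at 60 Hz and each
  harmonic below the low-pass cutoff. The filter family and harmonic count
  are our choices and are exposed as arguments.
* **Ocular cleaning.** A deflationary FastICA (tanh contrast, whitening by
  eigendecomposition) written for this package, as no ICA implementation is
  available among its dependencies. Components whose correlation with any
  EOG channel exceeds z = 3 (z-scored across components, per EOG channel)
  are zeroed before reconstruction. Note the z-rule needs a reasonable
  component count: the largest attainable z among k values is (k−1)/√k, so
  with fewer than ~11 components nothing can reach 3.
* **Epoching.** −100 to 1,000 ms around onset, inclusive endpoints at the
  sampling grid; baseline mean (−100 to 0 ms, left-closed right-open — the
  convention used for every analysis window in the package) subtracted per
  epoch and channel. Epochs that do not fit the recording are dropped with a
  message.
* **Artifact rejection.** An epoch is rejected iff any scalp channel's
  peak-to-peak amplitude within any 200 ms window (50 ms steps; the final
  partial window is evaluated when at least half a window remains) exceeds
  250 µV. The manual artifact marking of the emulated procedure is replaced
  by this automatic rule.
* **Spectral decomposition.** Complex Morlet wavelets with four cycles per
  frequency at 30 log-spaced frequencies, 4–100 Hz (fewer at reduced
  sampling rates), implemented as FFT-domain Gaussian filters on each epoch
  flanked by temporally reflected copies of itself; the buffers are
  discarded after convolution and base-10 log power is returned. A
  `time_bandwidth` argument is retained for parameterisations that use it;
  four cycles is the binding setting.
* **z-scoring.** Per channel × frequency feature: the across-epoch mean and
  SD of the *time-averaged* log power (rejected epochs excluded first) are
  applied to the epoch average and, for time-resolved use, to every sample.
  Reusing epoch-level statistics preserves the evoked dynamics the
  windowed decoder needs; per-sample statistics would erase them.

## Analysis conventions

* **P300.** Mean of the preprocessed voltage (not power) at Pz in
  [250, 450) ms; the early control window [50, 250) runs through the same
  code path. Condition statistics use one-way repeated-measures ANOVA and
  paired t tests with η² and Cohen's d; participants missing a condition
  are dropped per test.
* **Permutation contrast.** The difference between the novel and learned
  brain-behaviour correlations is tested by swapping, independently per
  participant, which condition's (ΔP300, Δparse) pair carries the novel
  label; two-tailed p = (1 + #{|null| ≥ |obs|}) / (1 + n_perm). The emulated
  analysis names only "permutation test"; this scheme is our construction
  and is seeded.
* **PCA feature selection.** Missing cells are imputed from each feature's
  Gaussian (μ, σ) over observed epochs; components with eigenvalue > 1 on
  the z-scored features are retained (Kaiser). Component signs are
  indeterminate, so each retained component is oriented to a non-negative
  loading sum before any cross-participant averaging.
* **Loading topography.** Retained-component loadings are averaged across
  components with eigenvalue weights by default (each component weighted by
  its share of explained variance) — the open choice here was weighted vs
  unweighted, and unweighted averaging lets the many near-threshold noise
  components drown the structure the decomposition actually found. Signed
  averaging (default) answers "which features load consistently in the same
  direction"; `absolute = TRUE` answers "where is loading magnitude
  concentrated" and is the right lens for variance-localisation questions
  such as posterior vs anterior concentration of a random-sign template.
* **Decoding.** L2-penalised logistic regression over eight log-spaced
  penalties (1e−4..1e4); AUC is computed per penalty from assembled
  leave-one-trial-out scores and averaged across penalties. Scores are the
  linear term *without* the intercept: the intercept is constant within a
  fold, and under leave-one-out it carries an anti-correlated class
  imbalance artifact that biases pooled AUC far below chance at strong
  penalties. Imputation and PCA are refitted inside every training fold by
  default; `fit_once = TRUE` reproduces the simpler fit-once pipeline.
  Classification features are the spectral features averaged over
  [250, 450) ms.
* **Predictive decoding.** For each held-out community, classifiers are
  trained on inner-node epochs of the other two communities (swap-affected
  trials excluded) and tested on the held-out community's learned-boundary
  epochs, restricted to visits where the same boundary node was not seen in
  the previous two trials; training and testing use the same 100 ms window
  (50 ms steps) and the window-averaged whole epoch. AUCs are averaged over
  penalties and the three rotations. Group timecourses are tested per
  window with one-sample t tests under Benjamini–Hochberg FDR
  (`decode_window_test()`). For onset localisation the package uses the
  half-maximum latency of the group-mean timecourse, which proved far more
  stable at small group sizes than the first FDR-significant window.
* **Pattern similarity.** Inner-node pairs at lag 3 within a Hamiltonian
  block, excluding swap-involved endpoints and — by default — any pair whose
  closed span contains a parse response (the strictest reading;
  `parse_filter = "endpoints"` offers the permissive one). Pearson r over
  retained PC scores, Fisher z with |r| clipped to 1 − 1e−10 before
  `atanh`. The boundary-position contrast compares epochs of the two true
  boundary items against epochs of a true boundary item and the swapped-in
  item occupying the other boundary position (i.e. boundary-node visits
  during the manipulated block, which display the inner partner's
  stimulus).
* **Behaviour.** d′ uses the log-linear correction (0.5 added to every
  cell) uniformly, keeping perfect scores finite. Both response modes are
  pooled for analysis with the mode kept as a column.

## Test and acceptance problem sizes

The validation suite runs everything at reduced scale; sizes were fixed as
design choices alongside the generator defaults:

* Sequence statistics: 100 parsing sequences of 1,200 trials and 100
  exposure sequences of 1,400 trials.
* Null calibration: decoding nulls at 20 seeds × 1,000 trials × 16
  features; window-FDR nulls over 100 runs of 3 simulated participants
  (120 trials, 8 channels, 100 Hz, 6 frequencies 4–30 Hz) with predictive
  mixing zeroed — the clean-run fraction is compared with the nominal 95%
  within two binomial standard errors, the package's calibration
  convention; parametric false-positive rates over 200–500 simulated
  datasets.
* Parameter recovery: P300 gaps from 6 participants × 300 trials per
  condition, with shuffled condition labels (a periodic label order would
  alias slow 1/f noise into condition differences) and the expectation taken
  from an effect-free run of the same filtering chain; topography from 8 participants × 240 trials at 16 channels;
  activation-pattern recovery at n = 2,000 trials; onset localisation from
  8 participants × 300 trials; run-length and community-similarity
  direction over 200 single-participant sessions each (300 trials / 8
  channels and 240 trials / 12 channels with theta-plus-broadband feature
  sets). For the two direction checks, "power" is the fraction of
  participants recovering the planted direction, which must exceed 0.8;
  sessions lacking a condition (for example no learned-boundary pair
  surviving the parse filter) are excluded and their fraction is bounded in
  the same test.

## Known limitations

* The FastICA component count equals the scalp channel count; in
  low-channel simulations the z = 3 rule is structurally unable to fire.
* Directions inside a Gaussian-noise subspace are rotation-indeterminate
  for ICA; only genuinely non-Gaussian sources (blinks, spikes) have stable
  components. This matches ICA theory, not an implementation quirk.
* Predictive-decoding nulls can sit slightly above 0.5,
  because 1/f autocorrelation leaks between temporally adjacent
  training and test epochs; the same structure is inherent in the emulated
  design, and the permuted-label control carries the same bias, which is
  why controls are compared against that null rather than against 0.5
  blindly.
* The simulator's community code is stationary within a session; learning
  dynamics across the exposure phase are not modelled, and exposure-phase
  EEG is not analysed.
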