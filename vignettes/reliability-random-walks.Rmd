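---
title: "Random-walk models of evolving reliability judgements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk models of evolving reliability judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reliwalk)
```

## The problem

When a person interacts repeatedly with an AI system — here, an image
classifier that mostly agrees with them but occasionally contradicts them —
their judgement of the system's reliability evolves. `reliwalk` models that
evolution on a discrete reliability scale with $n = 11$ levels
$x \in \{0, \dots, 10\}$ (0 = totally unreliable, 10 = fully reliable),
obtained by binning a 0–100 slider rating into bins of width 9 with
everything at or above 90 mapped to level 10 (`map_rating_to_state()`).
Two families of dynamics compete:

* a **continuous-time Markov birth–death chain**, in which the person
  occupies a *definite* reliability level at every instant and hops only
  between neighbouring levels, and
* a **quantum walk**, in which the state is a *superposed* amplitude
  vector over all levels until a rating is elicited; elicitation reads out
  probabilities via the Born rule.

The package also ships everything needed to exercise the comparison without
access to behavioural data: a synthetic Wizard-of-Oz session generator and a
simplified event-related-potential (ERP) stage for the accompanying
EEG question (is there a neural signature when reliability is perturbed?).

## Markov dynamics

The chain's generator is the tridiagonal intensity matrix $K$ built by
`build_intensity_matrix()`: the upward rate $\beta_+$ (default 0.6) moves
expectation one level up, the downward rate $\beta_-$ (default 0.4) one
level down, and the self-intensity $\alpha = \beta_+ + \beta_-$ (so 1.0 at
the defaults) is the total rate of leaving the current level. We orient $K$
for column-vector evolution: the probability vector $\phi(t)$ obeys the
Kolmogorov forward equation $\mathrm d\phi/\mathrm dt = K\phi$, solved as
$\phi(t) = e^{tK}\phi(0)$ (`evolve_markov()`, dense Padé matrix
exponential). Each column of $K$ sums to zero, which is what conservation
of probability under this equation requires; at the boundary levels the
out-of-range flow is dropped and the diagonal adjusted to $-\beta_+$ and
$-\beta_-$ (reflecting boundaries), since a uniform $-\alpha$ diagonal
cannot conserve probability at the edges of the scale. The long-time limit
is the detailed-balance stationary distribution
$\pi_i \propto (\beta_+/\beta_-)^i$ (`markov_stationary()`).

## Quantum dynamics

The wave state $\psi(t)$ evolves unitarily, $\psi(t) = e^{-itH}\psi(0)$
(`evolve_quantum()`, exact symmetric eigendecomposition), under a real
symmetric Hamiltonian built by `build_hamiltonian()`:

* diagonal potential $\mu_x = \mu\,x$ with slope $\mu = 0.05$ — the
  scripted agreement of the system accrues "energy" towards higher
  reliability levels linearly;
* nearest-neighbour coupling $\sigma^2 = 0.7$ — amplitude diffuses to
  adjacent levels, the wave analogue of the chain's neighbour hops (the
  symbol is conventional; the value 0.7 is the literal matrix entry, not a
  square root);
* a **corner coupling** $z = 0.2$ between the two extreme levels
  $H_{0,n-1} = H_{n-1,0} = z$, which opens a direct channel between "fully
  reliable" and "totally unreliable" — a brittle judgement can collapse in
  one step without traversing the intermediate levels. For $n = 2$ the
  corner pair coincides with the neighbour pair, so $z$ is applied only
  for $n > 2$.

Amplitudes are stored as complex numbers even though all inputs are real:
$e^{-itH}$ of a real matrix is complex-valued, and report probabilities are
squared moduli (`born_probabilities()`).

```{r hamiltonian}
H <- build_hamiltonian(hamiltonian_params(0.05, 0.7, 0.2), state_space(11))
round(H$H[1:4, 1:4], 2)
```

## Initial states

Two constructions are supported (`uniform_initial()`,
`weighted_initial()`). The uniform state spreads weight equally — the
agnostic choice, identical for every participant. The weighted state
centres a fixed 7-point stencil on the level mapped from the participant's
post-practice rating: probabilities
$(0.025, 0.0625, 0.17, 0.5, 0.17, 0.0625, 0.025)$ for the chain and
amplitudes $(0.17, 0.24, 0.41, 0.71, 0.41, 0.24, 0.17)$ for the wave, zero
beyond three neighbours. The raw stencils do not normalise exactly (the
probabilities sum to 1.015, the squared amplitudes to 1.0133); both
dynamics presume normalised states, so by default the vectors are rescaled
before evolution, and `normalize = FALSE` returns the raw stencil verbatim.
Near the edges of the scale the stencil is truncated and renormalised —
the simplest rule consistent with "zero beyond the three nearest
neighbours". Whether the stencils were meant to be renormalised before use
is genuinely open; we renormalise because the conservation invariants are
otherwise unverifiable.

## Scoring the models

`predict_trajectory()` evolves one initial state across a schedule of
times and records the predicted distribution at each; the point prediction
is the expected level $\sum_i i\,P(R = i)$ by default (smooth trajectories)
with the modal level available as an alternative readout.
`compare_models()` maps model time to the session as
$t = \text{trial index} \times \text{time scale}$ (default 1 per trial, a
free parameter — nothing in the design pins model time to wall time),
places each block's rating at its last trial, and scores both models by
RMSE between point predictions and observed (binned) states over blocks
1…20; the block-0 rating anchors the weighted initial state and is not
scored. There is no likelihood or fitting machinery here by design — the
comparison is purely predictive, parameters fixed in advance.

## The synthetic session

`generate_session()` emulates the study design exactly: 20 blocks × 28
trials, per-block counts of 21 match / 7 mismatch trials shuffled within
block, a manifest of 294 real + 294 AI-synthesised face identifiers each
shown at most once with a 50/50 presentation balance, and lognormal
reaction times (mean 0.8 s, SD 0.3 s — typical two-alternative
forced-choice values) truncated at the 2 s response deadline, beyond which
the trial is a timeout with no AI feedback. Participant classification
accuracy is deliberately not modelled: the Wizard-of-Oz manipulation
scripts agreement independently of correctness.

`generate_rating_trajectory()` is a *generator device*, not a cognitive
model: ratings follow a damped cosine,
$r(b) = a + (r_0 - a + A\cos(2\pi b/T))e^{-\lambda b} + \varepsilon$,
emulating the qualitative pattern of early oscillation that settles as
interactions accumulate. Defaults: start 50% (maximal uncertainty),
asymptote 75% (the scripted agreement rate, towards which a well-calibrated
judgement should drift), amplitude 15%, period 5 blocks, damping 0.15 per
block, noise SD 3%. A 50-replicate refit study (frozen in the tests)
recovers the asymptote to ~1.3% median relative error; the damping rate,
identified only through the decaying envelope of 21 noisy points, carries
~12% error under these conditions.

`generate_epochs()` builds feedback-locked EEG epochs: per condition, a sum
of Gaussian-bump components projected onto scalp regions of a 16-channel
10–20 montage plus white noise (default SD 5 µV). The default template has
an early occipital visual response (150 ms, 3 µV, both conditions), a
central P3-like positivity at 376 ms — 4 µV on frequent match trials, 8 µV
on rare mismatch trials, the oddball signature — and a mismatch-only 268 ms
central negativity. White noise is a deliberate simplification: real EEG
has 1/f background, ocular and muscle artifacts, and inter-trial latency
jitter, so passing recovery tests here demonstrates pipeline correctness,
not robustness to real recordings.

## The ERP stage

The pipeline operates on already-clean epochs (the upstream cleaning chain
— filtering, line-noise removal, ICA, artifact-subspace reconstruction,
re-referencing — is standard published-tool territory and out of scope).
`reject_trials()` drops trials exceeding 100 µV peak-to-peak on any channel
("large voltage changes" reads as range; an absolute mode is available) and
trials without a timely response. `baseline_correct()` subtracts each
trial's mean over its own 600 ms fixation baseline: the baseline is
anchored to the fixation period preceding the image, whose offset from the
feedback event varies with reaction time, so the window is carried per
trial. With epochs starting 1300 ms before feedback, the full 600 ms
fixation window only fits for reaction times ≤ 0.4 s; when it would
underflow, the generator shifts it right to the epoch start — the corrected
window is still pre-event and signal-free in the synthetic data.
`average_by_condition()` produces per-channel condition means, the
match − mismatch difference wave, and region averages over an editable
channel→region map (region membership is not standardised; the default is
a reasonable 10–20 assignment). `peak_latency()` reports sample-aligned
extrema (no interpolation — 4 ms resolution at 250 Hz, matching how such
latencies are conventionally reported).

One sampling convention: the default window (−1300, +950) ms at 250 Hz is
not an integer number of sampling intervals, so epochs carry samples at
$t_k = -1300 + 4k$ ms for $k = 0,\dots,562$ (last sample 948 ms).

## Numerical choices

* Markov propagation: dense Padé `expm`; repeated schedule steps reuse a
  cached per-interval propagator. Conservation holds to 1e−9 by
  construction and is enforced by tests at that tolerance.
* Quantum propagation: symmetric eigendecomposition — exactly unitary up
  to round-off, verified against fixed-step RK4 integration of the
  Schrödinger equation at step 1e−4.
* Tiny negative probabilities from exponentiation round-off (> −1e−12)
  are clipped to zero.
* Rating bins are half-open, $[9k, 9(k+1))$, closed at 100 — consistent
  with describing the bins by their two-decimal endpoints (e.g. 17.99).
* Ties in modal readout break towards the lower level.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is bitwise
reproducible. The shipped analyses use the full 560-trial session; the
test suite favours smaller sessions (4–10 blocks) and 1000-replicate
conservation sweeps, sizes chosen so the whole suite illustrates the
properties at desk scale. A full session of 16-channel epochs occupies
~40 MB in memory and is generated on demand rather than stored.

## Known limitations

* Model time is only conventionally linked to trials; RMSE comparisons are
  sensitive to the time scale, which is a free parameter here as it is in
  the design it reproduces.
* The state does not collapse and restart after each rating: one
  continuous evolution spans the session. Measurement-collapse dynamics
  and open-system (Lindblad) damping — the natural account of oscillations
  that die out — are out of scope.
* The rating generator's damped cosine and the white-noise EEG are
  emulators of described patterns, not validated models of either.
* The 5-level exposition scale is supported through generic $n$, but the
  rating binning is calibrated to $n = 11$ only.
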