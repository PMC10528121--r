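# reliwalk

Quantum and Markov random-walk models of how a person's judgement of an AI
system's reliability evolves over repeated interactions, together with a
synthetic Wizard-of-Oz experiment generator and a simplified event-related
potential (ERP) pipeline for the accompanying EEG question.

## The science in brief

Reliability judgements live on a discrete scale with $n = 11$ levels
$x \in \{0,\dots,10\}$; slider ratings on 0–100 are binned onto it (width-9
bins, ratings ≥ 90 → level 10). Two dynamics compete to predict the
block-by-block ratings:

* **Markov birth–death chain** — a definite state hopping between
  neighbouring levels under the intensity matrix $K$ (upward rate
  $\beta_+ = 0.6$, downward rate $\beta_- = 0.4$, self-intensity
  $\alpha = \beta_+ + \beta_- = 1$), evolving by the Kolmogorov forward
  equation $\phi(t) = e^{tK}\phi(0)$.
* **Quantum walk** — a superposed amplitude vector evolving unitarily,
  $\psi(t) = e^{-itH}\psi(0)$, under a symmetric Hamiltonian with linear
  potential $\mu_x = 0.05x$, neighbour coupling $\sigma^2 = 0.7$ and a
  corner coupling $z = 0.2$ linking the two extreme levels (abrupt
  collapse of high reliability expectations); ratings read out by the
  Born rule $P(R = i) = |\psi_i|^2$.

Both start from the same initial state — uniform, or a 7-point stencil
centred on the participant's post-practice rating — and are scored by RMSE
between predicted and observed states at block ends. The synthetic session
reproduces the study design (20 blocks × 28 trials, 75% scripted AI
agreement, 294 + 294 face stimuli); the EEG generator plants a P3-like
central positivity at 376 ms that is larger on rare mismatch trials, which
the ERP stage (rejection > 100 µV, 600 ms fixation baseline, condition
averages, difference wave, sample-aligned peaks) recovers.

## Worked example

```r
library(reliwalk)

space <- state_space(11)
map_rating_to_state(48.9)        # -> 5: a 48.9% rating sits in bin [45, 54)

ratings <- generate_rating_trajectory(rating_params(seed = 20260102L), 20)
cmp <- compare_models(ratings,
                      markov  = intensity_params(0.6, 0.4),
                      quantum = hamiltonian_params(0.05, 0.7, 0.2),
                      init = "weighted")
cmp
#> Model comparison over 20 block ratings (init = weighted, time scale = 1/trial)
#>   Markov RMSE:  1.5316
#>   Quantum RMSE: 0.8872
```

The Markov chain relaxes monotonically towards its stationary distribution
and misses the early oscillation in the ratings; the quantum walk's
wave-like dynamics track it, hence the lower RMSE on this synthetic
session. Running the numbered drivers reproduces the full analysis:

```sh
Rscript analysis/01_simulate_session.R   # session, ratings -> results/
Rscript analysis/02_model_comparison.R   # RMSE table, trajectories
Rscript analysis/03_erp_analysis.R       # region ERPs, peak table
```

Step 3 prints, for the default 5 µV-noise session:

```
Central P3: match 4.13 uV @ 380 ms, mismatch 8.23 uV @ 380 ms
  -> difference trough -4.18 uV @ 392 ms.
```

— the rare-condition positivity is twice the frequent-condition one, the
classic oddball signature, recovered within one sample of the planted
latency.

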