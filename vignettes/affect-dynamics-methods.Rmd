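---
title: "Quantifying affect dynamics from heart rate variability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying affect dynamics from heart rate variability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectdyn)
```

## The model

Affect dynamics — how a person moves between emotional states over time —
is modelled here as a discrete-time, discrete-space Markov chain over the
four quadrants of the valence–arousal circumplex: stress (A: high arousal,
negative valence), engagement (B: high arousal, positive), boredom (C: low
arousal, negative) and relaxation (D: low arousal, positive). The chain's
transition matrix is not observed directly; it is *measured
physiologically*, by quantifying vagally mediated short-term heart rate
variability around experimentally induced transitions between the
quadrants.

The physiological index is RMSSD, the root mean square of successive
RR-interval differences over $N$ beats:

$$\mathrm{RMSSD} = \sqrt{\tfrac{1}{N-1}\sum_{i=1}^{N-1}(RR_{i+1}-RR_i)^2},$$

in milliseconds. RMSSD is the standard ultra-short-term index of
parasympathetic (vagal) modulation and remains valid in windows as short
as tens of seconds, which is what makes a per-transition measurement
possible at all.

### From RMSSD to probabilities ("Markovization")

One RMSSD value is computed for each of the 16 cells of the $4\times4$
(from, to) matrix — 12 transition windows and 4 self windows. Row $i$ of
the raw matrix is then divided by its sum:

$$P_{ij} = \frac{\mathrm{RMSSD}_{ij}}{\sum_k \mathrm{RMSSD}_{ik}},$$

giving a row-stochastic matrix. The reading is relative: within each
origin state, the share of short-term cardiac reactivity directed toward
each destination is interpreted as the probability of that affective
transition. Markovization is invariant to rescaling any row by a positive
constant, so only the *pattern* of variability within a row matters, not
its absolute level — an individual with globally high or low HRV is not
advantaged.

Descriptive indexes group the 16 probabilities by the geometry of the
circumplex: **vertical** (AC, CA, BD, DB — same valence, arousal flips),
**horizontal** (AB, BA, CD, DC — same arousal, valence flips), **oblique**
(AD, DA, BC, CB — both flip) and **self** (the diagonal). The predictive
index is the steady state $\pi$ with $\pi P = \pi$, computed two ways:
ten-step power iteration from the equiprobable initial vector
$\pi_0 = (0.25, 0.25, 0.25, 0.25)$, which mirrors the clinical question
"after ten hypothetical emotional shifts, where does the patient live?",
and the left-eigenvector method, which is the exact stationary
distribution and serves as the reference. On irreducible, aperiodic
chains the two agree; reducibility or periodicity (numerically, a second
eigenvalue of modulus one) is treated as an error rather than answered
arbitrarily.

## The experimental schedule

The protocol that makes the measurement possible is a block design:
13 blocks of 120 s, each showing 12 affect-inducing images for 10 s
(1560 s of stimulation, 156 images), preceded and followed by 120-s
fixation baselines. The 12 consecutive block pairs must realize each of
the 12 directed transitions between distinct quadrants exactly once —
i.e. the block order is an Eulerian circuit on the complete directed
graph over four nodes. Since every node there has in-degree = out-degree
= 3, a circuit always exists; `generate_schedule()` samples one by a
randomized Hierholzer traversal, reproducibly from a seed. The published
protocol does not fix a particular block order, only the
all-transitions-once property, so any valid circuit is an equally
faithful realization; seeding makes a session reproducible.

Stimuli are classified into quadrants from their normative SAM ratings
(9-point scale): a dimension is high above 6 and low below 4, strict
inequalities, and anything in the `[4, 6]` band on either dimension is
excluded. Ratings exactly on a cut are excluded too — the selection rule
is deliberately conservative because ambiguous stimuli dilute the
induction. Image files themselves (e.g. IAPS) are never bundled or
touched; only identifiers and ratings flow through the package.

Analysis windows are 30 s wide: transition windows straddle each block
boundary ($120k \pm 15$ s after first-stimulus onset), and each state's
self window is centred at the midpoint ($60 \pm 15$ s) of its
*first-occurring* block, where the state is freshly induced and not yet
contaminated by habituation. Repeat blocks of a state contribute no self
window. Window membership of a beat uses the terminating beat time and
the half-open interval $[t_\mathrm{start}, t_\mathrm{end})$, so a beat on
a shared boundary is counted once. With defaults, the 16 windows tile the
16 matrix cells exactly once and transition windows never overlap; a
half-width of 60 s or more would make them overlap and is rejected.

## Signal handling choices

**Artifact correction.** Ectopic beats and missed detections corrupt
RMSSD badly because they create huge successive differences. Correction
is automated and reproducible: an interval is flagged when it deviates
from the median of its 11-beat neighbourhood (five beats each side,
itself excluded) by more than a named threshold level — `very_low` 450,
`low` 350, `medium` 250, `strong` 150, `very_strong` 50 ms — and flagged
intervals are replaced by linear interpolation between the nearest
unflagged neighbours, in the interval domain. Unflagged intervals are
returned bit-identical, matching the requirement that correction removes
artifacts without distorting normal RR intervals. The five-level
threshold ladder is a convention of HRV practice, adopted here so that
what is often a visual-inspection step becomes automatic; the mapping is
documented as such and the level is a parameter. Correction is idempotent
at a fixed level, and a series in which *every* interval is flagged is
refused rather than invented.

**Windowing.** A window must contain at least `min_intervals = 3`
intervals; RMSSD from a single difference is statistically meaningless.
With the default profile (mean RR 800 ms) a 30-s window holds ~37 beats,
giving a relative standard error of roughly $1/\sqrt{2N} \approx 12\%$
per window — the noise floor that the recovery experiment quantifies.

**Rounded published matrices.** Probability matrices printed to two
decimals have rows summing to 0.99–1.00. `as_transition_matrix()`
accepts row sums within ±0.02 and by default renormalizes. One subtlety
is documented rather than hidden: a published ten-step steady state
computed from such a matrix without renormalizing yields a final vector
summing to ~0.96, and its components differ from the
renormalized-matrix answer by up to ~0.01. Both behaviours are
available (`renormalize = FALSE` on `as_transition_matrix()` and
`steady_state_power()`), and reproducing figures computed from printed
values requires the raw variant; the eigen method on the renormalized
matrix is the reference for the true stationary distribution.

## The synthetic-data generator

`simulate_rr()` exists so the whole pipeline is testable end to end with
no recordings. It emulates exactly the statistical structure the method
assumes — window-specific short-term variability — and nothing more: each
interval is an independent Gaussian level
$RR_i = \mathrm{clip}(\mu + e_i)$, $e_i \sim N(0, \sigma(t)^2/2)$, where
$\sigma(t)$ is the RMSSD target of the window the beat falls in (default
baseline 30 ms outside windows, mean RR 800 ms, clip bounds 300–2000 ms).
Independent levels with variance $\sigma^2/2$ give successive differences
variance $\sigma^2$, so the expected RMSSD of a window equals its target
analytically — which is what parameter-recovery testing needs. The
generator was chosen over an AR(1) or point-process heart model precisely
for this controllability; it deliberately does *not* reproduce
respiratory sinus arrhythmia, autocorrelation, non-stationarity or
circadian drift, so passing recovery tests demonstrate correctness of the
pipeline's accounting, not robustness to physiological structure beyond
the model. Clipping bias is negligible for targets up to ~100 ms at a
mean of 800 ms.

Artifact injection mirrors the two canonical beat-detection failures:
`ectopic_split` turns one interval into a premature $0.4RR/0.6RR$ pair
and `missed_merge` fuses two adjacent intervals; both preserve total
recording duration exactly, so injected series stay aligned with the
protocol timeline.

## Problem sizes and numerical tolerances

The validation suite uses sizes chosen to make Monte Carlo summaries
stable: 1000 random matrices for the row-stochasticity property (row sums
within $10^{-9}$ of 1), 200 strictly positive chains for power/eigen
agreement (within $10^{-6}$ per entry), 50 replicate simulated sessions
for parameter recovery (median absolute cell error $\le 0.06$, comfortably
above the ~0.03 the window-level noise floor predicts), and 100
replicates for the artifact-robustness comparison, where a
ratio-of-medians estimator needs more replicates than a median alone —
at that size the per-cell error under 2% injected artifacts with
`medium` correction stays within 1.5× of the artifact-free error, and
the asymptotic ratio is ~1.3. Simulated sessions share one schedule, as
replicate sessions of one participant would.

## Known limitations

* The method is idiographic by design: one recording yields one matrix,
  and no inferential machinery (confidence intervals on $P_{ij}$,
  hypothesis tests between patients) is provided or implied.
* Markovization reads *variability shares* as probabilities; this is an
  operational definition, and its construct validity rests on the link
  between vagal reactivity and affective transition, not on anything the
  package can check.
* The artifact threshold ladder is a convention; recordings with dense
  artifacts (>~5%) should be inspected rather than trusted to
  interpolation.
* Self-transition variability is measured once per state (first block
  only), so the diagonal rests on fewer data than the off-diagonal cells.
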