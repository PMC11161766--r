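---
title: "Phase coding of spoken-word categorization: model and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase coding of spoken-word categorization: model and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasecode)
```

## The scientific problem

When an ambiguous spoken word can be heard as either of two Dutch words
(e.g. a morph between */xɑt/* "gat" and */dɑt/* "dat"), the interpretation
listeners report depends on the moment — the oscillatory phase — at which
the stimulus arrives. `phasecode` implements a mechanistic account of this
phase code and the full statistical machinery needed to detect it in
behavior and in region-of-interest neural time series.

The core hypothesis is an *excitability-ordering* principle: linguistic
units that are frequent in the language (probable "events") are represented
by neural populations with higher sensitivity, which therefore reach their
activation threshold at less excitable oscillatory phases than populations
coding rare units. An ambiguous stimulus is then resolved differently
depending on its arrival phase.

## The node model

The model has an input level (the four study words /xɑt/, /dɑt/, /xat/,
/dat/ plus an "empty" node used for entrainment trains), a phoneme level
(/x/, /d/, /ɑ/, /a/, empty) and a word level. At every millisecond the
activation of node $j$ at level $l$ is

$$A_{l,j}(t) = \big[C_{l-1 \to l}^\top\, A_{l-1}(t)\big]_j
  + P(T^a_j) + A_{\mathrm{osc}} \cos(2\pi f t + \phi_0),$$

the sum of connectivity-weighted input from the level below, a
post-activation term $P$, and a global excitability oscillation (default
$f = 6.25$ Hz, $A_{\mathrm{osc}} = 1$). Input-to-phoneme connectivity is 1
where the phoneme belongs to the word; input-to-word connectivity is the
identity (a hierarchical variant instead drives words from the phoneme
level through the same membership matrix).

$P$ depends on the time $T^a$ since the node last reached threshold, with
base inhibition $B = -0.2$:

$$P(T^a) = \begin{cases}
 -3B & 0 \le T^a < 20 \text{ ms (excitatory burst)}\\
 +3B & 20 \le T^a \le 100 \text{ ms (self-inhibition)}\\
 B & \text{otherwise, including never-activated nodes.}
\end{cases}$$

The window boundaries are configurable; we take the burst half-open on the
right and the inhibition window closed, so the three branches tile
$[0,\infty)$. Self-inhibition is essential: without it the more sensitive
node would win at every phase and no phase code could arise.

*Sensitivity* implements event probability: units whose trait is frequent
(consonant /d/, vowel /ɑ/, words /dɑt/ and /xat/, following the corpus log
frequencies) have their threshold lowered from 1 by the *threshold
reduction* $r \in [0, 0.5]$. With the default calibration
($A_{\mathrm{osc}} = 1$, $B = -0.2$) a reduced-threshold node fires
spontaneously once per cycle just before the oscillation peak whenever
$A_{\mathrm{osc}} + B \ge 1 - r$, i.e. for $r \ge 0.2$. The ensuing
refractory period is what allows the *rare* interpretation to win when a
stimulus lands shortly after the peak — the mechanism that converts
sensitivity differences into a phase code.

The categorization readout takes, separately per level, the candidate node
that crosses threshold first at or after probe onset within a decision
window of two oscillator cycles; simultaneous crossings are resolved by the
stronger activation, and exact ties or windows without crossings are
guesses (0.5 in the deterministic psychophysics protocol, a seeded random
0/1 in the trial-level protocol). Activations of simultaneous crossings
that differ by less than $10^{-6}$ are treated as ties so that knife-edge
symmetric races are not decided by floating-point residue.

### Numerical and design choices

- **Integration**: 1 ms Euler steps; stimuli are 80 ms rectangular pulses
  (half a 6.25 Hz cycle) in `stable` mode, or ramps from 0 to peak
  (`linear_ramp`) for the low-power variant.
- **Oscillation form**: the cosine convention with peak at $t = 0$;
  entrainment trains (five empty-word events at 6.25 Hz, a stimulus
  property kept fixed when the internal oscillator frequency is varied)
  start on a peak, so SOA maps to phase through
  $\phi = 2\pi f \cdot \mathrm{SOA}$.
- **Decision window**: two oscillator cycles. At least one full cycle is
  needed so a spontaneous firing of the sensitive node can serve as the
  response when the pulse itself drives nothing across threshold.
- **Most ambiguous morph**: the psychometric sweep presents each of 10
  morph levels at 16 phases spanning one cycle; a least-squares logistic
  fit gives the 50% point, and the entrainment/random-phase probes use
  that *continuous* midpoint. Snapping to the nearest discrete morph level
  was rejected: the 10-level grid does not contain 0.5, and for spectra
  whose two traits have opposed frequencies the flat (cancelling) response
  exists only at the exactly symmetric morph.
- **Level averaging**: the combined behavioral output averages the phoneme-
  and word-level values per presentation, then across presentations;
  guesses enter as 0.5 before averaging.

## The statistics chain

**Behavioral sinusoid test.** Response proportions per participant and SOA
are demeaned within participant and averaged; a fixed-frequency sinusoid
(regressors $\sin$, $\cos$ and an intercept, which is not redundant on a
finite SOA grid) is fit by least squares, and its $r^2$ is compared with a
null built by shuffling SOA labels independently within each participant
(default 10,000 permutations; add-one p-value rule). The split-half
comparison applies the same fit to each half of the experiment and
permutes half labels within participant.

**Time-frequency phase.** Single-trial phases come from complex Morlet
wavelets (5 cycles; Gaussian SD $n_c / 2\pi f$), on a default grid of
1–15 Hz in 1 Hz steps and −0.5–0 s in 20 ms steps; grid points whose
wavelet support (±2.5 SD) leaves the epoch are flagged missing rather than
padded.

**Phase–behavior coupling.** Per participant and grid point, a logistic
regression of the binary response on $\sin\phi$ and $\cos\phi$ gives the
effect magnitude $\sqrt{\beta_s^2 + \beta_c^2}$ and preferred phase
$\mathrm{atan2}(\beta_s, \beta_c)$. The magnitude is positively biased
under the null, so each participant's map is centered by subtracting its
mean over 20 within-participant response permutations. The group test is a
one-sample $t$ across participants on the centered maps, cluster-corrected:
contiguous points (4-neighborhood) with one-sided pointwise $p < 0.05$ form
clusters scored by their summed $t$; the max-cluster null comes from random
sign flips of whole participant maps — the label exchange of a one-sample
design. The final phase readout (circular mean phase differences against
the reference word, directed v-tests $V = n\bar R\cos(\bar\theta - \mu)$
with the one-sided normal approximation, and the product rule for
combining the three per-word probabilities) is implemented exactly as
described, including the deliberately uncorrected product.

## What the synthetic data emulate — and what they do not

`generate_behavioral_dataset()` draws Bernoulli responses whose probability
follows a sinusoid across SOA (defaults: 18 participants, 12 SOAs from 0.1
to 0.42 s, 40 trials per cell, common modulation phase). It emulates the
design and the assumed data-generating process, not human response biases,
lapses, learning or serial dependence; passing calibration here shows the
test is statistically sound, not that real effects of a given size exist.

`generate_neural_dataset()` builds per-trial ROI time series as 1/f noise
(spectral exponent 1) plus a 10 Hz background oscillation and, in streams
that carry an effect, a Gaussian-windowed oscillatory burst (SD 0.15 s) at
the effect frequency whose per-trial phase drives the response through
$P(\text{resp}) = \sigma(\beta\cos(\phi - \phi_0))$, with the preferred
phase $\phi_0$ fixed within and uniform across participants. A burst, not
a stationary component, is used because a stationary oscillation's phase at
*any* latency predicts its phase at the effect latency, which would smear
the effect over the whole prestimulus window. Defaults (20 participants,
200 trials, 100 Hz sampling, epochs −3.2–2.0 s so 5-cycle wavelets at 1 Hz
have full support over the analysis window) mirror the scale of the MEG
design. Not emulated: sensor physics, source leakage between ROIs,
nonstationary background spectra, artifacts, or between-participant
amplitude differences.

## Validation suites and problem sizes

The shipped checks (test suite and `scripts/acceptance.R`) run at these
sizes, chosen to bound Monte-Carlo error while keeping a desk-scale runtime:
type-I calibration over 1000 null behavioral datasets (199 permutations
each); power at modulation amplitudes 0–0.15 over 300 datasets each;
preferred-phase recovery over 50 seeds at 500 trials; cluster family-wise
error over 500 null map simulations (200 sign flips each); detection of the
injected STG effect over 50 replicates; and the four-cell double
dissociation over 25 replicates (50 mismatched cells). The acceptance
script reports the same quantities at reduced replicate counts.

One calibration property is at the edge of what these designs can resolve:
with 18 participants × 480 trials the sinusoid test's power is already
≈0.995 at modulation amplitude 0.05, so adjacent points of the power curve
can tie at 1 in any feasible number of simulations even though the
underlying power function is strictly increasing.

## Known limitations

- The model is a deliberate abstraction: no acoustic front end, no /t/
  coda, no reaction times, no neural delays — the target is the presence
  or absence of phase-dependent categorization, not quantitative phase
  estimates.
- The oscillator neither resets its phase to stimuli nor couples to input
  rhythm; entrainment is idealized as a fixed phase relation between train
  and oscillation.
- The spontaneous-firing regime depends on the calibration
  $A_{\mathrm{osc}} + B \ge 1 - r$; configurations far from the defaults
  may need recalibration of amplitude or inhibition to show the same
  qualitative pattern.
- Cluster inference gives family-wise control over the tested grid, but
  cluster extents are biased broad when effects leak across wavelet bands;
  locations should be read at cluster, not pixel, resolution.
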