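---
title: "Methods: simulation, classification and kinetics in fretsort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, classification and kinetics in fretsort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fretsort)
```

# The problem

Single-molecule FRET (smFRET) movies yield thousands of per-molecule
intensity traces, of which only a minority are analyzable: one donor and
one acceptor on one surface-attached molecule, alive long enough to watch.
The rest are aggregates, optically mis-colocalized molecule pairs,
hopelessly noisy traces, or photophysical oddities. Historically a human
sorts them; `fretsort` automates the sort with a per-frame sequence
classifier trained purely on simulated data, so that the only subjective
input left is a single confidence threshold.

The package covers the full loop: **simulate** labelled ground-truth
traces; **train** the classifier; **score** traces into a confidence value
with a photobleaching cut; **benchmark** against naive threshold sorting;
and **analyze** accepted traces with a hidden Markov model (HMM).

# The generative model

Each simulated molecule carries `n` FRET states (`n` uniform on 1..4),
with efficiencies drawn uniformly on [0, 1] under a minimum separation of
0.1 so that state transitions are distinguishable from noise. Kinetics are
Markovian: at every frame the molecule jumps to each *other* state with a
per-trace probability drawn uniformly on [0, 0.2] (with four states the
total leave probability can reach 0.6). Ideal unit-intensity channels
follow `DD = 1 - E`, `DA = E`, `AA = 1`, so `DD + DA = 1` exactly and the
ideal stoichiometry is 0.5.

Photophysics: each fluorophore photobleaches at an exponential time with
mean 500 frames (traces last 300 frames, so a sizable fraction never
bleach); donor bleach silences DD and DA while AA persists; acceptor
bleach silences DA and AA and the donor recovers to full unit intensity;
with probability 0.1 the molecule falls off the surface at an
Exponential(500) time, silencing everything. 20% of non-aggregate traces
blink (a zero-truncated Poisson(1) number of events so a "blinking" trace
always contains at least one; exponential mean 5 frames; one fluorophore
at a time). 15% of traces are aggregates of 2-10 independent pairs (summed
channels, independent bleach times), and 15% are "scrambled" artifacts:
with probability 0.9 a mis-colocalized pair of independent molecules
(donor-side channel from one, acceptor-side channels from another),
otherwise a time-flipped channel, a channel replaced by the rescaled
product of two channels, bursts of high-amplitude noise, or long dark
segments. Detection artifacts close the pipeline: AA is scaled by a
uniform 70-130% mismatch, 0-15% of DD bleeds into DA, and every channel
receives Normal(0, sigma) noise with sigma uniform on [0.01, 0.30] (in
units of the maximum single-fluorophore intensity), plus, for 80% of
traces, a centred Gamma(1, 1.1) component scaled by the same sigma to
mimic the skewed tail of shot noise.

Every frame is labelled with one of six classes - bleached (B), aggregate
(A), noisy (N), scrambled (X), static smFRET (S), dynamic smFRET (D).
Labelling decisions that the underlying physics does not fix, and the
choices made here:

* **Bleached onset.** For a single pair, FRET observation ends at the
  *first* bleach of either fluorophore (or fall-off); frames from there on
  are B even when one dye still emits. Aggregates stay A until all their
  signal is gone; scrambled traces stay X until their channels go dark for
  good. This matches how the scoring pipeline truncates traces.
* **Noisy.** smFRET traces with sigma above 0.25 are labelled N on live
  frames; aggregate/scrambled identity takes precedence over noise.
* **Static vs dynamic.** Decided on the observed (pre-bleach) window: a
  multi-state molecule whose transitions all fall after the bleach is
  static "within the experimental time frame".
* **Blinking** keeps the trace class (the classifier learns to ignore
  transient dark states); blink kinetics (Poisson(1) events of mean 5
  frames) are chosen short so blinking is distinguishable from bleaching.

Datasets are class-balanced by the *first-frame* label: traces bleached
from frame 0 are dropped and the five usable classes are under-sampled to
the rarest class. At the default priors the rarest first-frame class is
"noisy" (about 12% of traces), so 250,000 raw traces yield roughly
150,000 balanced ones.

# The classifier

The model maps a normalized trace (each trace divided by its single global
maximum, preserving channel ratios) of shape `frames x channels` (3
channels for ALEX, 2 without) to a `frames x 6` row-stochastic matrix.
Architecture: an initial 1-D convolution; a stack of pre-activation
residual blocks (batch norm, ReLU, convolution, twice; additive skip with
a 1x1 projection where the filter count grows; stride-1 max pooling so
the temporal length is never reduced); a final batch norm + ReLU; a
bidirectional LSTM whose outputs carry global context (a bleaching step
seen anywhere informs every frame); dropout on the LSTM outputs; and a
per-frame dense softmax. In the full-scale recipe (`nn_spec_full()`)
there are 16 blocks with filters 32 doubling to 256 every 4th block and
kernels 16 shrinking by 4 down to 4, with a 16-unit LSTM and 0.4 dropout.

Because no deep-learning framework is available in this toolchain, the
network - forward pass, backpropagation, Adam - is implemented from
scratch in RcppArmadillo and verified against finite-difference gradients
in the test suite. Training follows the published recipe: minibatches of
32, Adam at 0.001, learning rate divided by 10 after two epochs without
validation improvement, early stopping after five, 80/20 train/validation
split by trace, cross-entropy against labels smoothed by 0.05.

**Desk-scale defaults.** Training the full recipe on 150,000 traces takes
CPU-hours. The package's default `nn_spec()` is a reduced model of the
same family (4 blocks, 32 base filters, kernel 12, 32 LSTM units) that
trains in minutes on thousands of traces on one CPU core; compute is
single precision, as in the mainstream deep-learning stacks. Dropout is
lowered to 0.2 in the desk-scale spec: with a 10-100x smaller model the
published 0.4 leaves the network underfitting rather than regularized.
The test suite trains this reduced recipe on a few thousand balanced
traces; a green run therefore establishes that the architecture and
training loop learn the classification task well on the stated generative
world at reduced scale - not that the shipped defaults reproduce the
full-scale published accuracies, which require the full recipe and
dataset.

# Scoring and acceptance

Per-frame probabilities are turned into decisions in three steps.

1. **Bleach cut.** A 7-frame window slides over the bleached-class
   probability; at the first window where at least 4 frames exceed 0.5,
   that frame and everything after is discarded. Truncated end windows
   still require 4 hits, so a single confident frame cannot amputate a
   trace.
2. **Category scores.** Probabilities of the five non-bleached classes
   are summed over live frames and renormalized to sum to one. The
   *smFRET confidence score* is `P_S + P_D`. If bleaching strikes before
   15 frames (or fewer than 15 live frames exist), the trace is classified
   bleached with confidence 0 - a handful of pretty frames must not
   inflate the score.
3. **Decision.** Accept when the confidence reaches the user threshold
   (inclusive, `>=`); 0.85 is the recommended default. The assigned class
   is the argmax of the five scores; static and dynamic both count as
   smFRET.

One distinction worth keeping straight: the 15-frame minimum is a guard
of the *acceptance pipeline* - it stops a handful of good-looking frames
from inflating the confidence score. When the question is instead "what
does the classifier think this trace is" (per-trace confusion matrices),
the natural per-trace class is the argmax of the live-frame category
scores with no length veto; `category_scores(..., min_live = 1)` gives
that reading, and the test suite evaluates trace-level accuracy this way.

# The baseline sorter and the benchmark

The pre-learning acceptance rule the classifier is measured against:
remove photobleached frames with the same 4-of-7 window applied to
stoichiometry outside (0.3, 0.7); accept when the median live-frame
stoichiometry is inside (0.3, 0.7), a bleach was found, and the maximum
single-molecule intensity (total donor-excited emission `DD + DA`, the
standard choice because it is invariant to the FRET state) falls inside a
bounds window. Since published intensity bounds are not available, the
benchmark sweeps a fixed grid of windows - lower bounds 0 to 1.4, widths
0.3 to unbounded - and reports the best case (maximum precision, ties to
recall).

The benchmark population is 200 dynamic two-state molecules (FRET
0.3/0.7, transition probability 0.1 per frame, sigma 0.11, 5%
bleedthrough, mismatch 70-130%, non-bleaching molecules discarded) mixed
with 5000 contaminants drawn from the full training priors and kept only
when their ground-truth class is aggregate, noisy or scrambled. On this
mixture simple thresholding tops out around precision 0.2 at recall 0.4:
mis-colocalized molecule pairs produce intermediate stoichiometries and
single-molecule-like intensities, and no stoichiometry/intensity window
separates them from genuine smFRET.

# Kinetics

Accepted traces are idealized with a per-trace Gaussian-emission HMM
fitted by Baum-Welch, observing either the 1-D FRET efficiency series or
the 2-D (DD, DA) channels (diagonal covariance). Initialization is
deterministic (contiguous rank groups of the observations seed the K
means), so fits are exactly reproducible. The state count is chosen by
BIC, `-2 logL + p log n` with `p = K(K-1) + 2Kd + (K-1)`, ties toward
fewer states; a post-hoc merge collapses states whose means are closer
than 0.05 FRET with overlapping uncertainty. Dwell times come from the
Viterbi path; the final dwell of every trace is right-censored and
excluded from the per-state exponential lifetime MLE; transition-density
pairs (mean FRET before vs after each transition) support TDP plots.
Per-trace fitting (rather than a global shared-parameter HMM) was chosen
because heterogeneity between molecules is itself a quantity of interest;
a global fit is a possible extension.

# Numerical choices and degenerate inputs

* E and S are reported as `NA` wherever their denominators are not
  strictly positive (post-bleach frames), never as exceptions.
* `normalize_trace()` refuses all-nonpositive traces - there is no signal
  to scale.
* EM uses scaled forward-backward; emission variances are floored at
  1e-8; fits require at least K + 2 live frames.
* The window scans return the *window start*: frames between the start
  and the first confident bleached frame are sacrificed deliberately.
* All frame indices are 1-based inside R; exported text files use 0-based
  frame columns (documented in `write_traces()`).
* Per-trace RNG seeds derive from the dataset seed by a counter, so any
  single trace can be regenerated without replaying the whole dataset.

# Known limitations

* The simulator emulates background-corrected traces only: no camera
  model, PSF, raw images, or diffusing molecules.
* Scrambled traces are deliberately non-physical; their dark stretches
  overlap the bleached class, which bounds achievable per-frame accuracy
  on that class.
* Gamma-noise "centering" subtracts the mean (1.1), matching a zero-mean
  skewed read; other centerings are conceivable.
* The desk-scale classifier is not the published full-scale model; see
  above for what the tests do and do not establish.
* Correction factors (gamma, crosstalk) can be applied to E before HMM
  fitting but are never estimated here.
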