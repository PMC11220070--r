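---
title: "Context-gated suppression in uncued set-shifting: models and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-gated suppression in uncued set-shifting: models and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxgate)
```

## The problem

In an audio-visual set-shifting task an animal sees a visual grating and
hears a tone on every trial, but only one modality determines whether
licking is rewarded. Which modality is relevant (the *context*) is stable
within a block and switches without any cue, so the context must be
inferred from stimulus-choice-outcome contingencies. Congruent trials
(both modalities instruct the same response) carry no context information;
incongruent trials always do, whatever the outcome.

`ctxgate` implements the full analysis chain for this paradigm on
synthetic data with planted ground truth:

* the task contingency model and the exhaustive five-trial sequence space
  (`task_core`);
* go/no-go behavioural analyses: moving-average consistency segmentation,
  a Monte-Carlo consistency null, Bernoulli choice models, d'
  (`behavior`);
* a synthetic population-recording generator with low-dimensional coding
  subspaces and tunable context-gated suppression (`synthetic_neural`);
* spike-train preprocessing to baseline-standardized instantaneous firing
  rates (`neural_preproc`);
* time-resolved linear decoding and decision-vector geometry
  (`decoding_geometry`);
* single-neuron modality/context indices and their correlation
  (`single_neuron`);
* a gateless recurrent network trained on five-trial sequences, with
  weight-structure and representation analyses (`rnn_model`).

## Task model

Stimuli are binary per modality (go = 1, no-go = 0). A trial is congruent
iff the two stimuli agree; the target is the relevant modality's stimulus.
A training datum for the network is a sequence of five trials sharing one
context: 4 stimulus combinations over 5 trials give `4^5 = 1024` sequences
per context, 2048 total. A sequence whose first four trials are all
congruent and whose final trial is incongruent is unsolvable — no observer
can do better than chance on its final trial — and there are exactly
`2^4 * 2 = 32` such sequences per context (3.125% of the dataset). The
`solvable` flag is checked in the tests against a brute-force ideal
observer that asks whether trials 1-4 identify the context.

Sequences are enumerated lexicographically in the trial-wise
(visual, auditory) codes, so datasets are reproducible without a seed.

## Behavioural analyses

Performance curves are 21-trial equal-weight moving averages computed
separately for the four trial types (go/no-go x congruent/incongruent)
within each context block. A trial is *task-consistent* when all four
curves are at or above chance (0.5). Two conventions appear in the
literature for the threshold ("above" vs "above or equal"); the package
implements `>=` by default with a `strict` switch, since the choice only
matters at exact-0.5 ties.

Edge handling: the moving average uses shrinking windows at block edges
(the mean over the available trials of that type), so the mask is defined
at every trial; between trials of a type the curve carries the last value.
This choice is not dictated by the paradigm — any local average works —
but it avoids undefined segments in short blocks.

The consistency null asks whether the observed number of consistent
trials could arise from a context-unaware strategy: simulated sessions
keep the block's trial sequence, force congruent trials correct and draw
incongruent licks from a Bernoulli distribution at the block's empirical
incongruent lick rate. The Monte-Carlo estimator (default 10^6 sessions)
is validated against exact enumeration over all `2^k` incongruent outcome
vectors on small blocks.

Choice models assign each trial a lick probability: following the correct
or the opposite modality, a context-agnostic constant-rate model, and
context-aware models with an additive bias `beta` or a lapse `lambda`.
All probabilities are clipped to [0.001, 0.999] — so, e.g., a perfectly
performed session has mean log-likelihood `log(0.999)` under the
correct-modality model and `log(0.001)` under the opposite-modality
model. The bias is added before clipping (clip-after-add). Models are
compared by mean log-likelihood on consistent incongruent trials, the
only trials where context-aware and context-unaware strategies separate.
Sensitivity is `d' = qnorm(hit) - qnorm(fa)` with rates clipped to
[0.01, 0.99].

## The synthetic population generator

The generator is the ground-truth instrument for every population
analysis. Expected rates are

```
rate(trial, neuron, t) = baseline
  + sum over v of gain_v * sign_v(trial) * envelope_v(t) * embedding_v[neuron]
```

with variables v in {visual, auditory, context, decision}. Embeddings are
unit vectors in neuron space: random orthonormal directions by default
(with a configurable planted angle between the visual and auditory
directions), or block-disjoint subpopulations in the `disjoint` preset
used by oracle tests. Signs are +1/-1 for go/no-go, visual/auditory
context, lick/no-lick.

Defaults, chosen once as a plausible cortical regime and kept fixed:
60 neurons, trials spanning -1.5 s to 3 s around stimulus onset at
dt = 0.1 s, baseline 5 Hz, stimulus gains 4 Hz, context gain 2 Hz,
decision gain 3 Hz, Gaussian rate noise of 2 Hz (a Poisson-count mode is
provided; both modes produce the same decoder ranking of conditions at
matched signal-to-noise). Stimulus envelopes switch on at stimulus onset
with an exponential ramp (tau = 100 ms); the context signal is tonic —
present through the whole window including the prestimulus period —
matching the observation that context is maintained across trials;
decision-related activity ramps from 0.5 s, and can optionally persist
past the trial to emulate a choice memory trace.

Context-gated suppression multiplies the *irrelevant* modality's gain by
`suppression_gamma` in [0, 1], ramping in after `suppression_onset`
(default 0.25 s, tau 0.5 s): gamma = 1 leaves the two contexts
statistically identical, gamma = 0 silences the irrelevant stimulus after
the initial transient. The generator plants suppression directly; it does
not model the recurrent mechanism that produces it — that is the network
model's job.

What the generator deliberately does not emulate: spiking dynamics and
refractoriness, inter-neuron noise correlations beyond the shared
embeddings, laminar or cell-type structure, slow nonstationarities (drift
is planted explicitly where a test needs it), and reaction-time
variability. Tests passing on this generator therefore certify the
estimators — recovery of planted angles, gains and suppression — not any
claim about real cortical data.

## Preprocessing

Spike events are binned in 10-ms windows and smoothed with a Gaussian
kernel (sigma = 100 ms, truncated at 4 sigma, renormalized; at window
edges the kernel is renormalized over the retained support so no rate
mass is attributed to unobserved time). Rates are standardized per
neuron: the mean is the time-averaged prestimulus baseline (-1.5 to 0 s),
the standard deviation is computed over whole trials and pooled across
trials for stability (the pooling is a package choice; per-trial
deviations are too noisy at realistic trial counts). Zero-variance
neurons are flagged and their divisor replaced by 1.

## Decoding and geometry

At every timepoint an independent logistic-regression classifier is fit
(ridge penalty, lambda = 1e-3 — weak regularization so the decision
vector stays defined when classes are separable; the reference analyses of such recordings
do not state a regularizer, and results are insensitive to lambda over
several orders of magnitude). Accuracy is stratified 10-fold
cross-validation with the fold assignment fixed by seed and recorded. The
decision vector (DV) is the coefficient vector of the all-trials fit; the
intercept is kept for prediction but excluded from geometry, since the DV
is defined as the boundary normal.

Classes with fewer than 10 trials are refused (`available = FALSE`)
rather than silently fit. Trial-subset conditioning (consistent-only,
lick-only, relevant/irrelevant context) is applied before fitting.

Geometry: angles between DVs are `acos` of the unit-normalized dot
product; two DVs span a plane via Gram-Schmidt (axis 1 along the first
DV, axis 2 the orthogonalized second DV); activity projects by dot
products, including across time (train a DV in an early window, project
the whole trial). One estimation subtlety is worth knowing: when two
planted coding directions are *not* orthogonal, an unconditioned
discriminant whitens away the other variable's signal variance and biases
the estimated angle toward 90 degrees. Angle-recovery analyses therefore
condition each stimulus decoder on the other modality being fixed —
exactly the role single-modality trials play in recordings.

Chance calibration repeats the decoding with labels drawn from a fair
coin (40 shuffles by default) and reports the shuffled mean plus a
one-sided margin combining across-shuffle and across-fold standard
errors.

Statistics over trial time use block averaging: the accuracy series'
autocorrelation is computed at native lags and the first zero-crossing
sets the block width (0.6 s is the fallback and the canonical width);
block means over 0.6-3 s — four windows at the canonical width — enter
paired two-sided t tests. The suppression metric is the block-averaged
relevant-minus-irrelevant accuracy difference with that test.

The drift control for context decoding trains on 20 fixed trials (10 per
context) at the session edges and tests on middle trials (two folds of
5 + 5), and reciprocally. A stationary context signal gives matching
accuracy time courses; a slow drift makes the two directions disagree —
under a linear ramp the direction *tested* at the edges is inflated,
because the edge trials are maximally separated along the drift axis —
so the control's detection statistic is the significance of the
asymmetry, and its null outcome ("no difference") is the evidence that
the decoded context is not a drift artifact.

## Single-neuron indices

The modality index of a neuron is the difference between its visual and
auditory decoder coefficients (or input weights, for the network);
go and no-go signals are computed separately and combined. The context
index is the mean activity difference between the two contexts computed
on congruent trials only — incongruent trials would trivially differ
through the go/no-go reversal of the relevant signal. Window presets
follow the trial stages: whole trial, "pre" (-1.0 to -0.25 s), "start"
(0 to 0.75 s), "dec" (1.75 to 2.5 s). Mutual suppression between
modality-specific populations predicts a negative Pearson correlation
between the context index and the modality *rank* (descending index
order); correlating raw indices instead gives the same conclusion with
the opposite sign convention, and trimming extreme ranks is available
for display parity but excluded from statistics by default.

## The recurrent network

The network is gateless and biasless, with one-hot inputs:

```
h_t = tanh(U x_t + V r*_t + F h_{t-1})
o_t = tanh(D h_t)
```

30 hidden units; `x_t` stacks one-hot visual and auditory stimuli (4
channels), `r*_t` is the one-hot outcome of the *previous trial's*
decision (success/error, 2 channels), and the discrete decision is the
larger component of `softmax(o_t)` (an exact tie deterministically maps
to no-go). The trial clock has 15 steps: 3 prestimulus, 9 stimulus
(decision read at stimulus step 7), 3 poststimulus; the reward signal is
presented from the step after the decision until the next trial's
stimulus onset, and the first trial of a sequence has none. Hidden state
is reset to zero between sequences — sequences are independent data
points.

Training minimizes the cross-entropy between the softmax of the output at
the *final* trial's decision step and the contextual target, over all
2048 sequences, with ADAM at initial learning rate 1e-4 for 5000 epochs.
The loss acts on the raw output logits `D h` (the `tanh` in the output
equation does not change any decision, since `argmax` is monotone
invariant, but bounding the logits at +-1 caps the attainable confidence
and was found to destabilize late training). The reward channel is a
discrete input: decisions are not differentiated through.

Two training details deserve emphasis, because the optimization is
genuinely delicate — the network's own decisions set the reward inputs,
so the effective training data changes discontinuously whenever a
decision boundary is crossed:

* **Update granularity.** One epoch visits every sequence once in a
  fresh random order, with one ADAM update per sequence (batch size 1,
  configurable). Large-batch and full-batch variants at the same total
  epoch count plateau at chance on incongruent final trials (about 0.75
  overall): with only thousands of parameter updates the weak
  long-horizon gradient that builds the context memory never accumulates.
  Per-sequence updates (about 10 million over training) learn the task
  reliably, and are what the stated optimizer settings imply at standard
  training-loop defaults.
* **Learning-rate decay.** The learning rate decays linearly from its
  initial value to zero across epochs. Without decay the late training
  oscillates: the run visits high-performance solutions (fraction-correct
  above 0.95) but occasional excursions — driven by the discrete reward
  feedback — can leave the final snapshot far from them. Decay freezes
  training into the late solution.

Congruent final trials are learned before incongruent ones (following
either modality suffices for congruent trials; incongruent trials
additionally require context inference from the reward history), and the
maximum attainable incongruent accuracy is bounded by the unsolvable
sequences. Models are filtered at fraction-correct > 0.9 over all 2048
final trials for the representation analyses (the denominator — all
final trials — is an assumption the caption leaves open).

Analyses mirror the population toolkit by treating hidden units as
neurons and sequences as trials: per-step decoders for stimuli, context
and decision; DV angles at the first stimulus step (before recurrence
mixes the input — there the stimulus DV is equivalent to the input
weights) and at the decision step; projections of relevant- and
irrelevant-context activity onto the stimulus input-weight directions;
matrix powers `F^2 ... F^6` in modality-index order, whose block
structure (positive within-modality diagonal, negative across-modality
off-diagonal) is the mutual-inhibition signature of context-gated
suppression; and the pooled correlation between per-unit context index
and modality rank across models.

## Problem sizes and reproducibility

Every stochastic step takes a single integer seed, and identical
configurations produce byte-identical outputs. The analysis scripts and
the acceptance checks use moderate problem sizes chosen to characterize
the estimators well: populations of 24-60 neurons on a 0.1-0.25 s grid
with 100-200 trials; 10^4-10^5 Monte-Carlo null sessions (the function
default is 10^6); and small populations of trained networks — 10 models
at the full 5000 epochs for the pooled statistics, and a 3-model,
1200-epoch smoke population for the quick checks, with the constant-rate
hold fixed at 800 epochs (escape from the context-blind plateau
typically happens within the first 800 epochs, so the shortened schedule
keeps the full-rate window and compresses only the decay tail). The
qualitative results are stable across these choices, and a larger model
population is a straightforward scale-up of `rnn_train_models()`.

One caveat the package reports honestly: at the training conditions used
here the networks reproduce the acquisition statistics (9/10 seeds clear
the 0.9 filter; congruent before incongruent in all), the representation
orthogonality, and the signed block structure of the ordered recurrent
matrix, but the *per-unit* coupling between context index and modality
rank — the strongest form of the mutual-inhibition signature — is weak
and varies in sign across models. `rnn_pooled_correlation()` computes it
as an empirical output (the analysis scripts write it to
`results/05_rnn_analysis/pooled_correlation.csv`); it should not be read
as a guaranteed property of every trained population, and its magnitude
is sensitive to training details the update equations alone do not pin
down.

## Known limitations

* The generator's linear-Gaussian structure makes decoding a
  best-case setting; real populations have correlated noise and
  nonstationarity, so accuracies here are upper bounds.
* The network model omits the error-trial timeout of the behavioural
  paradigm and any gated architecture; both are out of scope by design.
* The consistency null conditions on the empirical incongruent lick rate
  rather than marginalizing over it; this matches the reference analysis
  but slightly understates uncertainty for very short blocks.
* `relevance_contrast` inherits any context-tuned rate difference as
  apparent relevance modulation; the planted-context-free fixtures in the
  tests isolate the suppression component.
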