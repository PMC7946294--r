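---
title: "Computing integrated information structures from multichannel recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing integrated information structures from multichannel recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iisr)
```

`iisr` computes mechanism-level and system-level integrated information
(IIT 3.0) from binarized multichannel neural time series, and decodes
arousal state from the resulting feature vectors. This vignette is the
package's account of the method: the model and its assumptions, the
conventions that had to be fixed where the theory leaves freedom, the
synthetic data the pipeline is validated on, and what that validation does
and does not show.

## From voltages to a system model

The pipeline assumes a continuous multichannel recording at a fixed
sampling rate (the working default is 1000 Hz). Three preprocessing steps
produce the raw material for everything else:

1. **Bipolar re-referencing** (`bipolar_rereference()`): channel *i* is
   electrode *i* minus electrode *i* + 1, removing common-mode signal; 16
   electrodes yield 15 channels, with channel 1 the most central.
2. **Epoch segmentation** (`segment_epochs()`): non-overlapping 2.25 s
   segments (2250 samples); a trailing partial segment is discarded.
3. **Median binarization** (`binarize_median()`): a sample is 'on' when
   strictly greater than its channel's within-epoch threshold, 'off'
   otherwise. The default threshold is the median, which forces an exactly
   balanced split on tie-free data and hence equal (maximal) entropy in
   every channel and epoch — the reason the median is preferred over any
   fixed voltage. The quantile is a parameter (`quantile_prob`), so
   threshold-sweep analyses are one argument away. Samples exactly at the
   threshold go to 'off'; with continuous voltages this is measure-zero,
   but the rule is fixed so that integer-valued inputs behave
   deterministically. Thresholds are computed per channel *per epoch* —
   epochs are never pooled.

The system model is the **state-by-channel TPM** (`estimate_tpm()`): for a
set of *n* channels, a 2ⁿ × *n* matrix giving each channel's probability
of being on at *t* + τ conditional on the joint state at *t*. Transitions
are counted at every valid *t* (overlapping windows) within an epoch and
never across epoch boundaries. Two conventions matter:

* **State indexing is little-endian**: the lowest-labelled channel is the
  least significant bit (`state_index()`), declared once in the object's
  `state_order` attribute and used everywhere, which is the cheapest
  defence against silent row-permutation bugs.
* **Unobserved states** (never seen at time *t* in the epoch) are filled
  with 0.5 per channel and flagged. The engine needs complete matrices,
  but because every downstream quantity is averaged over states *weighted
  by observed occurrences*, the fill can never leak into a reported Φ or
  φ value. The weighting identity is tested directly.

τ defaults to 4 samples (4 ms at 1000 Hz) — long enough for synaptic
interactions to show, short enough to stay within epoch-stationarity —
and is a plain argument, so 2 ms and 6 ms sweeps use the same code path.

The per-node conditional form embodies the conditional-independence
assumption: no instantaneous interactions among channels. The full
2ⁿ × 2ⁿ state-by-state matrix, when needed, is the product of per-node
Bernoullis (`state_by_state()`).

## The engine

For a mechanism *M* (a non-empty subset of channels) in its current state,
and a purview *P*:

* the **effect repertoire** is the distribution of *P*'s state at *t* + τ
  given *M* clamped now, channels outside *M* marginalized uniformly; it
  factorizes over purview channels by conditional independence;
* the **cause repertoire** is the Bayesian inversion: over past purview
  states, the normalized product of each mechanism channel's likelihood,
  non-purview past channels uniform. A zero normalizer (the mechanism
  state is unreachable) returns the uniform distribution and a flag.

**φ** is the irreducibility of a repertoire: all bipartitions of
(*M*, *P*) into two parts are enumerated (the part with both components
empty is excluded, as is the trivial no-cut partition), severed
mechanism→purview influences are noised by uniform marginalization, and φ
is the *minimum* earth mover's distance between the whole and partitioned
repertoires. Distances are not normalized by partition size — the raw
minimum is taken. The **core cause/effect** is the purview maximizing φ;
the concept's φ is the minimum of its two sides. All 2ⁿ − 1 concepts form
the cause-effect structure (CES); the vector of their φ values is the
**integrated information structure (IIS)**.

**Φ** is computed by re-deriving the full CES under every unidirectional
cut — all 2ⁿ − 2 ordered bipartitions, with influences from one part into
the other replaced by noise, the reverse direction intact — and taking the
minimum structure distance. `ces_distance()` weights each mechanism's
repertoire distances (cause plus effect) by the smaller of its full/cut φ,
and transports any residual |φ_full − φ_cut| to the maximally
uninformative distributions: the uniform distribution on the cause side
and the unconstrained effect repertoire on the effect side.

### Conventions the theory leaves open

* **Common comparison space.** Repertoires of different purviews are
  compared after expansion to the full *n*-channel space, filling
  off-purview channels with the maximum-entropy distribution,
  independently. This is the single most consequential convention in the
  package; a finer-grained concept-space transport would be a legitimate
  alternative and would change Φ values (not the feedforward-zero or
  reducibility properties).
* **Residual transport target.** The unconstrained effect repertoire used
  for the residual term is that of the larger-φ side's own system (full or
  cut).
* **Tie-breaking.** Core-purview ties (at 1e−12) go to the larger purview,
  then to the lexicographically first channel set; partition and cut ties
  go to the first candidate in a fixed enumeration order. Ties are
  measure-zero for estimated TPMs but the rules make outputs reproducible.
* **1-channel mechanisms** go through exactly the same partition rules as
  larger ones ({(M, ∅), (∅, P)} is their only bipartition) and their φ
  values are reported unchanged; whether they are a meaningful theoretical
  construct is a live question in the field, so downstream analyses can
  simply drop them.

### Exact EMD

The ground metric between purview states is the Hamming distance, and the
EMD is solved *exactly* by successive-shortest-path minimum-cost flow in
compiled code — φ values on real data are of order 10⁻², so an approximate
transport solver would drown the signal in solver error. Two fast paths
are proven identities, not approximations: distributions that factorize
over channels (all effect repertoires) have EMD equal to the sum of
per-channel marginal differences, and a cut that severs no actual
connection leaves the TPM bit-identical, so its CES distance is 0 without
recomputation. The identity, the solver, and the engine's every quantity
are tested against an independently written brute-force R implementation
(and the EMD additionally against a third-party LP solver), to 1e−6 over
randomized 2- and 3-node systems, every state.

Numerical tolerances: repertoire normalization 1e−10; φ tie detection
1e−12; identical-TPM cut detection 1e−15.

## The synthetic study

The paper-scale recordings this pipeline is designed for are not
redistributable, so the package carries a generator whose *defaults are
the study dimensions*: 13 subjects × 2 conditions × 8 epochs × 15
channels × 2250 samples at 1000 Hz (`synthetic_study_config()`).

Each channel is an AR(2) process, x_t = (a₁I + cW) x_{t−1} + a₂ x_{t−2} + ε,
with a₁ = 1.7, a₂ = −0.8: complex roots of modulus 0.89, i.e. a damped
~50 Hz oscillation whose autocorrelation at the 4-sample working lag is a
moderate ~0.45 — autocorrelated enough to look like an LFP, stochastic
enough that binarized transitions carry information. W is a
subject-specific symmetric random matrix (zero diagonal, unit spectral
radius), shared between conditions; the condition only scales it:
c = 0.1 × coupling, with coupling 0.35 in "wake" and 0.05 in
"anesthesia". Symmetric W makes the coupling bidirectional — recurrent,
not feedforward — which is what gives the wake condition its positive Φ
headroom; scaling *all* cross-channel weights by one factor mirrors a
global disruption of communication rather than any channel-specific
effect. The spectral-radius normalization guarantees stationarity
(|a₁ + 0.1·coupling| < 1 − a₂) for any coupling ≤ 1. A master seed fans
out to per-subject/epoch substreams through a counter scheme, so studies
are bit-reproducible and epochs independent.

Setting the two couplings equal is allowed and gives the degenerate
no-contrast control: by construction the conditions are then exchangeable
and any decoder must sit at chance.

What the generator does *not* emulate: line noise (the pass-through slot
where a notch filter would go is deliberately empty), non-stationarity,
stimulus responses, volume conduction beyond what bipolar referencing
removes, and any claim about real fly physiology. Ground-truth binary
Markov systems (`make_feedforward_tpm()`, `make_recurrent_tpm()`,
`sample_time_series()`) complement it for engine-level validation:
feedforward chains must score Φ = 0 exactly, logistic-coupling recurrent
systems must score higher Φ at higher coupling, and TPMs re-estimated from
sampled trajectories must recover the generator.

## Study pipeline and decoding

`run_study()` composes everything over subjects × conditions × epochs ×
channel sets: estimate the TPM, compute per-state Φ and the per-state
mechanism φ values, average with state-occurrence weights, attach the
channel set's spatial features (mean location relative to channel 1, and
total path distance — the sum of pairwise label differences). The
channel-set size k defaults to 4 (C(15,4) = 1365 sets, 15-dimensional
IIS) and is configurable from 2 to 5.

`decode_study()` classifies wake vs anesthesia per channel set with
nested leave-one-pair-out cross-validation: within-subject (pairs are the
matched epochs; 8 pairs → 8 outer folds, 7-pair inner loops) or
across-subject (pairs are subjects at a fixed epoch). Features are
z-scored with *training-set* statistics (population-SD convention,
zero-variance features to 0); the inner loop selects the SVM cost from
2⁻⁵⁰…2⁵⁰ in powers-of-10 exponent steps, ties to the lowest cost after
averaging over inner folds; the outer fold never participates in
selection (a guard test corrupts a held-out pair and asserts the chosen
cost is unchanged).

The classifier is L2-regularized L2-loss support vector classification,
solved in the primal by a semismooth Newton method. The squared hinge is
smooth and piecewise quadratic, so Newton converges in a handful of
iterations at *any* cost in the grid — dual coordinate descent, by
contrast, stalls at large cost on non-separable data. There is no bias
term (the boundary passes through the origin), which is the natural
choice for z-scored features. The Newton ridge is floored at 1e−10, so
costs beyond ~10¹⁰ produce numerically identical hard-margin solutions;
since cost selection happens on validation accuracy, this affects nothing
but solver conditioning. Mechanism-level accuracies can be averaged by
mechanism size (`aggregate_by_mechanism_size()`: 4, 6, 4, 1 mechanisms of
sizes 1–4 at k = 4).

## Validation scale, and what it shows

Exhaustive validation is only feasible where brute force is: the oracle
suite covers randomized 2- and 3-node systems completely (every state,
every mechanism, every purview), and structural guarantees — feedforward
⇒ Φ = 0, independent subsystems ⇒ Φ = 0, coupling monotonicity — extend
to 4-node systems. The end-to-end synthetic check runs a reduced study (6
channels, k = 3, 5–6 subjects, full epochs): with strong wake coupling it
must show mean Φ(wake) > Φ(anesthesia) and above-chance IIS decoding;
with equal couplings, chance-level decoding for every feature kind. A
full 15-channel, k = 4, 13-subject study runs through the identical code
path and is a matter of CPU-hours, not of different software; the reduced
sizes are this package's chosen test scale.

Passing these tests shows the implementation computes its definitions
exactly and that the pipeline detects a coupling contrast *of the kind
the generator produces*. It does not show that real LFPs satisfy
conditional independence (common input violates it), that the observed
TPM of a small channel subset reflects causal structure (observational,
not perturbational), or that binarization at the median is the right
state definition for any particular preparation — those remain scientific
judgments outside the package's scope.
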