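# iisr — integrated information structures from multichannel neural time series

`iisr` implements an analysis pipeline that asks how much a network of
neural signals integrates information, and whether that integration
collapses under anesthesia. It is aimed at electrophysiologists and
computational neuroscientists with multichannel voltage recordings
(e.g. linear-probe local field potentials) from two arousal conditions,
and at methodologists who need an exactly tested, self-contained engine
for Integrated Information Theory (IIT 3.0) quantities on small binary
systems.

## The computation

Continuous recordings are bipolar re-referenced (16 electrodes → 15
channels), split into 2.25 s epochs, and binarized per channel at the
within-epoch median (strictly-greater → 'on'). For a set of *n* channels,
the empirical **state-by-channel transition probability matrix** gives each
channel's probability of being on at *t* + τ (τ = 4 ms by default)
conditional on the joint state at *t*, under conditional independence of
channels given the past.

From the TPM, for every *mechanism* (non-empty channel subset) in its
current state, the engine computes **cause and effect repertoires** —
distributions over past/future *purview* states, with unexamined channels
marginalized at maximum entropy — and the mechanism's irreducibility

φ = min over bipartitions of (mechanism, purview) of
EMD(whole repertoire, partitioned repertoire),

where severed connections are replaced by noise and EMD is the exact earth
mover's distance with a Hamming ground metric. The purview maximizing φ is
the *core cause* (or *core effect*); a mechanism's concept carries
φ = min(φ_cause, φ_effect). The 2ⁿ − 1 mechanism φ values form the
**integrated information structure (IIS)**, and system-level integrated
information

Φ = min over unidirectional cuts of the φ-weighted distance between the
full and cut cause-effect structures,

so purely feedforward systems score exactly zero. Per-state values are
averaged weighted by state occurrences, then across epochs. Finally,
wake vs anesthesia is decoded from IIS / φ / Φ features with nested
leave-one-pair-out cross-validated linear SVMs (L2-regularized L2-loss,
cost grid 2⁻⁵⁰ … 2⁵⁰).

A synthetic-data module generates coupled-AR(2) pseudo-LFP studies
(13 subjects × 2 conditions × 8 epochs × 15 channels × 2250 samples at
1000 Hz by default) with strong cross-channel coupling in "wake" and weak
coupling in "anesthesia", so the whole pipeline is testable without any
recording.

## Worked example

```r
library(iisr)
library(dplyr)

cfg <- synthetic_study_config(n_subjects = 2, n_epochs_per_condition = 4,
                              n_channels = 5, seed = 7)
study <- preprocess_study(generate_pseudo_lfp(cfg))
res   <- run_study(study, k = 3, tau_samples = 4)

summarize_phi(res) |> group_by(condition) |> summarise(mean_phi = mean(big_phi))
#> 1 wake         0.0322
#> 2 anesthesia   0.0230

acc <- decode_study(res, feature = "iis", mode = "within")
mean(acc$accuracy)
#> 0.75
```

Mean Φ is higher in the strongly coupled "wake" condition (0.032 vs
0.023 here), and the IIS decodes the condition at 75% within-subject
accuracy in this small study. A single system can be inspected directly:

```r
tpm <- estimate_tpm(study$bin[[1]], nodes = c(1, 3, 5), tau_samples = 4)
compute_big_phi(tpm, system_state = c(0, 1, 0))
#> System-level integrated information
#>   state: 010  Phi = 0.0579576
#>   minimal cut: { 2 } -> { 1,3 }
```

`tidy()` on that object lists each mechanism's φ under the full and
minimally cut system; `glance()` gives the one-row summary; `autoplot()`
draws the IIS. In this state the φ of every 1-channel mechanism survives
the cut unchanged — only multi-channel mechanisms lose integration, which
is the typical pattern.

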