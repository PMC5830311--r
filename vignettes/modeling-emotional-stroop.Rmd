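---
title: "Modeling implicit emotion regulation in the emotional Stroop task"
author: "stroopdbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling implicit emotion regulation in the emotional Stroop task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task and the data it produces

The emotional-Stroop variant modeled here presents a face superimposed on a
nature scene; each image is independently threat-related or neutral, and a
block instruction tells the participant which feature (the *target*) to
classify while ignoring the other (the *distractor*). The default design is
24 subjects x 3 runs x 64 trials (two 32-trial attend blocks per run,
3--7 s jittered ISIs, exact 2x2 valence balance so the two valences are
uncorrelated, no immediate image repeats, and a trial-type sequence shared
by all participants). `build_group_design()` produces the 4608-trial group
table; `derive_target_distractor()` recodes face/scene valences by
instruction.

Responses enter the models as three classes. Each subject's correct
reaction times are median-split: `rt <= median` is *fast* (the tie rule
keeps every correct trial classified), `rt > median` is *slow*; incorrect
or missing responses are *error* (`discretize_responses()`).

## Five models as discrete dynamic Bayesian networks

Each candidate cognitive architecture is a per-trial Bayesian network over
binary hidden nodes (state 0 = off/suppressed/neutral, 1 =
on/enhanced/threat) plus the 3-state response, with optional *cross-trial*
edges carrying the previous trial's hidden states forward
(`build_model()`):

* **cohen** — attention (driven by the instruction) biases two
  feature-specific detectors that jointly generate the response.
* **cohen_mod** — adds a conflict monitor over the detectors whose previous
  state feeds the current attention node (conflict adaptation). Because the
  observed response is post-resolution, the monitor reads the detectors
  rather than response tendencies.
* **mathews** — task effort sharpens a target detector, threat evaluation
  biases a distractor detector toward threat; the detector interaction is
  placed at response generation (a detector-to-detector cycle is not
  representable in this framework).
* **mathews_mod** — the previous trial's detector states drive the current
  effort and threat-evaluation nodes (conflict adaptation and slow
  emotional interference).
* **wyble** — detectors feed a categorical layer, both biased by task
  demand; categorical conflict and detected negative information from the
  previous trial modulate the next trial's task demand. The verbal
  description of this architecture leaves some parent sets open; the wiring
  fixed here routes conflict through a categorical-level conflict node and
  gives negative detection the detectors as parents. It is one defensible
  reading among several, which is why the model is declared data rather
  than code and alternatives are easy to swap in.

Stimulus and instruction nodes are observed inputs and carry no estimated
parameters: the likelihood is that of the response stream given the
stimuli. A table with `x` parent configurations over a `y`-state child
contributes `x(y-1)` free parameters; initial-slice tables of nodes with
cross-trial parents are independently estimated and counted
(`count_free_parameters()` gives 18, 26, 18, 26 and 42 for the five models).

## Fitting: constrained multi-restart Baum-Welch

`em_fit()` runs expectation maximization on the flattened chain whose
super-state is the joint hidden configuration per trial (at most 2^7 = 128
states); cross-trial edges act through the projection onto the cross-edge
source nodes (at most 4 joint states), which keeps every per-trial kernel a
small matrix. The forward-backward pass is scaled per trial (equivalent to
log-domain arithmetic) and implemented in C++; runs are separate recording
blocks, so chains reset at run boundaries with initial-slice tables.

Because hidden nodes are unobserved, every model's likelihood is invariant
under flipping a node's off/on labels. Random priors are therefore drawn
uniformly on the simplex but re-drawn until the orientation inequalities
hold (`sample_constrained_prior()`): each detector reports threat with
probability above 0.5 under a threatening driving stimulus and below 0.5
under a neutral one at every modulator state, and the Mathews-family
modulators increase their detector's stimulus match. Response tables are
never constrained. After fitting, `vet_solution()` checks interpretability
on the *decoded* trajectories — each detector's Viterbi timecourse must
correlate positively with its stimulus, and no pair of hidden nodes may
exceed |r| = 0.80 (the trivial-solution flag); constant timecourses are
recorded as undefined rather than flagged. The strict prior inequalities
are deliberately not re-imposed post fit: fitted solutions (including the
published one this package's preset reproduces) can hold a detector's
false-alarm rate above 0.5 while remaining positively correlated with the
stimulus, so the decoded-correlation check is the faithful reading of the
off/on verification.

Defaults: convergence when the log-likelihood improves by less than `tol =
1e-6` (absolute), `max_iter = 500`, an additive floor of `1e-9` per cell
before row normalization in the M-step (prevents absorbing zeros), and
`n_restarts = 3000` at study scale — tests and examples use 50 or fewer.
Viterbi ties are broken toward the lowest configuration index
(configurations enumerate the first declared hidden node fastest).

## Model comparison

`information_criteria()` implements the standard forms AIC = 2 NLL + 2k,
AICc = AIC + 2k(k+1)/(n-k-1), HQC = 2 NLL + 2k ln(ln n), BIC = 2 NLL +
k ln n, with n the number of trials (4608 in the default design).
`relative_likelihood(aicc_min, aicc_j) = exp((aicc_min - aicc_j)/2)` is the
evidence ratio against the AICc-best model. `stability_regression()`
regresses each restart's final log-likelihood on its summed squared
parameter distance from the best solution (all table entries exactly as
stored, including redundant last columns, so the quantity is reproducible).

## The synthetic generator and the reference preset

No behavioral data ship with this package; `forward_sample()` draws
responses and hidden states from any model's tables over a design, and
`simulate_study()` composes design + sampling + RT attachment +
re-discretization. `preset_params()` returns the modified-Mathews parameter
set whose entries are fixed at the reported group-level values: fast 0.90
(both detectors neutral) and 0.73 (threat target, neutral distractor), slow
0.83 (neutral target, threat distractor), threat evaluation 0.94 after dual
detected threat, effort 0.68/0.74 after detected conflict, distractor
threat-hit rates 0.725/0.463 by threat-evaluation state. Every entry
carries a provenance flag; entries that were never reported are set to 0.5
exactly (maximal entropy) rather than invented, and the two readings of the
ambiguous target-detector description are both available
(`target_reading = "false_alarm"`, the default, treats 0.70/0.60 as
false-alarm rates so that effort improves matching; `"literal"` treats 0.83
as the neutral-hit rate).

`attach_rts()` places fast RTs at or below a nominal median and slow RTs
above it (uniform jitter, default median 650 ms, spread 150 ms, 10% of
errors missing). A median split can never yield more slow than fast correct
responses, so when a sampled subject is fast-heavy the excess fast trials
sit exactly at the nominal median and the `<=` tie rule reproduces the
classes on re-discretization; the (rare) opposite imbalance is flagged with
a warning and round-trips inexactly — no threshold rule could reproduce it.

## Linking hidden states to BOLD

`synthesize_bold()` plants effects: voxel signal = baseline + sum of
per-voxel betas times HRF-convolved, mean-centered trial modulators +
AR(1) Gaussian noise (marginal SD `sigma`). The HRF is the canonical
double-gamma (peak 6 s, undershoot 16 s, ratio 1/6); events are impulses at
onset (stimulus duration is not modeled); TR defaults to 2 s.
`build_design_matrix()` adds an intercept, a linear drift and an
unmodulated event regressor so amplitude-modulated columns carry only
trial-to-trial variation; `fit_am_glm()` is per-voxel OLS (the study-scale
analogue used REML prewhitening — an AR(1) variance correction is available
behind `ar1_correct`), `group_test()` is the voxelwise 20%-trimmed
one-sample test in both directions, and `cluster_threshold()` keeps
6-connected components of at least `k` suprathreshold voxels with `k`
user-supplied (smoothness-based estimation of `k` is out of scope).

## What the tests show — and what they cannot

The test suite verifies the machinery against independent oracles:
likelihoods and Viterbi paths match brute-force enumeration over all joint
hidden paths (chains of length 4, or 3 for the 7-node model); EM is
monotone on every dataset; forward samples reproduce configured
conditionals within 3 binomial SEs at 10^5 trials; a sharply identified
parameter set is recovered with mean absolute error below 0.05 by ~3x10^4
trials; planted BOLD encodings are detected at nominal specificity. Problem
sizes in the tests (50 restarts, 10 recovery replicates, 20-subject
fidelity samples, 10^3-voxel grids) are desk-scale choices that keep the
full suite in minutes while leaving each check statistically sharp.

Three limits are properties of the study conditions themselves, not of the
code, and the corresponding acceptance checks are left failing rather than
weakened:

* **Parameter recovery at n = 4608.** With most hidden-node rows of the
  preset at 0.5, the likelihood surface is nearly flat in several
  directions: EM initialized at the generating truth drifts several nats
  upward while moving response entries by ~0.1, and random restarts find
  structurally different solutions that fit slightly better. Recovery of
  the reported entries to +/-0.05 from a single study-sized dataset is not
  achievable; the same estimator succeeds on sharply identified parameters
  and at larger n.
* **Model recovery.** The observable signal that separates the five
  architectures on preset-simulated data is a few nats — smaller than the
  AICc penalty difference — because the discriminating structure lives
  almost entirely in table rows that were never reported. Information-
  criterion selection then prefers the smallest adequate model.
* **Slow emotional interference.** On neutral/neutral trials the preset's
  distractor-detector rows are 0.5 regardless of threat evaluation, so
  dual-threat history has essentially no pathway to speed the next
  response; simulated groups show the threat-distractor interference
  reliably but the post-threat speeding only at chance rate. Whatever
  produced that effect in the fitted model lies in unreported entries.

These limitations equally mean that passing tests on synthetic data say
nothing about real adolescents: the generator emulates the design,
the discretization convention and the reported probabilities, not RT
distributions, error mechanisms, learning or fatigue.
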