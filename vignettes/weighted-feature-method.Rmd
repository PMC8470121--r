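---
title: "Channel-weighted sEMG action recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-weighted sEMG action recognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgwfm)
```

## The problem

Surface electromyography (sEMG) records the electrical activity of skeletal
muscle from electrodes on the skin. For lower-limb movement recognition —
e.g. as the command signal of a rehabilitation exoskeleton — a trial is a
multichannel recording (here: 8 channels over the rectus femoris, biceps
femoris, tibialis anterior and gastrocnemius of both legs, 2000 Hz, 10 s)
labelled with one of six actions: raise/lower the right or left leg, sit to
stand, stand to sit. The pipeline in this package turns such trials into
class predictions in four stages:

1. **Segmentation** — find the action onset by a sliding-frame energy rule
   and cut a fixed 2 s *main feature segment*;
2. **Features** — four scalar features per channel over sliding windows:
   mean absolute value (MAV), root mean square (RMS), Willison amplitude
   (WA), and the log wavelet-packet coefficient energy (EC1);
3. **Weighted feature method (WFM)** — scale each channel's feature vector
   by a weight proportional to that channel's share of the total
   absolute-amplitude energy, so muscles that contribute more to an action
   weigh more in the fused feature vector;
4. **IGA-SVM** — classify with a one-vs-one RBF-kernel SVM whose penalty
   `c` and kernel parameter `g` are tuned by a genetic algorithm that
   combines championship selection with a four-tier fitness-sorted scheme.

## Segmentation: the framing energy method

A single-channel signal of `N` samples is cut into `M` frames of `L = 64`
samples advancing by `I = 32`; `M = floor((N - L)/I) + 1`, so trailing
samples that do not fill a frame are dropped and `(M-1)·I + L = N` holds
exactly for compatible lengths (20,000 samples give `M = 624`). Each frame's
energy is its sum of squared amplitudes; the onset is the first frame whose
energy exceeds an adaptive threshold in that frame *and the next three*
(`run_length = 4`; set 3 for the stricter "three in a row" reading). Onset
detection runs on the energy profile summed over channels: a trial has one
onset, and the sum is the least arbitrary single trigger.

The threshold is the mean frame energy, `th = sum(En)/M`. By default the
mean is taken over **all** frames of the trial: for a trial that contains
both rest and a burst, the whole-trial mean falls between the rest and burst
energy levels, which is what makes the 4-frame rule discriminate. Averaging
only a rest region is available (`threshold_from = "rest"`) but is fragile
as a default: by construction roughly half of the rest frames exceed the
mean of the rest energies, so runs of four supra-threshold rest frames occur
by chance and false-trigger the detector. With the whole-trial default, the
synthetic-data checks recover the true onset within one frame in essentially
every trial.

Given the onset frame `FS`, the segment bounds are `SN = (FS-1)·I + 1`
(first sample of the onset frame), `MSN = SN + 0.5·fs` and
`MEN = MSN + 2·fs`: the main feature segment is the 2 s of samples
`MSN … MEN-1`, skipping the 0.5 s initial transient. A recording that ends
before `MEN` is rejected as too short after onset.

Denoising (`denoise()`) is deliberately standard: a 4th-order 10 Hz
Butterworth high-pass (baseline drift, DC), a 2nd-order band-stop around the
50 Hz power line, and per-channel wavelet soft-thresholding (db4, level 4,
universal threshold with the noise scale estimated from the finest detail
level). It implements the usual goals of sEMG conditioning — broadband
noise, power-line interference, baseline drift — with textbook components;
it makes no claim beyond that, and each stage can be switched off. All
filtering is zero-phase (forward–backward), so onsets are not delayed.

## Features

Windows reuse the framing constants (`n_win = 64`, `inc_win = 32`) — the
only windowing constants the method defines — and all four features average
a per-window statistic over windows:

* `MAV = mean_j( sum|x| / (n-1) )` and `RMS = mean_j( sqrt(sum x² / (n-1)) )`.
  The `1/(n-1)` normaliser is the definition this pipeline is specified
  with; `mav_denom = "conventional"` restores `1/n`. RMS takes the root per
  window, paralleling the MAV's per-window structure — "root mean square"
  requires the radical even where a flattened rendering omits it.
* `WA = mean_j( #\{i : |x_i - x_{i+1}| ≥ th_WA\} )` with `th_WA = 1e-5` —
  10 µV for signals in volts, a conventional Willison threshold. This
  amplitude threshold is independent of the energy threshold of the onset
  detector: the two quantities have different units, and conflating them
  would make WA depend on the rest energy.
* `EC1 = log10( mean_j |S_j|² )` where `|S_j|²` is the total squared
  coefficient energy of window `j` under a depth-3 wavelet-packet
  decomposition (db4), summed over all 8 leaf nodes, clamped below at
  `log_floor = 1e-12` so silent windows stay finite. The packet transform is
  implemented in-package as a periodized orthonormal filter bank (no
  suitable wavelet package ships with the R ecosystem used here), with the
  recursive reference (`wpt_coefficients()`) cross-checked in the tests
  against the cached matrix form (`wpt_matrix()`) used for speed.

One consequence is worth stating plainly: an orthonormal transform conserves
energy, so summing squared coefficients over the *complete* leaf set makes
`|S_j|²` equal the window's signal energy exactly (Parseval). Under this
package's reading EC1 is therefore a log-energy feature, monotonically
related to RMS; the wavelet affects how energy distributes across leaves,
not the total. Alternative readings (a single leaf node, boundary-extended
non-orthogonal transforms) would break this identity, but none is specified
unambiguously; we keep the complete-leaf-set reading and the exact scaling
law `EC1(c·x) − EC1(x) = 2·log10(c)` that comes with it, which the tests
assert to 1e-9.

Features are normalised per column to `(-1, 1)` by an affine map fitted on
the training split only and reapplied to the test split (test values may
fall outside the interval; a constant training column maps to 0 with a
warning).

## The weighted feature method

For a denoised recording, the energy of channel `i` over the main feature
segment is `e_i = sum |x_i|`, and its weight is

&nbsp;&nbsp;&nbsp;&nbsp;`C_i = n · e_i / sum_k e_k`,

so `sum C_i = n` always, and the weights are invariant to a common
amplitude rescaling. The packaged worked example (`table2_fixture()`, six
actions × eight channels of reference energies) reproduces the published
weight table (`table3_fixture()`) to the printed 4 decimal places:

```{r wfm-example}
round(channel_weights(table2_fixture()["action1", ]), 4)
```

Two design choices deserve justification:

* **Weights are computed per recording from its own energies**, not looked
  up per action class. Action-conditional weights would require the label
  at prediction time, which is circular; per-recording weights make the
  transform well-defined for unlabelled data, and on synthetic trials the
  channel with the largest realised gain receives the largest weight in
  ≥95% of cases.
* **Fusion defaults to concatenation** of the weighted per-channel vectors
  (dimension `n·4 = 32`) rather than their literal sum (dimension 4): the
  summed variant collapses the classifier input to four numbers and
  discards the per-channel pattern that the weighting is meant to sharpen.
  Both are implemented (`mode = "sum"` / `"concat"`) and tested.

## IGA-SVM

The classifier is a one-vs-one RBF-SVM (`e1071`/libsvm solves the quadratic
program; the contribution here is the tuning wrapper, not the solver), with
`k(x, y) = exp(-g·||x - y||²)` and soft-margin penalty `c`. Fitness of a
candidate `(c, g)` is the mean held-out accuracy over stratified
cross-validation folds that are fixed for the whole run, so all individuals
are scored on identical splits.

Individuals are real-valued pairs `(log2 c, log2 g)` bounded by the
standard RBF grid `log2 c ∈ [-5, 15]`, `log2 g ∈ [-15, 3]`. Each
generation:

1. evaluate unevaluated individuals;
2. sort ascending by fitness (ties broken deterministically) and split into
   four tiers — bad, medium, well, good — of `floor(C/4)` each, remainder
   to the good tier;
3. select `floor(size·p)` members uniformly without replacement from each
   tier with probabilities `P, P+σ, P+2σ, P+3σ` (defaults 0.4/0.6/0.8/1.0:
   the good tier is kept whole);
4. recombine and mutate the selected pool: arithmetic blends
   `α·a + (1-α)·b` in log2 space with probability `pc = 0.7`, pairing
   consecutively in the fitness-blocked order (recombination is therefore
   assortative — elites blend with elites); Gaussian per-gene mutation with
   probability `pm = 0.1` and scale 10% of the range, clipped to bounds;
5. refill to size `C` with individuals drawn from the good tier (then the
   well tier if the deficit exceeds it). The refill block joins the next
   generation *intact* — it is not crossed or mutated. This protected
   elitist core is what sustains the population's average fitness: with
   operators applied to the whole refilled population instead, the tiered
   scheme loses its advantage over plain tournament selection entirely.

Evolution stops at `target_fitness` or after `max_generations` (default
50), whichever comes first; the best-ever individual is tracked outside the
population, so reported best fitness is non-decreasing by construction.
`evolve_plain_ga()` implements the unimproved comparator — championship
selection alone (tournament size 2) with the same operators — used by the
tests to show the tiered scheme's higher final average fitness.

## The synthetic generator

No public corpus covers these six lower-limb actions, so the package ships
a generator rather than data. sEMG is simulated as amplitude-modulated
band-limited Gaussian noise — a standard surrogate with the right
second-order statistics for every pipeline stage, with no claim to
motor-unit realism. Each channel carries unit-variance 10–500 Hz noise
(white noise shaped on the FFT grid by the squared magnitude of a 4th-order
Butterworth band-pass — the zero-phase spectrum, circularly exact)
multiplied by an envelope: `rest_noise_sd = 0.01` (volts) at rest, rising
by `gain_i · burst_noise_sd` (default 0.05) during the burst with 50 ms
raised-cosine ramps. Defaults: onset at 2 s, burst 3 s (the time an
unimpaired adult takes to complete these actions), 10 s trials at 2000 Hz,
8 channels. Per-trial channel gains are jittered by a log-normal factor
(`gain_jitter_sd = 0.25`) to emulate trial-to-trial variability; the
realised gains are returned as ground truth. The jitter level is the one
free knob with no published counterpart (per-action SNR is not reported
anywhere); it is set so that end-to-end recognition accuracy lands in the
low-to-mid 90s — above, but near, the 85% working floor the method targets —
rather than at a ceiling where comparisons between pipeline variants would
be vacuous. The six class gain templates
are the rows of the reference weight table rescaled to unit mean, so the
synthetic muscle-action structure mirrors the published one.

What the generator does *not* model — muscle fatigue, electrode shift,
crosstalk, non-Gaussian motor-unit spikes, non-stationary rest tone — bounds
what passing tests show: they validate the pipeline's mechanics and its
relative comparisons (weighted vs unweighted fusion, tiered vs tournament
selection) on data whose class structure is genuinely of the assumed form,
not performance on recorded human sEMG.

## Problem sizes and numerical choices in the checks

The test suite exercises the stochastic properties at sizes chosen to keep
a full run comfortably on one CPU while leaving the conclusions stable
across seeds:

* onset recovery: 200 trials at the full default geometry (10 s, 2000 Hz);
* selection-scheme comparison: a fixed 6-class problem of 15 recordings per
  class (5 s trials), with `gain_jitter_sd = 0.4` and
  `burst_noise_sd = 0.015` so that cross-validated accuracy sits mid-range
  (~0.5–0.85) — on the easy defaults every `(c, g)` reaches accuracy 1.0
  and a comparison of selection schemes would be vacuous; population 60,
  20 generations, 3-fold fitness, 20 replicate seeds;
* end-to-end ablation: 120 recordings per class (5 s trials, onset at 1 s),
  half/half split, GA scaled to population 16 × 4 generations × 3 folds,
  20 replicate seeds, denoising off since the generator emits clean
  band-limited signals.

Other numerical choices: energies and thresholds are plain double sums (no
compensated summation — frame energies are 64-term sums, far from
cancellation); the weight sum `ΣC_i = n` is asserted to 1e-9 relative;
tie-breaks in the GA sort are lexicographic in `(fitness, log2 c, log2 g,
position)`; all seeds fan out from one master seed through a fixed affine
map, so every reported number is reproducible bit for bit, which the
determinism test checks by comparing serialised reports byte for byte.

One caveat the ablation tests make visible: at this problem size the
weighted arm's accuracy advantage over the unweighted ablation is small
(a fraction of a percentage point on average), while cross-validated
hyperparameter selection on the SVM's flat `(c, g)` fitness plateau leaves
each arm with residual test-accuracy noise of a similar magnitude — CV
fitness cannot always distinguish plateau candidates whose test accuracy
differs by a few samples, and occasionally selects an effectively linear
kernel (tiny `g`, huge `c`) that cross-validates as well as the RBF
solutions. Per-replicate win/loss comparisons between the two arms should
therefore be read alongside the aggregate margin, not alone.

## Known limitations

* EC1 as specified is a monotone transform of window energy (see above);
  it is retained for fidelity, not for added discriminative power.
* The published recognition rates were measured on a private 4-subject
  corpus; nothing here reproduces them, and the synthetic accuracies are
  not comparable to them.
* One onset per trial: recordings with multiple bursts are segmented at the
  first qualifying run only.
* The WA threshold and the wavelet family/depth behind EC1 are convention,
  exposed as parameters rather than fixed truths.
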