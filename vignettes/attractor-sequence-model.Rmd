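---
title: "Sequence discrimination in a depressing point-attractor network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence discrimination in a depressing point-attractor network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attractorseq)
```

## The model

`attractorseq` simulates a firing-rate network of `n_E = 100` excitatory
units — each standing for a tightly coupled pool of similarly tuned
neurons — plus one shared inhibitory unit. Three variables describe each
unit: its rate $r_j$ (Hz), the synaptic gating fraction $s_j \in [0,1]$ of
its outgoing synapses, and a depression fraction $D_j \in (0,1]$:

$$\tau_r \frac{dr_j}{dt} = -r_j + \frac{r^{max}_j}{1 + e^{(\Theta_j - I_j)/\Delta_j}},
\qquad I_j = \sum_i s_i W_{ij} + I^{app}_j + \sigma \eta_j,$$

$$\tau_s \frac{ds_i}{dt} = -s_i + \tilde\alpha\, p_0\, r_i D_i \tau_s (1 - s_i),
\qquad \tau_D \frac{dD_i}{dt} = 1 - D_i - p_0\, r_i \tau_D D_i.$$

Strong uniform-random self-weights ($W^{self}_{EE} \in [(1-\sigma_W) w, w]$)
make each excitatory unit bistable: quiescent and active rates are both
stable under the same input, so the set of currently active units is a
point attractor that stores stimulus history. Weak random cross-excitation
($W^X_{EE}$ uniform in $[0, W^{max}_{EE}]$) "primes" different follow-up
units depending on which units are already on; short-term depression
transiently weakens the output of recently active units, pushing the
network onto self-avoiding trajectories; the single inhibitory unit
(driven by all excitatory units through $W_{EI}$, feeding back $W_{IE} < 0$)
keeps overall activity bounded and, crucially, stabilizes the quiescent
state.

Stimuli are 250 ms square current pulses of amplitude $I_{stim}$ delivered
to a random subset of `round(n_E * f_stim)` excitatory units (one fixed
subset per stimulus type), spaced 1.5 s apart so the network relaxes to a
new attractor in the 1250 ms gap after each pulse. After a sequence the
mean rate of each excitatory unit over the window 250–1250 ms past the
final offset is binarized at a strict 30 Hz threshold; these binary vectors
are the substrate of all decoding.

## Tasks and decoding

Two tasks are built in:

* **Two-choice evidence accumulation** (`task = "two_choice"`): all
  $2^6 = 64$ sequences of six "left"/"right" stimuli. A choice is correct
  when it matches the majority type; the 20 equal-count sequences are
  excluded from choice training and scoring. Deciding from the final
  stimulus alone is correct on 32 of the 44 scored sequences (73%) — the
  no-memory reference level computed by `last_stimulus_benchmark()`.
* **Word-list discrimination** (`task = "word_list"`): 70 distinct
  permutations of 7 stimulus types sampled by stacked randomized Latin
  squares, so every type occupies every serial position exactly 10 times.

Each sequence is presented 10 times to form training states, 10 more for
testing. The L1 nearest-target decoder assigns each test state to the
sequence with the closest mean training response; the resulting
column-stochastic confusion matrix yields the discrimination score
$\kappa = 1 - \text{mean error rate}/(1 - 1/N_{seq})$, clipped to $[0,1]$
(1 = perfect, 0 = chance). Binary choices use a classic perceptron readout
(zero-initialized, learning rate 1, fixed shuffled order, at most 1000
epochs — any linear separator suffices for the reported behavior, so these
hyperparameters are deliberately plain). Serial-position recall trains one
perceptron per (type, position) pair — 49 models for the 7-item task —
and summarizes primacy/recency as the excess accuracy of the first/last
position over the middle (4th) one. "Probability of first recall" compares
the post-sequence state with each list item's single-stimulus state (L1 on
binarized states, ties to the lowest type id, matching the decoder).

## Parameter choices that matter

Defaults follow the model's fiducial point: $W^X_{EE} = .346$,
$W^{self}_{EE} = 89$, $W_{IE} = -540$, $W_{EI} = .665$, $f_{stim} = .59$,
$I_{stim} = 1.07$, with $\tau_{s_E} = 50$ ms, $\tau_{s_I} = 5$ ms,
$\tau_D = 500$ ms, $\Theta_E = 6$, $\Delta_E = 1$, $\Delta_I = 3$,
$p_0^E = 1$, $p_0^I = .1$, $r^{max}_E = 100$ Hz, $r^{max}_I = 200$ Hz,
$\tilde\alpha = 1$. Four choices were genuinely open and deserve comment:

* **$\tau_r$ = 10 ms.** The sources state both 10 ms (next to the rate
  equation) and 100 ms (in the parameter table). The fixed points are
  unaffected, but the slower value lets rates lag the 250 ms pulses enough
  to change which attractor is reached; 10 ms reproduces the reference
  behaviors (perfect discrimination at strong weights) and is the default.
  Both values are accepted by `model_params()`.
* **$\Theta_I$ = 10.** Two values (10, 12) are quoted. Stability analysis
  and simulation both show that with $\Theta_I = 12$ the inhibitory unit is
  too sluggish at low rates to stabilize quiescence: the "empty" network
  ignites to ~97/100 active units before any stimulus and discrimination
  collapses ($\kappa \approx 0.2$ at $W^{self}_{EE}=88$,
  $W^{max}_{EE}=.476$). With $\Theta_I = 10$ the prepared quiescent state
  is a true fixed point and that same network discriminates all 64
  sequences perfectly ($\kappa = 1$). The default is therefore 10.
* **$\sigma_W$ = 0.1.** The self-weight spread has a documented range
  $[0, 0.2]$ but no stated central value; the midpoint is used, chosen once.
* **Noise discretization.** The white-noise current is integrated by
  Euler–Maruyama with per-step standard deviation $\sigma/\sqrt{dt}$
  ($dt$ in seconds), so fluctuation power does not depend on the step size;
  at $\sigma = .002$ this produces the intended few-Hz rate fluctuations in
  delay periods. A literal per-step convention is selectable via
  `integration_settings(noise_convention = "per_step")`.

## Numerical choices

Integration is fixed-step Euler–Maruyama at `dt = 0.5` ms (the stiffest
time constant, $\tau_{s_I} = 5$ ms, is still resolved 10-fold; halving `dt`
changes converged trajectories at first order and leaves task scores
essentially unchanged). The f-I exponent is clamped at ±500, which only
affects rates below $10^{-200}$ of $r^{max}$. Euler steps may overshoot the
$[0,1]$ ranges of $s$ and $D$ by rounding-level amounts; violations below
$10^{-9}$ are clipped and anything larger raises an integration error
naming the unit. L1 distance ties and first-recall ties resolve to the
lowest sequence/type id. Targets are fractional means of binarized training
states and test states are binarized before decoding (mean rates can be
decoded instead via `use = "rates"`). The compiled kernel and the plain-R
stepper implement the identical update rule and are cross-checked in the
test suite.

The quiescent baseline is prepared by settling the network without input
for at least 1.5 s from $r = s = 0$, $D = 1$ (optionally with a fixed
fraction `f_start_on` of units initialized active at their clamped-rate
fixed points). Settling for 1.5 s leaves a residual drift of order
$10^{-2}$ Hz because depression equilibrates on the $\tau_D$ scale; the
protocol uses the 1.5 s convention, and tests that assert an exact fixed
point settle for 10 s.

## What the generator emulates, and what it does not

All inputs are synthetic by design: random connectivity within the
documented ranges, random stimulus target sets, enumerated or
Latin-square-balanced sequences, optional Gaussian per-presentation
variability of amplitude (e.g. $0.9 \pm 0.2$) and duration
($\pm 10\%$), with non-positive draws redrawn. This emulates the study
conditions, not biological recordings: units are mean-field pools (no
spiking statistics), there is no long-term plasticity, stimuli are ideal
square pulses, and a single global inhibitory unit stands in for an
interneuron population. Passing tests therefore certify the dynamics,
protocol and decoding pipeline under the stated model assumptions — they
say nothing about fits to in-vivo data.

## Known limitations

* The attractor states are metastable, as the model summary itself notes:
  after a stimulus, depression keeps relaxing on the $\tau_D$ scale and
  occasionally flips marginal units seconds later. One consequence
  replicates poorly here: a decoder trained at a 1500 ms onset interval
  transfers badly to 3000 ms states in our runs (L1 $\kappa$ drops from 1
  to ~0.1 at the strong-weight point), whereas the original report found
  no detrimental impact. The machinery (`generalization_test()` with
  per-condition stimulus configurations) is provided so the question can
  be probed; the discrepancy is documented rather than hidden.
* With $\sigma = 0$ and no stimulus variability, repetitions are identical
  by construction. They are still executed by default; the provably
  equivalent `dedup = TRUE` fast path is used where wall time matters.
* Sweeps default to coarse grids (a handful of points, a few networks per
  point) sized for a desk run; the full-resolution maps of the original
  study (121–273 grid points × 10 networks) are reachable through the same
  `sweep_grid()` interface given proportionally more compute.

## A worked run

```{r example, eval = FALSE}
params <- model_params()                          # fiducial constants
wcfg <- weight_config(w_self = 88, w_cross_max = 0.476)
settings <- integration_settings()

res <- run_task_point("two_choice", params, wcfg,
                      settings = settings, network_seed = 1, dedup = TRUE)
res$kappa      # 1: all 64 sequences discriminated
res$accuracy   # 1: perceptron choice accuracy on non-tie sequences

bm <- last_stimulus_benchmark(enumerate_binary_sequences(6))
round(100 * bm$accuracy)   # 73: the no-memory reference level
```
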