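---
title: "Drifting memory ensembles from fluctuating excitability: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drifting memory ensembles from fluctuating excitability: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Chronic recordings show that the set of neurons encoding a stable memory
or behaviour changes gradually over days ("representational drift"), even
while the animal's behaviour is unchanged. One candidate mechanism is the
slow fluctuation of intrinsic excitability: the neurons that happen to be
most excitable at the time of a reactivation are preferentially recruited
into the ensemble, so each reactivation re-allocates the memory trace.
`driftnet` implements a minimal rate-network model of this hypothesis
together with the decoding analyses that quantify what the drifting code
still encodes (the day of a reactivation, the order of reactivations) and
a plastic read-out neuron that tracks the moving ensemble.

## The network

`N` rate neurons (default 50) interact through an all-to-all plastic
weight matrix `W` (self-connections included; the model is taken literally
as all-to-all). Rates follow leaky dynamics with a rectified-linear
input–output function:

$$\tau_r \frac{dr_i}{dt} + r_i =
  \mathrm{ReLU}\!\big(\Delta(t) + \textstyle\sum_j W_{ij} r_j - I
  + \varepsilon_i(t)\big),$$

where $\Delta(t)$ is the stimulation drive, $\varepsilon_i(t)$ the
per-neuron excitability, and $I$ a global inhibition that grows with
population activity,

$$I = I_0 + I_1 \sum_i r_i + I_2 \sum_i r_i^2 .$$

In the *slope* variant, excitability multiplies the ReLU instead of
shifting its threshold:
$\tau_r \dot r_i + r_i = \varepsilon_i \,\mathrm{ReLU}(\Delta + \sum_j
W_{ij} r_j - I)$.

Recurrent weights are Hebbian with passive decay and a hard bound
$[0, c]$:

$$\frac{dW_{ij}}{dt} = \frac{r_i r_j}{\tau_W} - \frac{W_{ij}}{\tau_{decay}},$$

optionally multiplied by a fixed binary mask (drawn once per simulation,
each directed synapse kept with probability $1-\text{sparsity}$).

Default constants (arbitrary units; one Euler step = one time unit):
$\tau_W = 800$, $\tau_{decay} = 1000$, $\tau_r = 20$, $I_0 = 12$,
$I_1 = 0.5$, $I_2 = 0.05$, $\delta = 15$, $E = 1.5$, $\theta = 5$,
$c = 1$, `N = 50`. `variant_params()` carries the alternative columns for
the slope, two-context and sparse variants.

## Protocol and excitability

A simulation spans `n_days = 4` days. Each day is an inter-day delay of
`ID = 1000` silent steps followed by `Nrep = 10` repetitions of
`T_rep = 100` driven steps ($\Delta = \delta$), each trailed by an
`IR = 100` step gap. Day-1 stimulation therefore occupies steps
1000–3000 and the whole run 12 000 steps.

Excitability is redrawn independently every day:
$\varepsilon_i = |\mathcal N(0, 1)|$, plus a boost $+E$ for that day's
block of ten neurons (days 1–4 boost neurons 11–20, 21–30, 31–40, 41–50 in
1-based indexing). A neuron is *active* when its rate strictly exceeds
$\theta$; the day-$d$ activity pattern $V_d$ is the rate vector at the
final step of the day's last repetition.

The day decoder needs reference patterns recorded *without* the boost.
`baseline_replay()` therefore reuses the very same daily baseline draws
(the boosted and baseline schedules share one RNG stream) and removes only
the $+E$ term, so the boosted run and its reference run differ in nothing
else. This pairing is a deliberate design choice: without shared draws the
reference patterns would carry no day-specific signature and "which day is
this pattern from?" would be ill-posed.

In the two-context protocol a random half of the neurons (context A,
drawn once per simulation) is stimulated first each day and the complement
(context B) second, each with the full repetition block and its own
preceding delay; day-1 windows are steps 1000–3000 (A) and 4000–6000 (B).
Only the stimulated half receives the drive.

## Decoders

* **Day decoder** — for each day $d$, infer
  $d_{inf} = \arg\max_{d'} \mathrm{corr}(V^0_d, V_{d'})$ over Pearson
  correlations against the baseline-replay references; the error is
  $d_{inf} - d$. Ties are broken to the earliest day and flagged.
* **Ordinal time decoder** — score every permutation $p$ of the days by
  $S(p) = \sum_i \mathrm{corr}(V_{p_i}, V_{p_{i+1}})$ and compare the true
  order against the full permutation distribution with
  $t = (S(p_{real}) - \mu) / (\sigma / \sqrt{n_{perm}})$. Two
  interpretations of the $\sqrt{\cdot}$ factor are possible (number of
  permutations vs number of neurons); they differ by a constant factor and
  do not change any ordering, and we use the permutation count
  ($n_{perm} = 24$ for four days). The real permutation is included in the
  null when computing $\mu,\sigma$. Because Pearson correlation is
  symmetric, $S(p) = S(\mathrm{reverse}(p))$ exactly, so the argmax set
  always contains at least two permutations.
* **Label shuffle** — the null for both decoders permutes each neuron's
  values across days independently (per-neuron day-label shuffle),
  preserving every neuron's multiset of rates.
* **Drift rate** — $\sum_{d=2}^{4} \big(1 - \mathrm{corr}(V_1, V_d)\big)$,
  0 for a perfectly stable code, 3 for complete decorrelation.

Zero-variance patterns (a dead or saturated network) raise an explicit
error rather than propagating `NA` silently.

## Read-out neuron

A linear output $y = \sum_i W^{out}_i r_i + \beta$ learns with a
homeostatically gated Hebbian rule,

$$\frac{dW^{out}_i}{dt} = h(\mathbf W^{out})\, r_i\, y / \tau_{out+}
  - W^{out}_i / \tau_{out-}, \qquad
  h = \max\!\big(0,\, 1 - \textstyle\sum_j W^{out}_j\big),$$

so learning stops once the summed weight reaches 1 and weights only decay
thereafter ($\tau_{out+} = 200$, $\tau_{out-} = 1000$; weights floored at
0; $h$ clamped at 0 since the raw $1 - \sum W$ would otherwise turn the
rule anti-Hebbian). The read-out integrates concurrently with the network,
with the same Euler step, because $y$ feeds its own weight update.

Because the update is proportional to $y$ itself, an exactly zero initial
weight vector can never start learning ($y \equiv 0$). Each output
therefore starts from a tiny uniform seed weight `w0 = 1e-3` per synapse
($h(0) = 0.95 \approx 1$, i.e. effectively "before learning").

The chance-level control shuffles the output weight vector uniformly; a
fresh permutation is drawn at every recorded time point (`n_shuffle = 10`
replicates). The quality index averages the summed real/shuffled output
ratio over days 2–4. In the two-context experiment two outputs receive a
supervision current $\beta_k = 0.1$ while their assigned context is
stimulated on day 1, which allocates output 1 to context A and output 2
to context B.

## Numerical choices

* Explicit Euler, `dt = 1`, with the per-step order: inhibition from the
  current rates → rate update → weight update from the *new* rates →
  clip to $[0, c]$ → mask. The mask is applied after the clip (a masked
  synapse is structurally absent). These orderings are conventions; at
  `dt = 1` with $\tau_r = 20$ their effects are far below the run-to-run
  variability across seeds, and the suite pins them with a scalar-loop
  oracle at $10^{-10}$ precision.
* `dt <= tau_r` is enforced so rates cannot become negative.
* Naive initial conditions: $r(0) = 0$, $W(0) = 0$.
* "Active" is strict ($r > \theta$); boundary ties are not active.
* Non-finite dynamics abort with the offending step index instead of
  being clipped silently.
* Neuron indices are 1-based throughout (R convention); the read-out
  center of mass $\sum_i i\,W^{out}_i / \sum_i W^{out}_i$ is reported in
  those coordinates.
* For the block-size sweep, a width-$w$ protocol boosts the 0-based range
  $[d\,w, (d+1)w)$ on day $d$, wrapped modulo $N$; at $w = 10$ this
  reproduces the default blocks, and at larger widths the wrap-around
  keeps blocks inside the network at the cost of partial overlap between
  days.

## What the generator emulates — and the regime it lands in

The simulator *is* the data generator: every analysis in the package runs
on activity produced from a configuration plus a seed, and a fixed
(config, seed) pair reproduces every table bit-for-bit. It emulates
multi-day reactivation of a single ensemble (or two interleaved
ensembles) under daily redraws of intrinsic excitability. It does not
emulate spiking statistics, structured topology beyond the random mask,
within-day excitability fluctuations, neuromodulation, or any behavioural
read-out — conclusions about real recordings therefore rest on the
model's premises, not on the tests passing.

Under the default constants the network operates in a **sharply
competitive** regime, and this shapes every downstream result. During a
stimulation the linear inhibition term ($I_1\sum r$) keeps the population
budget small until the Hebbian positive feedback ignites, and the ignition
recruits only the handful of neurons with the highest current total input;
once their mutual weights saturate at the cap, the inhibition they
generate excludes everyone else. Concretely (seed 0, defaults): the day-1
assembly comprises 4–6 neurons drawn from the top of the excitability
distribution, with within-assembly weights ~40× background; assemblies
re-form each day almost from scratch, so the drift rate sits near its
saturation value of 3, the day-1 pattern decorrelates within one day, and
the ordinal decoder's real-order score is not reliably maximal. The
decoders, read-out and shuffle controls all behave mechanically as
specified — the day decoder is exact whenever the reference and target
ensembles coincide (e.g. at `E = 0`), the read-out output beats its
shuffled-weight control in every seed and its center of mass follows the
winning blocks across days — but the *gradual* flavour of drift (partial
ensemble turnover day over day) is only approached, not robustly
attained, at the published operating point. A development-time sensitivity
analysis (integration order, time step, boost form, decay constant, noise
injections, plasticity gating) found the compact-assembly regime robust to
all of them; slowing the weight decay several-fold softens the turnover
but degrades the day decoder and contradicts the stated constant, so the
published constants are kept as-is and the package reports what they
produce.

## Problem sizes

The test-suite and the acceptance script use the study-scale conditions:
`N = 50`, 12 000-step runs (24 000 for two contexts), 10 seeds per
condition, 10 label shuffles or weight shuffles per seed. The full suite
runs in roughly eight minutes and `scripts/acceptance.R` in about three
on one core. Unit tests of the operations use reduced networks
(`N = 5–20`, a few hundred steps) with a non-vectorized scalar oracle.

## Known limitations

* The compact-assembly regime above: at the default operating point the
  model yields abrupt rather than gradual ensemble turnover, and
  day-decoder exactness degrades when reference and target ensembles
  diverge.
* The ordinal decoder enumerates all `n_days!` permutations and is
  limited to 8 days.
* The homeostatic read-out assumes a single scalar budget
  ($\sum W^{out} = 1$); no synapse-specific normalization is modelled.
* Serialization uses plain CSV/JSON containers; very long rate traces are
  better regenerated from (config, seed) than stored.
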