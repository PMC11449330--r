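---
title: "A three-population integrate-and-fire model of developing sleep-wake behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-population integrate-and-fire model of developing sleep-wake behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnet)
```

## The model

Infant mammals alternate rapidly between short sleep and wake bouts whose
durations are both exponentially distributed; through development the mean
bout lengths grow and the wake-bout distribution becomes heavy-tailed
(power-law-like), while sleep stays exponential. `somnet` simulates the
standard circuit-level account of this behaviour: three brainstem
populations of leaky integrate-and-fire (LIF) neurons — wake-active (WA,
dorsolateral pontine tegmentum), sleep-active (SA, nucleus pontis oralis)
and wake-promoting (WP, the locus coeruleus, LC) — coupled all-to-all with
signed synaptic weights.

Each neuron's membrane potential $v(t)$ evolves as

$$\frac{dv}{dt} = -\frac{C}{\tau}\,(v - V_0)
  \;+\; \sum_{X} \pm\, s_{XY}\,\frac{\Sigma_X}{N_X}
  \;+\; p_Y\, X_{\mathrm{Pois}},$$

where $V_0 = -70$ mV is the resting potential, $\tau = 15$ ms the membrane
time constant, $C = 1$ a capacitance factor, $\Sigma_X$ the number of
spikes emitted by population $X$ at the previous step, $N_X$ its size,
$s_{XY} \ge 0$ the synaptic strength from $X$ onto target population $Y$,
and $X_{\mathrm{Pois}}$ an independent Poisson(1) draw per neuron per step
scaled by the population's noise multiplier $p_Y$. A neuron whose updated
potential reaches the $-55$ mV threshold emits a spike and resets to
$V_0$. The signs are structural: WA and SA excite themselves and inhibit
each other; WA and WP excite each other; SA inhibits WP; WP sends nothing
to SA. Mutual inhibition makes the WA/SA pair a bistable switch whose two
metastable states are read out as WAKE and SLEEP; the per-neuron Poisson
drive supplies the fluctuations that trigger transitions.

## Numerical scheme and conventions

Several integration details matter and are fixed as follows.

* **Forward Euler with dt = 1 ms.** Times are in milliseconds throughout;
  with $\tau = 15$ and a 15 mV threshold gap, the default noise scales
  ($p \approx 1.05$) place the mean drive exactly at the spiking boundary
  under 1 ms steps, which is what makes the switch noise-driven rather
  than deterministic.
* **Spike handling.** Threshold crossing registers one spike and resets
  the voltage to rest in the same step. There is no refractory period and
  no action-potential excursion (it would be cosmetic here), and no lower
  clamp — mutual inhibition legitimately drives the inactive population
  below rest. We verified that adding even a one-step refractory clamp
  roughly halves mean bout lengths and destroys the wake/sleep asymmetry
  of LC firing, so the no-refractory convention is also the one that
  reproduces the published statistics.
* **One-step synaptic delay.** $\Sigma_X$ entering the update from step
  $t$ to $t+1$ is the count recorded at step $t$; this breaks the
  algebraic loop of simultaneous spiking.
* **Uniform population coupling.** The synaptic term
  $s_{XY}\Sigma_X/N_X$ is applied to every neuron of the target
  population exactly as written, including a neuron's own previous spike
  in its self-excitation term. The alternative (excluding the own spike)
  is not an $O(1/N)$ correction at $N = 5$: it weakens effective
  self-excitation enough to shorten mean bouts by 25–40% and pushes the
  developmental (LC-strength) bout means well away from their published
  values, so the uniform mean-field reading is used.
* **Initial conditions and reproducibility.** All voltages start at rest;
  one seeded generator is consumed in a fixed order (per step: all
  Poisson draws population-major, neuron-minor, then all updates), so a
  run is bit-reproducible from its seed, and the compiled stepping loop
  is verified against a plain-R reference implementation in the tests.

## Behavioural-state analysis

States are classified from population spike counts with a trailing 30 ms
sliding window: step $t$ is WAKE if WA fired more spikes than SA over
$(t-30, t]$, SLEEP if SA fired more; ties keep the previous label, and
steps before the first strict majority inherit it. WP activity never
enters classification. The first `burn_in` steps (default 1000; half the
run for very short runs) are discarded before classification.

Bouts are maximal runs of one label. The first and last runs are censored
— their true durations are unknown — so they are flagged and excluded
from statistics, which report per state the count, arithmetic mean,
population standard deviation and maximum of the interior bout durations.
No minimum-bout-length filter is applied. The LC concordance analysis
computes WP spikes per second per neuron separately over wake- and
sleep-labelled time; `representative_lc_rates()` instead samples the
first 1000 ms of each interior bout at least that long and reports the
median per-bout rate, a robust reading of a "representative bout".

Distribution shape is diagnosed from the empirical survivor function
$\hat S(t) = \#\{T_i \ge t\}/n$ evaluated at each distinct observed
duration. An exponential sample is linear in $\log \hat S$ versus $t$, a
power law in $\log \hat S$ versus $\log t$; `fit_exponential()` reports
the maximum-likelihood rate $\hat\lambda = 1/\bar T$ plus the semi-log
OLS $R^2$, and `loglog_linearity()` the log-log OLS slope and $R^2$
(optionally over only the upper tail of the curve; the default uses the
whole curve). `shape_report()` labels a state by whichever scale is more
linear — at most "power-law-like", never a power-law claim, since
mixtures of exponentials can be log-log linear too. Histogram tables use
Freedman–Diaconis bins.

## Presets and what the generator emulates

`preset_names()` lists the registered configurations. The three
small-network presets (`n5-no-lc`, `n5-moderate-lc`, `n5-strong-lc`; 5
neurons per population, recommended $10^6$ steps) differ only in the
LC-coupling column — $s_{LC\,WA}$ of 0/3/4 with matching changes in
$s_{WA\,LC}$, $s_{SA\,LC}$, $s_{LC\,LC}$ and the SA noise scale — and
emulate infancy, adolescence and adulthood. The mutual-inhibition
variants (`n5-weak-mi`, `n5-moderate-mi`, `n5-strong-mi`) scale the
reciprocal WA–SA strengths to 75/100/125% of 24 on the no-LC base. The
large-network presets (`n500-*`, $10^5$ recommended steps) use the
rescaled strength table for 500-neuron populations; `n50-strong-lc`
applies those strengths at the intermediate size (no published column
exists for $N = 50$, so it is explicitly an interpolation), and the
`legacy-*` presets reproduce the earlier two-population
mutual-inhibition-only systems (1 or 10 neurons per population, no
self-excitation, WP inert).

Two preset fields required judgement. The large-network table prints only
synaptic strengths, so membrane constants and noise multipliers are
inherited from the small network; we inherit the *no-LC* column's
$p_{SA} = 1.05$ for every large-network case. Carrying the LC-bearing
columns' $p_{SA} = 1.08$ instead makes sleep absorbing at $N = 500$ — the
rescaled LC strengths (~0.2) contribute only ~0.005 mV/ms while a 0.03
mV/ms noise asymmetry is systematic at large $N$, and a full $10^5$-step
run then produces zero bouts, contradicting the switching the model is
meant to show. Second, the published remark that mutual inhibition should
be roughly 2.5× self-excitation conflicts with the printed 24 versus 6;
the presets follow the printed table.

## What the simulations show — and what they do not

At the preset study conditions ($10^6$-step small-network runs) the
package's own test suite and acceptance script recompute, among others:
near-equal wake/sleep bout means without LC coupling; a greater-than-4×
increase in mean wake bout length from no-LC to strong-LC with less than
2× change in sleep; strictly increasing bout means across the
mutual-inhibition sweep; LC firing concentrated in wake (rate ratio
within [1.5, 4.5]); and a strong-LC maximum wake bout more than 5× the
no-LC maximum. Bout means land within roughly 10–20% of the published
values — the exact integration conventions behind those numbers are not
fully recoverable, and the conventions above were fixed on first
principles, not per-quantity.

One published feature does **not** emerge under these conventions: while
strong LC coupling lengthens wake bouts dramatically and fattens their
maximum, the simulated wake-bout distribution remains close to
exponential in shape (semi-log $R^2 > 0.92$, SD/mean near 1), so its
survivor curve does not become *more* log-log linear than the no-LC one.
The corresponding assertions in the acceptance tests are deliberately
left failing rather than weakened. The published SD/mean range of
1.4–1.7 implies bout sets far more dispersed than any classification
convention we examined (windows of 5–30 ms, both tie rules, either
self-coupling reading) produces from this model.

These are simulations of an idealised circuit: homogeneous populations,
all-to-all coupling, no synaptic kinetics, delays, refractoriness, LC
oscillations or synchrony, and no EEG/EMG observation model. Passing
tests show the implementation reproduces the *model's* behaviour under
its stated conditions, not that the model captures any particular real
recording.

## A short run

```{r example, eval = FALSE}
library(somnet)
summary <- run_experiment("n5-strong-lc", steps = 1e6, seed = 8)
summary
```

Problem sizes used throughout the test suite are the study conditions
above: $10^6$ steps for the $N = 5$ presets, $10^5$ for $N = 500$,
$2 \times 10^5$ for $N = 50$; unit and property tests use hundreds of
steps, where the compiled core is checked step-for-step against the
plain-R oracle.
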