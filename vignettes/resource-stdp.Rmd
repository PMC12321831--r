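---
title: "Resource-dependent heterosynaptic STDP: model and implementation notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource-dependent heterosynaptic STDP: model and implementation notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`restdp` simulates a pool of $N_\mathrm{exc} = 200$ excitatory neurons,
recurrently connected with probability 0.25 by plastic synapses, driven by
$N_\mathrm{in} = 50$ independent Poisson spike trains that each contact a
neuron with probability 0.10. All connections carry axonal delays drawn
uniformly from 1–5 ms. Everything is integrated with forward Euler at
$dt = 0.1$ ms.

**Neurons** are refractory leaky integrate-and-fire units,

$$\tau_v \frac{dv_n}{dt} = -v_n + r_n \Big(\sum_i s_i + \sum_j s_j\Big),
  \qquad v_n \to 0 \text{ if } v_n \ge \theta,$$

with $\tau_v = 25$ ms and threshold $\theta = 1$. A spike starts a 3 ms
absolute refractory period (the membrane is clamped at 0 and the threshold
test is disabled; synaptic and refractory dynamics keep integrating), and the
relative-refractoriness gain $r_n$ is reset to 0 at the spike and recovers as
$\tau_r\, dr_n/dt = 1 - r_n$ with $\tau_r = 5$ ms.

**Synaptic currents** are double-exponential pairs,
$\tau_{sr}\,ds' \!/dt = -s' + I\,w$ and $\tau_{sf}\,ds/dt = -s + s'$, with
rise $\tau_{sr} = 2.6$ ms and fall $\tau_{sf} = 31.3$ ms; a presynaptic
arrival through weight $w$ increments $s'$.

**Plasticity** extends pair-based STDP with a conserved local resource. A
pre/post pair at timing difference $\tau = t_\mathrm{post} - t_\mathrm{pre}$
requests

$$f(\tau) = \begin{cases} e^{-\tau/\tau_\mathrm{STDP}} & \tau \ge 0 \\
  0.18\, e^{\tau/\tau_\mathrm{STDP}}\, w & \tau < 0 \end{cases}$$

with $\tau_\mathrm{STDP} = 20$ ms. Depression is weight dependent (silent
synapses are never depressed) and carries the 0.18 multiple that balances it
against the extra depression contributed heterosynaptically. What makes the
rule distinctive is that a potentiation request is **funded**, not simply
applied:

1. the neighbors within 3 dendritic positions of the potentiating synapse
   are depressed by exponential-distance shares of the request, each capped
   at its current weight (heterosynaptic depression);
2. any shortfall is drawn from a per-neuron resource pool $p_n$, capped at
   the pool level;
3. the synapse gains exactly what was collected, so
   $\sum_j w_j + p_n$ on the neuron is invariant under every plasticity
   event. If neighbors and pool are empty, potentiation is impossible.

Depression relocates the removed weight into the pool for reuse. Pools start
log-normal, $p_n = 2 e^{\xi}$ with $\xi \sim \mathcal N(0,1)$, decay with
$\tau_p = 10$ s, and are the only leak in the resource budget: over any run
without deletion, initial total resources equal final weights + pools +
integrated pool decay (the engine tracks this accumulator, and the tests
assert it).

Recurrent weights start at 0 — a newly formed network of silent spines —
and input weights are fixed, uniform on (0, 1).

## Choices the equations leave open

These were genuinely open in the model description; each is exposed as a
parameter and the default is stated here once.

**Unitary PSC amplitude.** Read literally under forward Euler, an arrival
adds $w\,dt/\tau_{sr}$ to $s'$, which makes the summed input drive of a
typical neuron about $0.01\,\theta$ — the network could never fire. We
therefore normalize the unitary current to its peak: an arrival adds
`psc_peak_gain()` $\times\, w \approx 15.08\,w$ to $s'$, so a single spike
through weight $w$ produces a current excursion peaking at exactly $w$
(7.05 ms after arrival). This is the standard amplitude convention for
double-exponential synapses; with it the 50 Hz stimulus gives a mean drive
of a few $\theta$ and the network fires in the reported regime. The gain is
the model's excitability scale and is exposed as `syn_gain`.

**Pairing scheme.** Nearest-spike pairing with re-use: every presynaptic
arrival pairs with the neuron's most recent postsynaptic spike (depression),
and every postsynaptic spike pairs with each afferent's most recent arrival
(potentiation). Timing is measured at the synapse, i.e. after the axonal
delay. Exact coincidences ($\tau = 0$) count as potentiation. Pairings with
negligible requests are still applied but excluded from the event log below
a `log_min_request` threshold (default $10^{-8}$).

**Kernel normalization.** The six neighbor shares
$e^{-|k|}/\big(2\sum_{k'=1}^{3} e^{-k'}\big)$ sum to exactly 1, so fully
neighbor-funded potentiation conserves resources by construction — the
stated purpose of the rule. At dendrite ends, and across the gaps left by
deleted synapses, the kernel is renormalized over the neighbors that exist;
the alternative (leaving shares unnormalized) would systematically
under-potentiate edge synapses.

**Scarce neighbors.** A neighbor holding less than its share gives
everything it has and the rest of the shortfall moves to the pool stage; the
shortfall is not redistributed among the other neighbors. When several
afferents of one neuron potentiate in the same time step they are processed
in ascending dendritic position — under scarcity the order matters, so it is
fixed and seed-stable.

**Refractoriness.** The reset value of $r$ at a spike is not stated by the
equations; the default is 0 (`r_reset`), and $r$ recovers during the
absolute refractory period while the membrane stays clamped.

**Dendritic layout.** Synapses occupy contiguous integer positions
0..(m−1) on each target neuron, ordered by presynaptic index by default
(`dendrite_order = "random"` gives a seeded permutation instead). Input
synapses are not plastic and do not occupy dendritic positions; only
recurrent synapses compete for resources.

## Protocols

**Learning** (`run_learning`): 50 Hz input for the first 20 s, then free
running to 40 s. A memory has been learned when a subset of neurons keeps
firing after the input stops.

**Degeneration** (`run_degeneration`): the learning protocol to 40 s, then
one uniformly-random surviving recurrent synapse is deleted per interval.
With replenishment the deleted weight joins the target neuron's pool (and
can fund compensatory potentiation of survivors); without it the weight is
discarded. The run stops when no spike has occurred anywhere for 500 ms
(`quiet_window`) — once the network has been silent that long, with no
input, it cannot restart — or when no synapses remain.

The deletion rate is not part of the model description; the default spreads
all deletions uniformly over a 100 s deletion phase (`total_duration`
140 s), i.e. one deletion per ≈10 ms for the default network. The
"time to weight-sum zero" used in the degeneration comparison is the
duration from deletion onset to the end of the weight-sum trace's decay:
the first time the trace reaches 0, or activity cessation, whichever comes
first — after cessation plasticity is silent and the trace no longer
evolves, only the deletion bookkeeping would.

## Seeding and reproducibility

A master seed spawns four independent sub-seeds (topology, pools, input
spikes, deletion order) via `derive_seeds()`, so experiments can vary one
source of randomness at a time, and paired replenish-on/off runs share
network, input and deletion order exactly. Identical configurations are
bit-reproducible end to end.

## Numerical notes

* Forward Euler at $dt = 0.1$ ms throughout; the linear subsystems are well
  inside the stability region ($dt/\tau_{sr} \approx 0.04$ is the largest
  step-to-constant ratio).
* The engine integrates per-neuron current aggregates rather than per-synapse
  currents — exact for linear dynamics up to floating-point summation order.
  The test suite contains a brute-force per-synapse R implementation with
  explicit per-event bookkeeping; on a 3-neuron fixture over 200 steps the
  optimized engine reproduces its spike raster, weights, pools and event log
  bit-for-bit, and membrane trajectories to $10^{-12}$.
* Resource caps use `min()` against the available amount, so weights and
  pools can touch 0 exactly but never go negative; per-event conservation
  holds to $10^{-12}$ (asserted), and whole-run budgets to $10^{-8}$
  relative.
* Ties: $v = \theta$ exactly counts as a spike; a pre arrival and post spike
  in the same step pair with $\tau = 0$ (potentiation).

## What the simulations show — and what they do not

All inputs are generated internally (Poisson trains, Bernoulli topology,
log-normal pools); there is no external data. The simulations reproduce the
qualitative hallmarks the rule was built for: unimodal weight distributions
with a silent-synapse peak and long tail, reduced/non-potentiability under
resource scarcity, increasing nonfilopodia spine spacing, and the
compensatory response to synaptic deletion with pool replenishment. They do
not model inhibition, structural spinogenesis, multi-compartment dendrites,
resource diffusion times, or any molecular identity for the resource; and a
point-process input with homogeneous rate is the simplest possible stand-in
for afferent drive. Quantitative outcomes of the degeneration experiment
(remaining-connection fractions at cessation, decay-time ratios) depend on
the deletion rate, which the model description leaves open — comparisons
across conditions on paired seeds are the robust statements.

Problem sizes used by the test suite: the property and equivalence tests run
on 2–50 neuron fixtures in milliseconds; the experiment-level checks run the
full 200-neuron protocol for 10 seeds (learning) and 10 paired seeds
(degeneration), a few minutes of compute in total.

```{r example}
library(restdp)
cfg <- run_config(seed = 1)
sim <- run_learning(cfg)
rep <- metric_report(sim)
d_on <- run_degeneration(run_config(
  protocol = protocol_config(total_duration = 140), seed = 1))
```
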