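# restdp

Resource-dependent heterosynaptic STDP in recurrent spiking networks.

## The problem

Pair-based STDP on its own destabilizes recurrent networks: potentiation
begets activity begets potentiation, so models usually bolt on global
controls (hard weight bounds, synaptic scaling, weight normalization) that
have no clean biological counterpart. Experiments, meanwhile, show unimodal
synaptic weight distributions peaking near zero with a long tail, silent and
non-potentiable synapses, and heterosynaptic depression of unstimulated
spines near a stimulated one — as if spines competed for a limited local
resource.

`restdp` implements an STDP rule built around that competition, for
computational neuroscientists studying learning stability, synaptic
homeostasis, and degeneration. Potentiation must be *funded*: a potentiating
synapse draws resources from its dendritic neighbors (depressing them with
exponentially decaying shares up to 3 positions away) and from a per-neuron
resource pool; depression relocates weight back into the pool. Every
plasticity event conserves the neuron's total resources,

    sum_j w_j + p_n  =  const   (per event; the pool alone decays, tau_p = 10 s)

so each synapse finds its own saturation point and no global constraint is
needed. The STDP window is

    f(tau) = exp(-tau / tau_STDP)              tau >= 0   (potentiation request)
    f(tau) = 0.18 * exp(tau / tau_STDP) * w    tau <  0   (depression request)

with tau_STDP = 20 ms, nearest-spike pairing, and weight-dependent
depression. The network is the standard test bed: 200 refractory
leaky integrate-and-fire neurons (tau_v = 25 ms, theta = 1, 3 ms absolute +
5 ms relative refractoriness), double-exponential synaptic currents
(2.6 ms rise, 31.3 ms fall), 25% recurrent connectivity with 1–5 ms axonal
delays, driven by 50 independent 50 Hz Poisson trains for the first 20 s.
Recurrent weights start at zero; resource pools start log-normal
(p = 2 e^xi). Forward Euler at dt = 0.1 ms, with the inner loop in C++.

Two protocols reproduce the headline experiments: **learning** (stimulate
20 s, then free-run; a neuron subset keeps firing — a memory) and
**degeneration** (from 40 s, delete random recurrent synapses one by one;
with resources of deleted synapses replenishing the pool the network
compensates and the memory survives far more deletion than when
replenishment is blocked).

## A worked example

```r
library(restdp)

cfg <- run_config(seed = 1)      # all defaults: 200 neurons, 50 Hz x 20 s
sim <- run_learning(cfg)
print(sim)
#> stdp_sim: 40.0 s simulated, 1138058 spikes from 197 neurons
#>   final weight sum 501.142 over 1262 nonzero synapses; pool sum 22.251

# memory: activity persists after the input stops at 20 s
memory_alive(sim$raster, 40000)
#> [1] TRUE

# silent-synapse peak: most recurrent synapses end with exactly zero weight
sum(sim$weights == 0); sum(sim$weights > 0); max(sim$weights)
#> [1] 8649
#> [1] 1262
#> [1] 10.9822

# resource scarcity limits potentiation (efficacy < 100%)
eff <- potentiation_efficacy(sim$events)
mean(eff < 100)
#> [1] 0.967247

# the learned graph, delay-weighted
graph_metrics(checkpoint_network(sim, which = 20, time = TRUE))$mean_in_degree
#> [1] 7.105
```

The printed numbers above are what `seed = 1` produces on this code. The
weight sum plus pool sum plus the integrated pool decay equals the initial
pool total to numerical precision — the conservation law is checked, not
assumed.

The degeneration experiment runs as a pair on one seed (identical network,
input and deletion order; only replenishment differs):

```r
d_on  <- run_degeneration(run_config(
  protocol = protocol_config(total_duration = 140), seed = 1))
d_off <- run_degeneration(run_config(
  protocol = protocol_config(total_duration = 140,
                             replenish_on_delete = FALSE), seed = 1))
print(d_on); print(d_off)
#> stdp_degeneration (replenish on): 15.8% of synapses remained when activity ceased
#>   activity ceased at 124.2 s; weight-sum decay lasted 84.2 s
#> stdp_degeneration (replenish off): 62.0% of synapses remained when activity ceased
#>   activity ceased at 78.0 s; weight-sum decay lasted 38.0 s
```

With replenishment the memory survives to a smaller fraction of remaining
connections and the mean weight of surviving (nonfilopodia) spines rises
during deletion — the compensatory mechanism; blocking replenishment removes
both effects.

A command-line front end (`inst/scripts/restdp`) wraps the same functions:
`restdp simulate|degenerate|analyze|fixtures --config cfg.yaml --seed N --out dir/`,
with YAML configs (`load_config`/`save_config`) and plain-text outputs.

## Package layout

* `R/` — network construction, parameters/config, plasticity operations,
  engine wrapper, protocols, analysis metrics, fixtures, text serialization.
* `src/core.cpp` — the forward-Euler engine (delivery ring buffer, LIF
  dynamics, resource-dependent STDP, pool decay, deletion schedule).
* `tests/testthat/` — unit and property tests per module, a brute-force
  per-synapse reference simulator the engine must match bit-for-bit on
  fixtures, and experiment-level acceptance tests.
* `vignettes/resource-stdp.Rmd` — model description, the conventions chosen
  where the equations leave freedom, numerical notes, limitations.
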