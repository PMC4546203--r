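# motifstdp

Self-organization of two-synapse microcircuits in recurrent spiking networks
with spike-timing-dependent plasticity (STDP).

`motifstdp` is for computational neuroscientists who want to predict — not
just simulate — how pair-based Hebbian STDP reshapes the wiring of a
recurrent network of exponential integrate-and-fire (EIF) neurons driven by
its own internally generated spiking covariance. It provides three tiers
that can be cross-validated against each other:

1. **Ground truth:** a fast stochastic simulator (compiled core) of the EIF
   network with exponential synapses, white/shared noise, and online
   additive STDP with hard bounds.
2. **High-dimensional theory:** Fokker–Planck (threshold-integration)
   single-neuron statistics — stationary rate $r$, linear response
   $A(\omega)$, baseline spectrum $C^0(\omega)$ — assembled into network
   spike-train cross-covariances by linear response,
   $$C(\omega) = (I - (W\cdot K))^{-1}\, C^0(\omega)\, (I - (W\cdot K))^{-*},
     \qquad K_{ij}(\omega) = A_i(\omega) J(\omega),$$
   and a fast–slow weight evolution
   $dW_{ij}/dt = W^0_{ij}\,\epsilon\,[\,r_i r_j S + \int L(s) C_{ij}(s)\,ds\,]$
   with re-linearization as the weights drift.
3. **Reduced theory:** a closed 11-dimensional ODE system for the mean
   weight $p$ and the strengths of divergent, convergent, chain,
   recurrent-loop and open-chain motifs (plus their mixed
   weight/adjacency counterparts), whose coefficients are the four
   rule–covariance overlap integrals $S$, $S_F$, $S_B$, $S_C$. Fixed-point
   and separatrix analysis shows how balanced STDP rules make network
   structure bistable.

Network generators cover Erdős–Rényi digraphs and digraphs with correlated,
truncated power-law in/out-degree distributions (Gaussian copula coupling).

## Worked example

Predict and verify how a balanced, depression-tilted STDP rule reshapes an
Erdős–Rényi network:

```r
library(motifstdp)

net  <- weighted_network(make_erdos_renyi(300, 0.15, seed = 8))
rule <- stdp_rule_balanced(-1)          # S = -0.1 * eps * f+ tau+

## frozen operating point and rule-covariance overlaps
op   <- frozen_operating_point(noise_params(), eif_params())
ints <- stdp_integrals(rule, op)
ints
#> stdp_integrals: S = -3.333e-05, S_F = 9.758e-07, S_B = -6.321e-07, S_C = 1.549e-08
#>   operating point: r = 9.179 Hz (mu_eff = 1.1147)

## separatrix of the mean synaptic weight on the unstructured set
cfg <- motif_ode_config_from_network(net$W0)
mean_weight_fixed_points(cfg, ints)$separatrix
#> [1] 0.0716
```

The unstable fixed point sits at $p^\* = 0.072$, far below the half-max
initial condition $p(0) = p_0 W^{max}/2 = 0.375$ — so although the rule is
depression-dominated, this network's mean weight grows. The reduced ODE
system quantifies what grows at whose expense:

```r
tr <- integrate_motifs(motif_strengths(net), cfg, ints, T_total = 600,
                       n_out = 7)
round(subset(tr, time_s %in% c(0, 600),
             c(time_s, p, q_div, q_con, q_ch)), 6)
#>   time_s        p    q_div    q_con    q_ch
#> 1      0 0.372250 0.003006 0.002745 0.000105
#> 7    600 0.379301 0.003121 0.002851 0.000097
```

Mean weight, divergent and convergent motifs potentiate while chain motifs
decay — neurons become in- *or* out-hubs, not both. The same transient can
be recomputed from the high-dimensional theory (`evolve_network()`, which
re-linearizes every neuron each 100 s step) and measured in the spiking
simulation (`simulate_network()` with `plasticity_on = TRUE`); the test
suite does both.

Spiking statistics come from the same machinery:

```r
sim <- simulate_network(weighted_network(make_erdos_renyi(1000, 0.15, 1)),
                        eif_params(), noise_params(),
                        cfg = sim_config(T = 5e4, seed = 2))
spike_count_correlations(sim, sim$net_final$W0, window = 100)[1:2]
#> $all_pairs
#> [1] 0.000527
#> $connected_pairs
#> [1] 0.00133
```

## Conventions worth knowing

* Matrix entry (i, j) is the synapse j → i (row = postsynaptic).
* Weights, motif coordinates and STDP amplitudes are on a rescaled O(1)
  scale; applied synaptic amplitudes carry the factor
  `epsilon = 1/(N p0)`, keeping total input per neuron invariant.
* Frequencies are in cycles/ms (`1 = 1 kHz`), transform convention
  $\hat y(\omega) = \int y(t) e^{-2\pi i \omega t} dt$; lags in ms; rates
  in spikes/ms.
* Cross-covariances satisfy $C_{ij}(s) = \langle y_i(t+s) y_j(t)\rangle -
  r_i r_j$, so covariance from a forward connection j → i lives at
  positive lags.
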