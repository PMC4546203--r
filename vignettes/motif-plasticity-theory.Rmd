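---
title: "Self-consistent STDP theory and motif dynamics: models, numerics, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-consistent STDP theory and motif dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in `motifstdp`: the models and
their assumptions, the numerical methods behind each exported function, the
parameters that matter (with units and defaults), and the places where the
design was genuinely open and a choice had to be made. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The model

### Neurons and network

Each of the `N` neurons is an exponential integrate-and-fire (EIF) unit,

$$C \frac{dV_i}{dt} = g_L (V_L - V_i) + g_L \Delta e^{(V_i - V_T)/\Delta}
  + I_i(t) + \sum_j W_{ij} (J * y_j)(t),$$

with a numerical spike registered at `Vth = 30` mV, reset to `Vre = -72` mV
and an absolute refractory period of 2 ms. Synapses are current-based
exponentials, `J(t) = H(t) e^{-t/tauS}` with `tauS = 5` ms, so `W_{ij}` is
the peak postsynaptic current (uA/cm^2) of the synapse from `j` to `i`
(matrix orientation: **row = postsynaptic, column = presynaptic**,
everywhere, including all CSV output). External input is white noise,
`I_i = mu + g_L sigma D xi_i(t)` with `D = sqrt(2C/g_L)`, which makes the
stationary standard deviation of the passive membrane voltage equal to
`sigma` independently of the membrane time constant. Defaults (`eif_params()`,
`noise_params()`): `C = 1`, `g_L = 0.1`, `V_L = -72`, `Delta = 1.4`,
`V_T = -48`, `mu = 1`, `sigma = 9`, `N = 1000`, connection density
`p0 = 0.15`, `Wmax = 5`.

Weights, motif coordinates and STDP amplitudes live on a rescaled O(1)
scale; the synaptic amplitudes actually applied are multiplied by
`epsilon = 1/(N p0)`. This keeps the summed input per neuron constant as
`N` or `p0` change, which is what makes networks of different size
comparable (and is why shrinking the network speeds learning by exactly the
ratio of the epsilons).

### Plasticity

The pair-based additive Hebbian STDP window for a lag `s = t_post - t_pre`
is exponential on each side: amplitude `f_plus`, timescale `tau_plus` for
`s >= 0`; amplitude `-f_minus`, timescale `tau_minus` for `s < 0`; hard
bounds `0 <= W <= Wmax` are enforced per branch (potentiation is blocked at
the upper bound, depression at zero). All pre/post pairs contribute;
exactly coincident pairs are credited to potentiation. The simulator
implements this with two exponential traces per neuron, which makes
all-to-all pairing exact at O(1) cost per spike.

The net area `S = f_plus tau_plus - f_minus tau_minus` classifies rules:

* *unbalanced* (`stdp_rule_unbalanced()`): `|S|` of order `f tau`; firing
  rates dominate and all weights drift together;
* *balanced* (`stdp_rule_balanced()`): `S = ± delta * epsilon * f_plus
  tau_plus` (the *relative* convention for the imbalance `delta`, default
  0.1; the absolute scale of `S` is not separately identifiable, so tying it
  to the potentiation area is the natural normalization). Here spike-timing
  covariance, not rate, decides what happens.

The window timescales are not uniquely pinned down by the modeling context;
we default to `tau_plus = 20` ms, `tau_minus = 40` ms with `f_plus = 2.5e-3`
(rescaled scale), i.e. potentiation sharper and stronger per pair than
depression, the experimentally typical shape. `f_plus` only sets the speed
of learning (none of the fixed points or separatrices depend on it); the
default traverses the weight range in roughly an hour of biological time
under an unbalanced rule.

## 2. Fast-slow theory

Because single weight changes are tiny, weights are effectively frozen on
the millisecond timescale of spiking covariance. Averaging the pair rule
over that fast timescale gives the drift

$$\frac{dW_{ij}}{dt} = W^0_{ij}\,\epsilon \left[ r_i r_j S +
  \int L(s)\, C_{ij}(s)\, ds \right],$$

where `C_ij(s) = <y_i(t+s) y_j(t)> - r_i r_j`. (The lag convention is fixed
by requiring that covariance from a forward connection overlap the
potentiation side of the window; it implies `C_ij(s) = C_ji(-s)`, which the
estimator reproduces exactly.) The theory predicts the *drift* only; the
spike-driven diffusion around it is visible in simulations as trial-to-trial
spread.

### Single-neuron statistics

`stationary_rate()`, `linear_response()` and `power_spectrum()` solve the
Fokker-Planck equation of the white-noise-driven EIF by threshold
integration: flux/density pairs are integrated downward from the absorbing
boundary at `Vth` with reinjection at `Vre`, using an exponential
integrating-factor step that is robust where the spike current makes the
drift huge. The refractory period enters as a dead time for the rate, a
delayed reinjection for the linear response, and a pure delay factor on the
first-passage-time transform; the power spectrum follows from the renewal
relation `C0 = r (1-|f|^2)/|1-f|^2`. The zero-frequency point of a
modulated solve is degenerate and is filled by even/odd quadratic
extrapolation from the neighbouring grid points — the test suite checks
`A(0)` against an independent finite difference `dr/dmu` to better than 1%.

Numerical defaults (validated by self-convergence, not inherited from any
reference implementation): voltage grid of 4000 points from
`min(V_L + mu/g_L, V_re) - 6 sigma` to `Vth`; frequency grids
`frequency_grid(1, 1/2048)` for scalar rule-covariance quadratures and
`frequency_grid(0.5, 1/512)` for network solves. The quadrature values of
`S_F`, `S_B`, `S_C` change by under 0.2% when either grid is refined
twofold.

### Network covariances

`full_covariance()` evaluates
`C(w) = (I - W.K)^{-1} C0 (I - W.K)^{-*}` frequency by frequency with dense
LU solves (`K_ij = A_i J`, `C0` diagonal: only internally generated
correlations). A spectral-radius guard at `omega = 0` rejects coupling too
strong for linearization. `truncated_covariance()` keeps only length-one
paths — direct forward, direct backward, and common input — which is the
approximation the reduced motif theory is built on. Self-consistent rates
come from damped fixed-point iteration of `r_i = r(mu + tauS (W r)_i,
sigma)`; per-neuron spectral statistics are shared between neurons whose
effective input agrees to within 0.002 uA/cm^2 (the rate differs by less
than ~2e-5 spikes/ms across such a bin).

`evolve_network()` advances all weights with Euler steps of 100 s of
biological time (halving the step changes endpoint weights by under 1% in
the test suite), re-linearizing every neuron at every step.

## 3. The reduced motif theory

`motif_strengths()` maps a weighted network to 12 coordinates: mean weight
`p`; divergent/convergent/chain strengths `q_div, q_con, q_ch` (variance of
weighted out-degrees, variance of weighted in-degrees, and their covariance,
each above the chance level `p^2`); the chain split `q_ch = q_rec + q_op`
into disynaptic loops and open chains (exact by construction); five mixed
weight/adjacency motifs `qX_*` (mean weight conditioned on motif
membership); and the loop-conditioned second moment `qX2_rec`.

`motif_rhs()` implements the closed ODE system for these coordinates. Its
coefficients are the four scalars computed by `stdp_integrals()` — `S` and
the rule-covariance overlaps `S_F` (forward), `S_B` (backward), `S_C`
(common input) — frozen at the operating point of a network with all
weights at `Wmax/2` (`frozen_operating_point()`). For the default Hebbian
shape, `S_F > 0`, `S_B < 0`, `S_C > 0` and `S_F + p0 S_B > 0`; the test
suite asserts this sign structure rather than particular values.

Points worth knowing about the reduced system:

* **Invariant set.** With `q0 = 0` and all motif coordinates zero, the
  printed equations keep `q_div, q_con, q_ch` and the four mixed div/con/
  chain coordinates exactly at zero, and `p` follows the scalar quadratic
  `dp/dt = p0 r^2 S + eps (p (S_F + p0 S_B) + p^2 S_C)`. The
  loop-conditioned coordinates (`qX_rec`, `q_rec`, `qX2_rec`) are *not*
  exactly invariant: they drift at O(eps) through the backward-covariance
  term `eps (1-p0)(qX_rec + p p0) S_B` (this term follows directly from
  re-deriving the system, so the drift is a property of the theory, not a
  transcription artifact). The invariant-set statement is therefore exact
  for the measurable motif strengths and leading-order for the
  loop-conditioned auxiliaries; the tests assert exactly that.
* **Unbalanced closed forms.** Integrating the rate-only system gives
  `q^a(t) = q^a(0) + 2 qX^a(0) r^2 S t + q0^a (r^2 S)^2 t^2` for
  `a = div, con` (chains use the sum of the two mixed chain coordinates).
  `unbalanced_solution()` uses these coefficients — the ones implied by the
  ODE system itself — and the tests verify trajectory/closed-form agreement
  at integrator tolerance. Because the quadratic term carries `S^2`, motif
  structure is expansive even under depression-dominated rules.
* **Fixed points.** On the unstructured set the mean weight obeys a
  quadratic; for balanced depression-tilted rules one root is positive and
  unstable (`mean_weight_fixed_points()`), the separatrix between network
  potentiation and depression. It rises with `p0`.
* **Frozen coefficients and their cost.** Freezing `r, S_F, S_B, S_C` at
  one operating point discards the coupling between per-neuron rate
  heterogeneity (effective input scales with weighted in-degree) and motif
  drift. Comparing against the high-dimensional theory (which re-linearizes
  per neuron) on Erdos-Renyi transients: `p` and `q_div` agree to a few
  percent of their dynamic range; `q_con` — conditioned on postsynaptic
  neurons, where the heterogeneity lives — is reproduced to ~10-20%; and
  `q_ch`, an order of magnitude smaller than the other motifs in ER
  networks, is dominated by these beyond-closure effects and is only
  meaningful on the dominant motif scale. The acceptance tests encode these
  graded tolerances. The closure itself (re-summing three- and four-synapse
  motifs into one- and two-synapse strengths) was checked term by term
  against exact matrix sums with frozen scalar statistics and is accurate to
  ~0-13% per term at `N = 300`.
* **No bounds.** The reduced system ignores the weight bounds (it describes
  the pre-saturation transient); `integrate_motifs()` warns when `p` leaves
  `[0, p0 Wmax]`.

## 4. The simulator as ground truth

`simulate_network()` is an Euler-Maruyama integrator (`dt` default 0.05 ms,
resolving `tauS` and both STDP windows) with hard-threshold spike detection,
reset and refractoriness, exponential synaptic currents, and optional online
STDP. Noise uses dedicated xoshiro256++ streams (private noise, common
input, initial conditions are independent substreams, so switching one
feature does not reshuffle another's draws; runs are bit-reproducible given
the seed). Refractory neurons still consume their private-noise draw so
spike timing does not desynchronize the streams. A configurable cap on the
network-mean rate (default 200 Hz) aborts runaway (rate-unstable) runs with
an error, mirroring the spectral-radius guard of the theory.

Common input can be white or an Ornstein-Uhlenbeck process with a 5 ms
timescale. The OU process is normalized to unit stationary variance (the
common current is `sqrt(c) g_L sigma D z(t)`); the alternative unit-
spectral-density normalization makes the shared-input covariance peak an
order of magnitude weaker and, in a reciprocally connected pair, too weak
for joint potentiation to outlast synaptic competition at `c = 0.05`.

### What the generator does and does not emulate

The synthetic networks (`make_erdos_renyi()`, `make_degree_correlated()`)
and the simulator define the study conditions: excitatory-only recurrent
networks, homogeneous cellular parameters, stationary white-noise drive,
current-based synapses without delays. Degree-structured networks draw
in/out-degree targets from a two-piece truncated power law (exponents 0.2
and -1, break at `N/10`, cut at `N`), couple them with a Gaussian copula,
and realize edges with Chung-Lu probabilities `d_in,i d_out,j/(N^2 p0)`
(clipped at 1 with a warning). Because continuity at the break, unit
normalization and a mean of `N p0` cannot hold simultaneously for this
family, the drawn degrees are rescaled to the target mean — the one reading
of the construction that satisfies all stated constraints at once. Passing
tests on these fixtures show the theory is self-consistent under its own
assumptions; they do not speak to inhibition, conductance synapses,
transmission delays, triplet/voltage/calcium plasticity rules, or
non-stationary drive, all of which are out of scope.

## 5. Numerical choices, degenerate inputs, limitations

* Frequency-domain quantities are stored on the nonnegative half-grid and
  mirrored by Hermitian symmetry; inverse transforms check for aliasing
  (spectral energy at the grid edge above 1% of peak is an error) and
  subtract the white floor `r` before transforming diagonal spectra.
* The covariance solve treats frequencies independently (results do not
  depend on evaluation order); per-frequency work is one LU factorization
  plus triangular solves restricted to the requested neuron subset.
* Empty graphs, zero weight matrices and silent neurons are legal inputs:
  motif statistics return zeros, the covariance collapses to the baseline
  spectra, and correlation averages exclude silent neurons (reporting the
  count).
* Degenerate STDP windows with `f_plus tau_plus = f_minus tau_minus` have
  `S = 0` exactly (used by the tests to isolate covariance-driven terms).
* Known limitations: the linear-response covariance is a weak-coupling
  theory (EPSPs of a millivolt or more visibly exceed it); the reduced
  motif system inherits the frozen-coefficient limitations quantified
  above, and is expected to fail qualitatively when chain motifs are
  strongly over-represented; spike-count correlation estimates depend
  mildly on the counting window (the estimator exposes it; all reported
  correlation numbers use the 100 ms default).

## 6. Problem sizes used by the tests

The suite validates against brute-force enumeration at `N <= 12`,
Monte-Carlo spiking at `N = 2..120` with 100-400 s of biological time, the
full covariance machinery at `N = 1000` (one realization, 200-neuron
evaluation subset), and the high-dimensional-vs-reduced comparison at
`N = 300` over a 600 s transient — sizes chosen so that each check
resolves the quantity it asserts with comfortable Monte-Carlo margin.
`scripts/acceptance.R` re-runs the N = 1000 and N = 100 pipelines end to
end from a single seed.
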