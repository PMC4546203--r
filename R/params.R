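#' Exponential integrate-and-fire membrane parameters
#'
#' Parameters of the EIF membrane equation
#' \deqn{C dV/dt = g_L (V_L - V) + g_L \Delta \exp((V - V_T)/\Delta) + I(t),}
#' in which an action potential is initiated when the voltage diverges past
#' the soft threshold `VT`; numerically a spike is registered at `Vth`, after
#' which the voltage is reset to `Vre` and held for the absolute refractory
#' period `tau_ref`.
#'
#' Defaults correspond to a cortical regular-spiking operating point with a
#' 10 ms membrane time constant (`C/gL`).
#'
#' @param C membrane capacitance (uF/cm^2)
#' @param gL leak conductance (mS/cm^2)
#' @param VL leak reversal potential (mV)
#' @param Delta action-potential steepness (mV)
#' @param VT action-potential initiation threshold (mV)
#' @param Vth numerical spike threshold (mV)
#' @param Vre reset potential (mV)
#' @param tau_ref absolute refractory period (ms)
#' @return an object of class `eif_params`
#' @export
eif_params <- function(C = 1, gL = 0.1, VL = -72, Delta = 1.4, VT = -48,
                       Vth = 30, Vre = -72, tau_ref = 2) {
  p <- list(C = C, gL = gL, VL = VL, Delta = Delta, VT = VT, Vth = Vth,
            Vre = Vre, tau_ref = tau_ref)
  stopifnot(Delta > 0, tau_ref >= 0, C > 0, gL > 0)
  if (!(Vre < VT && VT < Vth))
    stop("EIF parameters must satisfy Vre < VT < Vth")
  class(p) <- "eif_params"
  p
}

#' External input (noise) parameters
#'
#' The external current to neuron i is
#' \deqn{I_i(t) = \mu + g_L \sigma D \xi_i(t), \quad D = \sqrt{2 C / g_L},}
#' so that the stationary standard deviation of the passive membrane voltage
#' equals `sigma` regardless of the membrane time constant. A fraction `c` of
#' the fluctuating part can be shared between neurons, either as white noise
#' or as an Ornstein-Uhlenbeck (OU) process with timescale `ou_tau`; the
#' private/common split uses sqrt(1-c), sqrt(c) amplitudes so the total input
#' variance does not depend on `c`.
#'
#' @param mu mean input current (uA/cm^2)
#' @param sigma noise strength (mV)
#' @param c common-input fraction in \[0, 1\]
#' @param common_kind `"white"` or `"OU"`
#' @param ou_tau OU timescale of the common input (ms)
#' @return an object of class `noise_params`
#' @export
noise_params <- function(mu = 1, sigma = 9, c = 0, common_kind = c("white", "OU"),
                         ou_tau = 5) {
  common_kind <- match.arg(common_kind)
  stopifnot(sigma >= 0, c >= 0, c <= 1, ou_tau > 0)
  p <- list(mu = mu, sigma = sigma, c = c, common_kind = common_kind,
            ou_tau = ou_tau)
  class(p) <- "noise_params"
  p
}

#' Pair-based additive Hebbian STDP rule
#'
#' The rule maps a pre/post spike-time lag s = t_post - t_pre to a weight
#' change
#' \deqn{L(s) = H(W^{max}-W) f_+ e^{-|s|/\tau_+} \;(s \ge 0), \qquad
#'       L(s) = -H(W) f_- e^{-|s|/\tau_-} \;(s < 0),}
#' with hard bounds on the weight enforced by the Heaviside factors. All
#' pre/post pairs contribute (all-to-all pairing); exactly coincident pairs
#' (s = 0) are credited to potentiation.
#'
#' `f_plus` and `f_minus` are on the rescaled O(1) weight scale used by the
#' motif theory; the amplitude actually applied to a synapse in an N-neuron
#' network is `epsilon * f` with `epsilon = 1/(N p0)`, mirroring the epsilon
#' scaling of the weights themselves.
#'
#' @param f_plus,f_minus pair amplitudes (weight units, rescaled scale)
#' @param tau_plus,tau_minus decay constants of the potentiation and
#'   depression windows (ms)
#' @param wmax hard upper bound of a single weight (rescaled scale)
#' @return an object of class `stdp_rule`
#' @seealso [stdp_rule_balanced()], [stdp_rule_unbalanced()]
#' @export
stdp_rule <- function(f_plus = 2.5e-3, f_minus = f_plus / 2,
                      tau_plus = 20, tau_minus = 40, wmax = 5) {
  stopifnot(tau_plus > 0, tau_minus > 0, f_plus >= 0, f_minus >= 0, wmax > 0)
  r <- list(f_plus = f_plus, f_minus = f_minus, tau_plus = tau_plus,
            tau_minus = tau_minus, wmax = wmax)
  class(r) <- "stdp_rule"
  r
}

#' Area under the STDP rule
#'
#' `stdp_area(rule)` returns S = integral of L(s) ds =
#' `f_plus * tau_plus - f_minus * tau_minus` (bounds ignored), the net
#' potentiation/depression bias that multiplies the firing-rate term of the
#' weight drift.
#'
#' @param rule an [stdp_rule()]
#' @return scalar S (weight * ms)
#' @export
stdp_area <- function(rule) {
  rule$f_plus * rule$tau_plus - rule$f_minus * rule$tau_minus
}

#' Balanced STDP rule presets
#'
#' Constructs a rule whose net area S is a small imbalance
#' \eqn{S = \pm \delta \epsilon f_+ \tau_+} (relative convention), so that
#' spike-timing covariance, and not just firing rates, drives plasticity.
#' `sign = +1` tilts the balance towards potentiation, `sign = -1` towards
#' depression. The potentiation window is sharper and higher-amplitude than
#' the depression window (tau_plus < tau_minus, f_plus > f_minus), the
#' experimentally typical shape.
#'
#' @param sign +1 (potentiation-dominated) or -1 (depression-dominated)
#' @param delta relative imbalance (dimensionless)
#' @param epsilon scaling 1/(N p0) of the target network
#' @param f_plus,tau_plus,tau_minus,wmax as in [stdp_rule()]
#' @return an `stdp_rule`
#' @export
stdp_rule_balanced <- function(sign = -1, delta = 0.1, epsilon = 1 / 150,
                               f_plus = 2.5e-3, tau_plus = 20, tau_minus = 40,
                               wmax = 5) {
  stopifnot(sign %in% c(-1, 1), delta >= 0, epsilon > 0)
  ## S = f+ tau+ - f- tau- = sign * delta * epsilon * f+ tau+
  f_minus <- f_plus * (tau_plus / tau_minus) * (1 - sign * delta * epsilon)
  stdp_rule(f_plus = f_plus, f_minus = f_minus, tau_plus = tau_plus,
            tau_minus = tau_minus, wmax = wmax)
}

#' Unbalanced STDP rule presets
#'
#' Depression-dominated (`"depression"`): the total amount of depression
#' (f_minus * tau_minus) is twice the total potentiation, so S = -f_plus *
#' tau_plus. Potentiation-dominated (`"potentiation"`): total potentiation is
#' twice total depression, S = +f_plus * tau_plus / 2 ... expressed with the
#' same potentiation window, i.e. f_minus tau_minus = f_plus tau_plus / 2.
#'
#' @param which `"depression"` or `"potentiation"`
#' @param f_plus,tau_plus,tau_minus,wmax as in [stdp_rule()]
#' @return an `stdp_rule`
#' @export
stdp_rule_unbalanced <- function(which = c("depression", "potentiation"),
                                 f_plus = 2.5e-3, tau_plus = 20,
                                 tau_minus = 40, wmax = 5) {
  which <- match.arg(which)
  area_ratio <- if (which == "depression") 2 else 0.5
  f_minus <- area_ratio * f_plus * tau_plus / tau_minus
  stdp_rule(f_plus = f_plus, f_minus = f_minus, tau_plus = tau_plus,
            tau_minus = tau_minus, wmax = wmax)
}

#' Evaluate the STDP window L(s) (bounds ignored)
#'
#' @param rule an [stdp_rule()]
#' @param s vector of spike-time lags, s = t_post - t_pre (ms)
#' @return vector of weight changes
#' @export
stdp_window <- function(rule, s) {
  ifelse(s >= 0, rule$f_plus * exp(-abs(s) / rule$tau_plus),
         -rule$f_minus * exp(-abs(s) / rule$tau_minus))
}

#' Fourier transform of the STDP window
#'
#' Under the convention \eqn{\hat L(\omega) = \int L(s) e^{-2\pi i \omega s} ds}
#' (frequency in cycles/ms):
#' \deqn{\hat L(\omega) = f_+\tau_+ / (1 + 2\pi i \omega \tau_+)
#'   - f_-\tau_- / (1 - 2\pi i \omega \tau_-).}
#'
#' @param rule an [stdp_rule()]
#' @param omega frequencies (cycles/ms)
#' @return complex vector
#' @export
stdp_window_ft <- function(rule, omega) {
  two_pi_i <- 2i * pi
  rule$f_plus * rule$tau_plus / (1 + two_pi_i * omega * rule$tau_plus) -
    rule$f_minus * rule$tau_minus / (1 - two_pi_i * omega * rule$tau_minus)
}

#' Simulation configuration
#'
#' @param dt integration step (ms); should resolve the synaptic and STDP time
#'   constants (dt <= min(tauS, tau_plus, tau_minus)/10)
#' @param T total simulated time (ms)
#' @param seed integer seed for the simulator's RNG streams
#' @param plasticity_on logical; apply online STDP
#' @param record_weights_every cadence of weight snapshots (ms; 0 = none)
#' @param record_spikes logical
#' @param rate_cap abort threshold for the network-mean firing rate (Hz);
#'   exceeding it raises a rate-instability error
#' @return an object of class `sim_config`
#' @export
sim_config <- function(dt = 0.05, T = 1000, seed = 1, plasticity_on = FALSE,
                       record_weights_every = 0, record_spikes = TRUE,
                       rate_cap = 200) {
  stopifnot(dt > 0, T >= dt, rate_cap > 0)
  cfg <- list(dt = dt, T = T, seed = as.integer(seed),
              plasticity_on = isTRUE(plasticity_on),
              record_weights_every = record_weights_every,
              record_spikes = isTRUE(record_spikes), rate_cap = rate_cap)
  class(cfg) <- "sim_config"
  cfg
}

#' Synaptic filter transform
#'
#' Exponential synapse J(t) = H(t) exp(-t/tauS), transformed as
#' \eqn{\hat J(\omega) = \tau_S / (1 + 2\pi i \omega \tau_S)}.
#'
#' @param omega frequencies (cycles/ms)
#' @param tauS synaptic decay (ms)
#' @return complex vector
#' @export
synaptic_filter_ft <- function(omega, tauS = 5) {
  tauS / (1 + 2i * pi * omega * tauS)
}
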