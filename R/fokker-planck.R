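## Fokker-Planck (threshold integration) numerics for the white-noise-driven
## EIF neuron: stationary rate, linear response A(omega), first-passage-time
## density transform and renewal power spectrum C0(omega).
##
## The membrane drift is f(V) = (gL (VL - V) + gL Delta exp((V-VT)/Delta)
## + mu)/C and the voltage diffusion coefficient is Dv = sigma^2 gL / C, so
## that the passive membrane voltage has stationary standard deviation sigma.
## All solvers integrate the flux/density pair downward from the absorbing
## boundary at Vth with reinjection at Vre, using an exponential (integrating
## factor) stepping scheme that is robust where the exponential spike current
## makes the drift huge.
##
## Fourier convention throughout: y(omega) = int y(t) exp(-2 pi i omega t) dt,
## frequency in cycles/ms.

#' Symmetric frequency grid
#'
#' A uniform grid of frequencies (cycles/ms) symmetric about and containing
#' zero, used for linear response functions, spectra and rule-covariance
#' quadratures.
#'
#' @param omega_max largest frequency (cycles/ms); 1 cycle/ms = 1 kHz
#' @param domega grid spacing (cycles/ms)
#' @return an object of class `frequency_grid`: list with `omega` (full
#'   symmetric vector), `omega_pos` (the nonnegative half), `domega`
#' @export
frequency_grid <- function(omega_max = 1, domega = 1 / 2048) {
  n <- round(omega_max / domega)
  stopifnot(n >= 8)
  om_pos <- (0:n) * domega
  g <- list(omega = c(-rev(om_pos[-1]), om_pos), omega_pos = om_pos,
            domega = domega, omega_max = n * domega)
  class(g) <- "frequency_grid"
  g
}

## Voltage grid: uniform, containing Vre and Vth exactly; lower bound far
## enough below the passive equilibrium that the stationary density there is
## negligible.
fp_vgrid <- function(eif, mu, sigma, nV) {
  v_eq <- eif$VL + max(mu, 0) / eif$gL
  Vlb <- min(eif$VL, eif$Vre, v_eq) - 6 * sigma
  ## build grid downward from Vth so that Vth is exactly a grid point, then
  ## snap Vre to its nearest point
  h <- (eif$Vth - Vlb) / (nV - 1)
  V <- seq(Vlb, eif$Vth, length.out = nV)
  k_re <- which.min(abs(V - eif$Vre))
  list(V = V, h = h, k_re = k_re)
}

## Stationary solve, vectorized over mu. Returns rates and (optionally) the
## stationary density on the voltage grid.
fp_stationary <- function(mu, sigma, eif, nV = 4000, return_density = FALSE) {
  stopifnot(sigma > 0)
  g <- fp_vgrid(eif, max(mu), sigma, nV)
  V <- g$V; h <- g$h; k_re <- g$k_re
  nmu <- length(mu)
  Dv <- sigma^2 * eif$gL / eif$C
  psi <- eif$gL * (eif$VL - V) +
    eif$gL * eif$Delta * exp(pmin((V - eif$VT) / eif$Delta, 30))
  psi_mid <- 0.5 * (psi[-1] + psi[-length(psi)])  # between k-1 and k
  p <- matrix(0, nmu, nV)
  pk <- numeric(nmu)
  for (k in nV:2) {
    a <- (psi_mid[k - 1] + mu) / (eif$C * Dv)
    ah <- a * h
    eah <- exp(-ah)
    phi <- ifelse(abs(ah) < 1e-12, 1, -expm1(-ah) / ah)
    jflux <- if ((k - 1) >= k_re) 1 else 0
    pk <- pk * eah + (h * phi / Dv) * jflux
    p[, k - 1] <- pk
  }
  ## trapezoid over the voltage grid gives the mean first-passage time for
  ## unit reinjected flux; the refractory period adds as a dead time
  Tfp <- h * (rowSums(p) - 0.5 * (p[, 1] + p[, nV]))
  rate <- 1 / (Tfp + eif$tau_ref)
  out <- list(rate = rate, V = V, h = h, k_re = k_re)
  if (return_density) out$P0 <- p * rate  # integrates to 1 - rate*tau_ref
  out
}

#' Stationary firing rate of the EIF neuron
#'
#' Solves the stationary Fokker-Planck equation by threshold integration on a
#' voltage grid (absorbing boundary at `Vth`, reinjection at `Vre`) and folds
#' in the absolute refractory period as a dead time,
#' r = 1 / (T_fp + tau_ref).
#'
#' @param mu mean input current (uA/cm^2); may be a vector
#' @param sigma noise strength (mV), > 0
#' @param eif an [eif_params()]
#' @param nV number of voltage grid points
#' @return stationary rate(s) in spikes/ms
#' @export
stationary_rate <- function(mu, sigma, eif = eif_params(), nV = 4000) {
  r <- fp_stationary(mu, sigma, eif, nV)$rate
  if (any(!is.finite(r)) || any(r < 0))
    stop("stationary Fokker-Planck solve failed (non-finite rate); ",
         "check the voltage grid and parameters")
  r
}

## One-operating-point frequency-domain sweep. Integrates four flux/density
## pairs downward from Vth, vectorized over the strictly positive frequencies:
##   (h) homogeneous with unit threshold flux and delayed reinjection
##   (e) driven by a unit current modulation acting on the stationary density
##   (1) first-passage solution launched at Vth
##   (2) first-passage solution launched at Vre
## A(omega) = -j_e/j_h at the lower boundary; the first-passage-time density
## transform is f0(omega) = j_2/j_1 there.
fp_freq_solve <- function(mu, sigma, eif, omega_pos, nV = 4000) {
  st <- fp_stationary(mu, sigma, eif, nV, return_density = TRUE)
  V <- st$V; h <- st$h; k_re <- st$k_re
  om <- omega_pos[omega_pos > 0]
  iOm <- 2i * pi * om
  nw <- length(om)
  Dv <- sigma^2 * eif$gL / eif$C
  psi <- eif$gL * (eif$VL - V) +
    eif$gL * eif$Delta * exp(pmin((V - eif$VT) / eif$Delta, 30))
  psi_mid <- 0.5 * (psi[-1] + psi[-length(psi)])
  P0 <- st$P0[1, ]
  src <- exp(-iOm * eif$tau_ref)     # reinjected flux, delayed by tau_ref

  zero <- complex(real = rep(0, nw))
  j_h <- 1 + zero; p_h <- zero
  j_e <- zero;     p_e <- zero
  j_1 <- 1 + zero; p_1 <- zero
  j_2 <- zero;     p_2 <- zero      # activated at k_re

  nVl <- length(V)
  for (k in nVl:2) {
    a  <- (psi_mid[k - 1] + mu) / (eif$C * Dv)
    ah <- a * h
    eah <- exp(-ah)
    phi <- if (abs(ah) < 1e-12) 1 else -expm1(-ah) / ah
    cstep <- h * phi / Dv
    drive <- 0.5 * (P0[k] + P0[k - 1]) / eif$C

    if (k == k_re) {                # crossing the reinjection point
      j_h <- j_h - src
      j_2 <- j_2 + 1
    }

    jn <- j_h + iOm * h * p_h
    p_h <- p_h * eah + cstep * (0.5 * (j_h + jn))
    j_h <- jn

    jn <- j_e + iOm * h * p_e
    p_e <- p_e * eah + cstep * (0.5 * (j_e + jn) - drive)
    j_e <- jn

    jn <- j_1 + iOm * h * p_1
    p_1 <- p_1 * eah + cstep * (0.5 * (j_1 + jn))
    j_1 <- jn

    jn <- j_2 + iOm * h * p_2
    p_2 <- p_2 * eah + cstep * (0.5 * (j_2 + jn))
    j_2 <- jn
  }

  A_pos <- -j_e / j_h
  f0 <- j_2 / j_1
  fI <- exp(-iOm * eif$tau_ref) * f0   # ISI density transform incl. dead time
  r <- st$rate[1]
  C0_pos <- r * (1 - Mod(fI)^2) / Mod(1 - fI)^2

  ## even/odd quadratic extrapolation to omega = 0 where the solve degenerates
  extrap0 <- function(y) (4 * y[1] - y[2]) / 3
  A0 <- complex(real = extrap0(Re(A_pos)))
  C00 <- extrap0(C0_pos)

  list(rate = r, omega_pos = c(0, om), A_pos = c(A0, A_pos),
       C0_pos = c(C00, C0_pos))
}

#' Single-neuron spectral statistics at one operating point
#'
#' Computes, for a white-noise-driven EIF neuron at operating point
#' (`mu`, `sigma`): the stationary rate r; the linear response function
#' A(omega) (rate modulation per unit current modulation), by threshold
#' integration of the modulated Fokker-Planck equation; and the baseline
#' spike-train power spectrum C0(omega), from the first-passage-time density
#' transform via the renewal relation
#' \deqn{C^0(\omega) = r (1 - |\tilde f|^2)/|1 - \tilde f|^2,}
#' with the refractory period folded in as a pure delay factor.
#'
#' A and C0 are returned on the full symmetric grid, with A(-omega) =
#' conj(A(omega)) and C0 even.
#'
#' @param mu mean input current (uA/cm^2)
#' @param sigma noise strength (mV)
#' @param eif an [eif_params()]
#' @param grid a [frequency_grid()]
#' @param nV voltage grid points
#' @return object of class `neuron_stats`: list with `rate`, `A`, `C0`,
#'   `grid`, `mu`, `sigma`
#' @export
single_neuron_stats <- function(mu, sigma, eif = eif_params(),
                                grid = frequency_grid(), nV = 4000) {
  sol <- fp_freq_solve(mu, sigma, eif, grid$omega_pos, nV)
  A_full <- c(Conj(rev(sol$A_pos[-1])), sol$A_pos)
  C0_full <- c(rev(sol$C0_pos[-1]), sol$C0_pos)
  out <- list(rate = sol$rate, A = A_full, C0 = C0_full, grid = grid,
              mu = mu, sigma = sigma)
  class(out) <- "neuron_stats"
  out
}

#' Linear response function A(omega)
#'
#' Convenience wrapper around [single_neuron_stats()] returning only the
#' complex linear response on the full symmetric grid.
#'
#' @inheritParams single_neuron_stats
#' @return complex vector on `grid$omega`
#' @export
linear_response <- function(mu, sigma, eif = eif_params(),
                            grid = frequency_grid(), nV = 4000) {
  single_neuron_stats(mu, sigma, eif, grid, nV)$A
}

#' Baseline spike-train power spectrum C0(omega)
#'
#' @inheritParams single_neuron_stats
#' @return real nonnegative vector on `grid$omega`
#' @export
power_spectrum <- function(mu, sigma, eif = eif_params(),
                           grid = frequency_grid(), nV = 4000) {
  single_neuron_stats(mu, sigma, eif, grid, nV)$C0
}

#' Self-consistent network firing rates
#'
#' Solves the fixed point r_i = r(mu_eff_i, sigma) with effective mean input
#' \deqn{\mu^{eff}_i = \mu + \tau_S \sum_j W_ij r_j}
#' (the integral of the exponential synaptic kernel is tauS), by damped
#' fixed-point iteration on the Fokker-Planck stationary rate.
#'
#' @param net a [weighted_network()]
#' @param noise a [noise_params()]
#' @param eif an [eif_params()]
#' @param tauS synaptic time constant (ms)
#' @param tol convergence tolerance on the max rate change (spikes/ms)
#' @param max_iter iteration cap; exceeding it raises a rate-instability error
#' @param nV voltage grid points
#' @return list with `rates` (spikes/ms) and `mu_eff` (uA/cm^2)
#' @export
self_consistent_rates <- function(net, noise, eif = eif_params(), tauS = 5,
                                  tol = 1e-6, max_iter = 500, nV = 4000) {
  W <- net$W
  r <- rep(stationary_rate(noise$mu, noise$sigma, eif, nV), nrow(W))
  damp <- 0.7
  for (it in seq_len(max_iter)) {
    mu_eff <- noise$mu + tauS * as.vector(W %*% r)
    r_new <- fp_stationary(mu_eff, noise$sigma, eif, nV)$rate
    dmax <- max(abs(r_new - r))
    r <- damp * r_new + (1 - damp) * r
    if (!all(is.finite(r)) || mean(r) > 0.2)
      stop("rate instability: self-consistent rates diverged ",
           "(recurrent excitation too strong for a stable fixed point)")
    if (dmax < tol) {
      return(list(rates = r, mu_eff = noise$mu + tauS * as.vector(W %*% r)))
    }
  }
  stop("rate instability: self-consistent rate iteration did not converge in ",
       max_iter, " iterations")
}

#' Spectral statistics for every neuron in a network
#'
#' Solves the self-consistent rates and computes each neuron's linear
#' response and baseline power spectrum at its own effective operating
#' point. Fokker-Planck solves are shared between neurons whose effective
#' mean inputs agree after quantization to `dmu` (the rate changes by well
#' under 1e-4 spikes/ms across a default bin).
#'
#' @inheritParams self_consistent_rates
#' @param grid a [frequency_grid()]
#' @param dmu operating-point quantization (uA/cm^2)
#' @return list with `rates`, `mu_eff`, matrices `A` (complex) and `C0`
#'   (one row per neuron, columns on `grid$omega`), `grid`, `sigma`
#' @export
network_neuron_stats <- function(net, noise, eif = eif_params(), tauS = 5,
                                 grid = frequency_grid(), dmu = 0.002,
                                 nV = 4000) {
  sc <- self_consistent_rates(net, noise, eif, tauS, nV = nV)
  mu_q <- round(sc$mu_eff / dmu) * dmu
  uq <- sort(unique(mu_q))
  M <- length(grid$omega)
  A <- matrix(0i, length(mu_q), M)
  C0 <- matrix(0, length(mu_q), M)
  rate <- numeric(length(mu_q))
  for (m in uq) {
    idx <- which(mu_q == m)
    s <- single_neuron_stats(m, noise$sigma, eif, grid, nV)
    A[idx, ] <- matrix(s$A, length(idx), M, byrow = TRUE)
    C0[idx, ] <- matrix(s$C0, length(idx), M, byrow = TRUE)
    rate[idx] <- s$rate
  }
  list(rates = rate, mu_eff = sc$mu_eff, A = A, C0 = C0, grid = grid,
       sigma = noise$sigma)
}
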