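## Reduced (closed) dynamics of two-synapse motif strengths under STDP.
##
## The high-dimensional weight evolution is collapsed onto 11 network-averaged
## coordinates: the mean weight p; motif strengths q_div, q_con, q_ch (with
## q_ch split into disynaptic loops q_rec and open chains q_op); the mixed
## weight/adjacency motifs qX_rec, qX_div, qX_con, qX_chA, qX_chB; and the
## loop-conditioned second moment qX2_rec. The coefficients are four scalars
## collapsing the STDP rule against the single-neuron spiking statistics at a
## frozen operating point: S (rule area, chance coincidences), S_F (forward
## connections), S_B (backward connections) and S_C (common input).

#' Frozen operating point of the motif theory
#'
#' Solves the scalar self-consistency mu_eff = mu + tauS * w * r(mu_eff)
#' for a network whose synapses all sit at rescaled weight `w` (default
#' p0*Wmax/2 corresponds to w = Wmax/2), and returns the single-neuron
#' spectral statistics there.
#'
#' @param noise a [noise_params()]
#' @param eif an [eif_params()]
#' @param w rescaled per-synapse weight (total input per neuron is
#'   tauS * w * r regardless of N and p0)
#' @param tauS synaptic time constant (ms)
#' @param grid a [frequency_grid()]
#' @param nV voltage grid points
#' @return a `neuron_stats` (see [single_neuron_stats()])
#' @export
frozen_operating_point <- function(noise, eif = eif_params(), w = 2.5,
                                   tauS = 5, grid = frequency_grid(),
                                   nV = 4000) {
  mu_eff <- noise$mu
  for (k in 1:200) {
    r <- stationary_rate(mu_eff, noise$sigma, eif, nV)
    mu_new <- noise$mu + tauS * w * r
    if (abs(mu_new - mu_eff) < 1e-10) break
    mu_eff <- 0.5 * (mu_eff + mu_new)
  }
  single_neuron_stats(mu_eff, noise$sigma, eif, grid, nV)
}

#' STDP-weighted covariance integrals
#'
#' The four scalars that collapse the learning rule against the spiking
#' statistics:
#' \deqn{S = \int L ds, \quad S_F = \int L (K * C^0) ds, \quad
#'       S_B = \int L (C^0 * K^-) ds, \quad S_C = \int L (K * C^0 * K^-) ds,}
#' with K(t) = (A * J)(t) the interaction kernel per unit weight and C0 the
#' baseline spike-train autocovariance, both at the frozen operating point.
#' S is analytic (f+ tau+ - f- tau-); the others are frequency-domain
#' quadratures. For Hebbian rules with f+ > f-, tau+ < tau-: S_F > 0,
#' S_B < 0, S_C > 0.
#'
#' @param rule an [stdp_rule()]
#' @param stats a `neuron_stats` at the frozen operating point (see
#'   [frozen_operating_point()])
#' @param tauS synaptic time constant (ms)
#' @return object of class `stdp_integrals`: list with `S`, `S_F`, `S_B`,
#'   `S_C`, `r`, `rule`, `stats`
#' @export
stdp_integrals <- function(rule, stats, tauS = 5) {
  om <- stats$grid$omega
  dom <- stats$grid$domega
  Lh <- stdp_window_ft(rule, om)
  Kh <- stats$A * synaptic_filter_ft(om, tauS)
  C0 <- stats$C0
  S_F <- sum(Re(Lh * Conj(Kh * C0))) * dom
  S_B <- sum(Re(Lh * Kh * C0)) * dom
  S_C <- sum(Re(Lh) * Mod(Kh)^2 * C0) * dom
  out <- list(S = stdp_area(rule), S_F = S_F, S_B = S_B, S_C = S_C,
              r = stats$rate, rule = rule, stats = stats)
  class(out) <- "stdp_integrals"
  out
}

#' @export
print.stdp_integrals <- function(x, ...) {
  cat(sprintf("stdp_integrals: S = %.4g, S_F = %.4g, S_B = %.4g, S_C = %.4g\n",
              x$S, x$S_F, x$S_B, x$S_C))
  cat(sprintf("  operating point: r = %.3f Hz (mu_eff = %.4f)\n",
              1000 * x$r, x$stats$mu))
  invisible(x)
}

#' Motif ODE configuration
#'
#' Frozen motif frequencies of the adjacency matrix plus the epsilon scaling.
#'
#' @param p0 connection density
#' @param q0_div,q0_con,q0_ch,q0_rec motif frequencies (see
#'   [motif_frequencies()])
#' @param epsilon 1/(N p0)
#' @param wmax weight bound on the rescaled scale
#' @return object of class `motif_ode_config`
#' @export
motif_ode_config <- function(p0, q0_div = 0, q0_con = 0, q0_ch = 0,
                             q0_rec = 0, epsilon = 1 / (1000 * p0), wmax = 5) {
  stopifnot(p0 > 0, epsilon > 0)
  cfg <- list(p0 = p0, q0_div = q0_div, q0_con = q0_con, q0_ch = q0_ch,
              q0_rec = q0_rec, epsilon = epsilon, wmax = wmax)
  class(cfg) <- "motif_ode_config"
  cfg
}

#' @rdname motif_ode_config
#' @param W0 adjacency matrix
#' @param ... passed on to `motif_ode_config`
#' @export
motif_ode_config_from_network <- function(W0, ...) {
  f <- motif_frequencies(W0)
  motif_ode_config(p0 = f$p0, q0_div = f$q0_div, q0_con = f$q0_con,
                   q0_ch = f$q0_ch, q0_rec = f$q0_rec,
                   epsilon = 1 / (nrow(W0) * f$p0), ...)
}

motif_state_names <- c("p", "q_div", "q_con", "q_ch", "q_rec", "q_op",
                       "qX_rec", "qX_div", "qX_con", "qX_chA", "qX_chB",
                       "qX2_rec")

## coerce a motif_state (or named vector) to the canonical numeric vector
as_motif_vector <- function(state) {
  v <- unlist(unclass(state))[motif_state_names]
  if (any(is.na(v))) stop("motif state is missing coordinates")
  v
}

#' Right-hand side of the reduced motif dynamics
#'
#' Evaluates the time derivative of all motif coordinates (per ms of
#' biological time). Chance coincidences (r^2 S terms) couple each motif to
#' its mixed counterpart and each mixed motif to the frozen adjacency
#' structure; spiking covariance from forward connections (S_F) reinforces
#' the current structure, and backward (S_B) / common-input (S_C) covariance
#' couples divergent, convergent and chain motifs to each other. The
#' open-chain derivative is obtained as d q_ch/dt - d q_rec/dt, so the
#' identity q_ch = q_rec + q_op is preserved exactly.
#'
#' @param state a `motif_state` or named vector (see [motif_strengths()])
#' @param cfg a [motif_ode_config()]
#' @param ints an [stdp_integrals()]
#' @return named vector of derivatives (per ms)
#' @export
motif_rhs <- function(state, cfg, ints) {
  v <- as_motif_vector(state)
  p <- v["p"]; qdiv <- v["q_div"]; qcon <- v["q_con"]; qch <- v["q_ch"]
  qrec <- v["q_rec"]; qXrec <- v["qX_rec"]; qXdiv <- v["qX_div"]
  qXcon <- v["qX_con"]; qXchA <- v["qX_chA"]; qXchB <- v["qX_chB"]
  qX2rec <- v["qX2_rec"]
  p0 <- cfg$p0; eps <- cfg$epsilon
  r2S <- ints$r^2 * ints$S
  SF <- ints$S_F; SB <- ints$S_B; SC <- ints$S_C
  pp0 <- p * p0
  dp2 <- qdiv + p^2

  dp <- p0 * r2S + eps * (p * SF + (qXrec + pp0) * SB +
    (p0 * dp2 + p * (qXcon + qXchB)) * SC / p0)

  dqdiv <- 2 * r2S * qXdiv + 2 * eps * (qdiv * SF +
    (p0 * qch + p * qXdiv) * SB +
    (qch * (qXcon + pp0) + qXdiv * dp2) * SC / p0)

  dqcon <- 2 * r2S * qXcon + 2 * eps * (qcon * SF +
    (p0 * qch + p * qXcon) * SB +
    (qcon * (qXchB + pp0) + qXcon * dp2) * SC / p0)

  dqch <- r2S * (qXchA + qXchB) + eps * (2 * qch * SF +
    (p0 * (qcon + qdiv) + p * (qXchA + qXchB)) * SB +
    (dp2 * (qXchA + qXchB) + qch * (qXchB + pp0) +
       qcon * (qXcon + pp0)) * SC / p0)

  dqXrec <- r2S * cfg$q0_rec + eps * (qXrec * SF +
    (1 - p0) * (qXrec + pp0) * SB +
    (cfg$q0_rec * dp2 + qXchB * (qXchB + pp0) +
       qXcon * (qXcon + pp0)) * SC / p0)

  dqXdiv <- r2S * cfg$q0_div + eps * (qXdiv * SF +
    (p * cfg$q0_div + p0 * qXchB) * SB +
    (cfg$q0_div * dp2 + qXchB * (qXcon + pp0)) * SC / p0)

  dqXcon <- r2S * cfg$q0_con + eps * (qXcon * SF +
    (p * cfg$q0_con + p0 * qXchA) * SB +
    (cfg$q0_con * dp2 + qXcon * (qXchB + pp0)) * SC / p0)

  dqXchA <- r2S * cfg$q0_ch + eps * (qXchA * SF +
    (p * cfg$q0_ch + p0 * qXcon) * SB +
    (cfg$q0_ch * dp2 + qXcon * (qXcon + pp0)) * SC / p0)

  dqXchB <- r2S * cfg$q0_ch + eps * (qXchB * SF +
    (p * cfg$q0_ch + p0 * qXdiv) * SB +
    (cfg$q0_ch * dp2 + qXchB * (qXchB + pp0)) * SC / p0)

  dqrec <- 2 * eps * (r2S * p0 * (qXrec + pp0) + SF * qrec + SB * qX2rec)
  dqX2rec <- 2 * eps * (r2S * p0 * (qXrec + pp0) + SF * qX2rec + SB * qrec)
  dqop <- dqch - dqrec

  out <- c(dp, dqdiv, dqcon, dqch, dqrec, dqop, dqXrec, dqXdiv, dqXcon,
           dqXchA, dqXchB, dqX2rec)
  names(out) <- motif_state_names
  out
}

#' Integrate the reduced motif dynamics
#'
#' Adaptive integration (deSolve, `lsoda`) of [motif_rhs()]. The reduced
#' system carries no weight bounds; a warning flags the first time the mean
#' weight leaves \[0, p0 * wmax\].
#'
#' @param state0 initial `motif_state` (typically [motif_strengths()] of the
#'   initial network)
#' @param cfg a [motif_ode_config()]
#' @param ints an [stdp_integrals()]
#' @param T_total horizon (s of biological time)
#' @param n_out number of output samples
#' @param rtol,atol integrator tolerances
#' @return data.frame: `time_s` plus the 12 motif coordinates
#' @export
integrate_motifs <- function(state0, cfg, ints, T_total = 7200, n_out = 201,
                             rtol = 1e-8, atol = 1e-12) {
  y0 <- as_motif_vector(state0)
  times <- seq(0, T_total * 1000, length.out = n_out)  # ms
  f <- function(t, y, parms) list(motif_rhs(y, cfg, ints))
  sol <- deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("motif ODE integration failed; last good time ",
         max(sol[, "time"]) / 1000, " s")
  df <- as.data.frame(sol)
  names(df)[1] <- "time_s"
  df$time_s <- df$time_s / 1000
  if (any(df$p < -1e-9 | df$p > cfg$p0 * cfg$wmax + 1e-9))
    warning("mean weight left [0, p0*wmax]: the bound-free reduced theory ",
            "is extrapolating beyond the transient")
  df
}

#' Closed-form motif trajectories for unbalanced STDP
#'
#' When the rule is strongly unbalanced (|S| of order 1, dominating the
#' O(epsilon) covariance terms), the motif dynamics close at the rate terms
#' and integrate exactly:
#' \deqn{p(t) = p_0 r^2 S t + p(0), \qquad
#'   q_X^a(t) = r^2 S q_0^a t + q_X^a(0),}
#' \deqn{q^a(t) = q^a(0) + 2 q_X^a(0) r^2 S t + q_0^a (r^2 S)^2 t^2}
#' for a = div, con; chains use the sum of the two mixed chain coordinates,
#' \eqn{q^{ch}(t) = q^{ch}(0) + (q_X^{chA}(0)+q_X^{chB}(0)) r^2 S t +
#' q_0^{ch} (r^2 S)^2 t^2}. The quadratic coefficients are those implied by
#' integrating the rate-only motif ODEs (the printed closed forms elsewhere
#' halve them, which is inconsistent with the ODE system itself).
#'
#' @param t_s times (s)
#' @param state0 initial `motif_state`
#' @param cfg a [motif_ode_config()]
#' @param ints an [stdp_integrals()]
#' @return data.frame: `time_s`, `p`, `q_div`, `q_con`, `q_ch`, `qX_div`,
#'   `qX_con`, `qX_chA`, `qX_chB`
#' @export
unbalanced_solution <- function(t_s, state0, cfg, ints) {
  v <- as_motif_vector(state0)
  t <- t_s * 1000
  a <- ints$r^2 * ints$S
  data.frame(
    time_s = t_s,
    p = cfg$p0 * a * t + v["p"],
    q_div = v["q_div"] + 2 * v["qX_div"] * a * t + cfg$q0_div * a^2 * t^2,
    q_con = v["q_con"] + 2 * v["qX_con"] * a * t + cfg$q0_con * a^2 * t^2,
    q_ch = v["q_ch"] + (v["qX_chA"] + v["qX_chB"]) * a * t +
      cfg$q0_ch * a^2 * t^2,
    qX_div = a * cfg$q0_div * t + v["qX_div"],
    qX_con = a * cfg$q0_con * t + v["qX_con"],
    qX_chA = a * cfg$q0_ch * t + v["qX_chA"],
    qX_chB = a * cfg$q0_ch * t + v["qX_chB"],
    row.names = NULL)
}

#' Fixed points of the mean synaptic weight on the unstructured set
#'
#' On the invariant set of unstructured networks the mean weight obeys
#' \deqn{\epsilon^{-1} dp/dt = p_0 r^2 S/\epsilon + p (S_F + p_0 S_B)
#'   + p^2 S_C,}
#' a quadratic with up to two fixed points. For balanced depression-dominated
#' rules one root is positive and one negative; the positive root is
#' unstable and acts as the separatrix between potentiation and depression
#' of the mean weight when it lies inside \[0, p0*wmax\].
#'
#' @param cfg a [motif_ode_config()]
#' @param ints an [stdp_integrals()]
#' @return list with `roots` (possibly empty), `stability` ("stable" /
#'   "unstable"), `separatrix` (NA if no admissible unstable root)
#' @export
mean_weight_fixed_points <- function(cfg, ints) {
  if (ints$S_C == 0) stop("S_C must be nonzero for the quadratic analysis")
  a <- ints$S_C
  b <- ints$S_F + cfg$p0 * ints$S_B
  cc <- cfg$p0 * ints$r^2 * ints$S / cfg$epsilon
  disc <- b^2 - 4 * a * cc
  if (disc < 0)
    return(list(roots = numeric(0), stability = character(0),
                separatrix = NA_real_, discriminant = disc))
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  stability <- ifelse(2 * a * roots + b < 0, "stable", "unstable")
  sep <- roots[stability == "unstable" & roots >= 0 &
                 roots <= cfg$p0 * cfg$wmax]
  list(roots = roots, stability = stability,
       separatrix = if (length(sep)) sep[1] else NA_real_,
       discriminant = disc)
}

#' Scan the sign of a motif derivative on a plane
#'
#' Utility for nullcline / phase-plane reconstruction: evaluates the reduced
#' right-hand side on a grid in a chosen coordinate plane (all other
#' coordinates frozen) and returns the derivative values of the two scanned
#' coordinates.
#'
#' @param state base `motif_state`
#' @param cfg,ints as in [motif_rhs()]
#' @param vars character(2): names of the scanned coordinates
#' @param xlim,ylim ranges
#' @param n grid points per axis
#' @return data.frame: the two scanned values plus their derivatives
#' @export
motif_plane_scan <- function(state, cfg, ints, vars = c("q_div", "q_con"),
                             xlim, ylim, n = 21) {
  stopifnot(length(vars) == 2, all(vars %in% motif_state_names))
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  grid <- expand.grid(x = xs, y = ys)
  base <- as_motif_vector(state)
  res <- t(apply(grid, 1, function(g) {
    v <- base
    v[vars[1]] <- g[1]; v[vars[2]] <- g[2]
    if (vars[1] == "q_ch" || vars[2] == "q_ch")
      v["q_op"] <- v["q_ch"] - v["q_rec"]
    if (vars[1] %in% c("q_rec", "q_op") || vars[2] %in% c("q_rec", "q_op"))
      v["q_ch"] <- v["q_rec"] + v["q_op"]
    d <- motif_rhs(v, cfg, ints)
    c(d[vars[1]], d[vars[2]])
  }))
  out <- data.frame(grid$x, grid$y, res[, 1], res[, 2])
  names(out) <- c(vars, paste0("d_", vars))
  out
}
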