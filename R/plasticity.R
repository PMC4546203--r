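## Self-consistent slow evolution of the full weight matrix: every synapse
## drifts according to the STDP rule integrated against the rates and the
## linear-response spiking covariances, which are recomputed (re-linearized)
## as the weights evolve.

#' Theoretical drift of every synaptic weight
#'
#' Computes \eqn{dW_{ij}/dt = W^0_{ij} \epsilon [ r_i r_j S + \int L(s)
#' C_{ij}(s) ds ]} (actual weight units per ms of biological time), with the
#' potentiation and depression branches gated separately by the hard bounds:
#' the potentiation contribution is zeroed where W has reached the upper
#' bound, the depression contribution where W has reached 0, mirroring the
#' per-branch Heaviside factors of the pair rule.
#'
#' @param net a [weighted_network()]
#' @param stats output of [network_neuron_stats()]
#' @param rule an [stdp_rule()] (amplitudes on the rescaled scale; the
#'   epsilon scaling of the applied rule is handled internally)
#' @param flavor covariance flavor, `"full"` or `"truncated"`
#' @param tauS synaptic time constant (ms)
#' @return matrix of weight drifts (actual scale, per ms)
#' @export
weight_drift <- function(net, stats, rule, flavor = c("full", "truncated"),
                         tauS = 5) {
  flavor <- match.arg(flavor)
  cov <- if (flavor == "full") full_covariance(net, stats, tauS = tauS)
         else truncated_covariance(net, stats, tauS = tauS)
  rule_p <- rule; rule_p$f_minus <- 0
  rule_m <- rule; rule_m$f_plus <- 0
  Gp <- rule_weighted_integral(cov, rule_p)
  Gm <- rule_weighted_integral(cov, rule_m)
  rr <- stats$rates %o% stats$rates
  drift_p <- rr * stdp_area(rule_p) + Gp
  drift_m <- rr * stdp_area(rule_m) + Gm
  wmax_act <- rule$wmax * net$epsilon
  gate_p <- net$W < wmax_act
  gate_m <- net$W > 0
  net$W0 * net$epsilon * (gate_p * drift_p + gate_m * drift_m)
}

#' Evolve the network weights under the self-consistent theory
#'
#' Euler-steps every synaptic weight by [weight_drift()] with a plasticity
#' time step of `step` seconds (default 100 s), re-linearizing the network at
#' every step: rates, linear response functions and baseline spectra are
#' recomputed from the updated effective inputs. Weights are clipped to
#' `[0, epsilon * wmax]` after each full Euler increment.
#'
#' @param net a [weighted_network()]
#' @param rule an [stdp_rule()]
#' @param noise a [noise_params()]
#' @param eif an [eif_params()]
#' @param T_total total plasticity time (s)
#' @param step Euler step (s)
#' @param flavor covariance flavor for the drift
#' @param grid frequency grid for the per-step statistics
#' @param tauS synaptic time constant (ms)
#' @param dmu operating-point quantization (uA/cm^2)
#' @return object of class `theory_trajectory`: list with `times` (s),
#'   `p` (mean weight, rescaled scale), `mean_rate` (spikes/ms), `motifs`
#'   (data.frame of motif-state snapshots), `weights` (list of sparse
#'   triplet data.frames, actual scale), `net_final`, `error` (NULL or a
#'   message if the trajectory was truncated by a rate instability)
#' @export
evolve_network <- function(net, rule, noise = noise_params(),
                           eif = eif_params(), T_total = 3600, step = 100,
                           flavor = "full",
                           grid = frequency_grid(0.5, 1 / 512), tauS = 5,
                           dmu = 0.002) {
  times <- seq(0, T_total, by = step)
  edges <- which(net$W0 == 1)
  snap <- function(net) {
    ij <- arrayInd(edges, dim(net$W))
    data.frame(post = ij[, 1], pre = ij[, 2], w = net$W[edges])
  }
  motifs <- list(); weights <- list(); pvec <- numeric(0); rvec <- numeric(0)
  err <- NULL
  for (k in seq_along(times)) {
    stats <- tryCatch(
      network_neuron_stats(net, noise, eif, tauS, grid, dmu),
      error = function(e) e)
    if (inherits(stats, "error")) {
      err <- conditionMessage(stats)
      times <- times[seq_len(k - 1)]
      break
    }
    motifs[[k]] <- as.data.frame(unclass(motif_strengths(net)))
    weights[[k]] <- snap(net)
    pvec[k] <- motif_mean_weight(net)
    rvec[k] <- mean(stats$rates)
    if (k == length(times)) break
    dW <- tryCatch(weight_drift(net, stats, rule, flavor, tauS),
                   error = function(e) e)
    if (inherits(dW, "error")) {
      err <- conditionMessage(dW)
      times <- times[seq_len(k)]
      break
    }
    Wn <- net$W + (step * 1000) * dW
    Wn <- pmin(pmax(Wn, 0), rule$wmax * net$epsilon) * net$W0
    net$W <- Wn
  }
  out <- list(times = times, p = pvec, mean_rate = rvec,
              motifs = do.call(rbind, motifs), weights = weights,
              net_final = net, error = err)
  class(out) <- "theory_trajectory"
  out
}

#' @export
print.theory_trajectory <- function(x, ...) {
  cat(sprintf("theory_trajectory: %d snapshots over %.0f s\n",
              length(x$times), max(x$times)))
  cat(sprintf("  p: %.4f -> %.4f; mean rate %.2f -> %.2f Hz\n",
              x$p[1], x$p[length(x$p)], 1000 * x$mean_rate[1],
              1000 * x$mean_rate[length(x$mean_rate)]))
  if (!is.null(x$error)) cat("  truncated by error:", x$error, "\n")
  invisible(x)
}

#' Plot a theory trajectory
#'
#' Base-graphics overview: mean synaptic weight and motif strengths against
#' plasticity time.
#'
#' @param x a `theory_trajectory`
#' @param ... passed to [plot()]
#' @export
plot.theory_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$times, x$p, type = "l", xlab = "time (s)",
       ylab = "mean weight p", ...)
  m <- x$motifs
  rng <- range(m$q_div, m$q_con, m$q_ch)
  plot(x$times, m$q_div, type = "l", ylim = rng, xlab = "time (s)",
       ylab = "motif strength", col = 2, ...)
  graphics::lines(x$times, m$q_con, col = 3)
  graphics::lines(x$times, m$q_ch, col = 4)
  graphics::legend("topleft", c("q_div", "q_con", "q_ch"), col = 2:4, lty = 1,
                   bty = "n")
  invisible(x)
}
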