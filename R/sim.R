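## R-side interface to the compiled EIF network simulator and empirical
## spike-statistics estimators.

#' Simulate a recurrent EIF network
#'
#' Euler-Maruyama integration of the EIF membrane equation for every neuron,
#' with exponential current-based synapses (a spike of neuron j injects a
#' postsynaptic current of amplitude `W[i, j]` decaying with `tauS` into each
#' target i), white-noise drive with an optional shared component, and
#' optional online additive Hebbian STDP with hard bounds (all-to-all
#' pairing via exponential traces; exactly coincident pairs potentiate).
#'
#' The STDP amplitudes actually applied are `epsilon * f_plus/f_minus` and
#' the actual bound is `epsilon * wmax`, consistent with the epsilon-scaled
#' weights stored in `net`.
#'
#' @param net a [weighted_network()]
#' @param eif an [eif_params()]
#' @param noise a [noise_params()]
#' @param stdp an [stdp_rule()] (ignored unless `cfg$plasticity_on`)
#' @param cfg a [sim_config()]
#' @param tauS synaptic time constant (ms)
#' @return object of class `spike_data`: list with `spikes` (data.frame
#'   `neuron`, `time_ms`), `N`, `T`, `net_final` (network with final
#'   weights), `weight_traj` (data.frame `time_ms`, `pre`, `post`, `w` if
#'   snapshots were requested; weights on the actual scale)
#' @export
simulate_network <- function(net, eif = eif_params(), noise = noise_params(),
                             stdp = stdp_rule(), cfg = sim_config(),
                             tauS = 5) {
  edges <- which(net$W0 == 1, arr.ind = TRUE)  # col 1 = post i, col 2 = pre j
  record_times <- if (cfg$record_weights_every > 0)
    seq(cfg$record_weights_every, cfg$T, by = cfg$record_weights_every)
  else numeric(0)
  ccfg <- list(dt = cfg$dt, T = cfg$T, tauS = tauS, seed = cfg$seed,
               plasticity_on = cfg$plasticity_on,
               record_spikes = cfg$record_spikes, rate_cap = cfg$rate_cap)
  srule <- list(f_plus = stdp$f_plus * net$epsilon,
                f_minus = stdp$f_minus * net$epsilon,
                tau_plus = stdp$tau_plus, tau_minus = stdp$tau_minus,
                wmax = stdp$wmax * net$epsilon)
  res <- .sim_eif_network(net$N,
                          as.integer(edges[, 2] - 1L),
                          as.integer(edges[, 1] - 1L),
                          net$W[edges], unclass(eif), unclass(noise), srule,
                          ccfg, record_times)
  if (res$aborted)
    stop(sprintf(paste0("rate instability: network-mean firing rate ",
                        "exceeded %g Hz at t = %.0f ms"),
                 cfg$rate_cap, res$t_end))
  Wf <- matrix(0, net$N, net$N)
  Wf[edges] <- res$w_final
  net_final <- net
  net_final$W <- Wf
  out <- list(
    spikes = data.frame(neuron = res$spike_id, time_ms = res$spike_t),
    N = net$N, T = cfg$T, net_final = net_final)
  if (length(record_times) > 0) {
    nE <- nrow(edges)
    out$weight_traj <- data.frame(
      time_ms = rep(res$record_times, each = nE),
      pre = rep(edges[, 2], length(record_times)),
      post = rep(edges[, 1], length(record_times)),
      w = as.vector(res$w_rec))
  }
  class(out) <- "spike_data"
  out
}

#' @export
print.spike_data <- function(x, ...) {
  r <- nrow(x$spikes) / (x$N * x$T) * 1000
  cat(sprintf("spike_data: N = %d, T = %.0f ms, %d spikes (mean %.2f Hz)\n",
              x$N, x$T, nrow(x$spikes), r))
  invisible(x)
}

## binned spike-count matrix (nbins x N); only safe for moderate nbins * N
bin_spikes <- function(spikes, N, T, bin) {
  nb <- floor(T / bin)
  keep <- spikes$time_ms <= nb * bin & spikes$time_ms > 0
  b <- pmin(ceiling(spikes$time_ms[keep] / bin), nb)
  flat <- (spikes$neuron[keep] - 1) * nb + b
  matrix(tabulate(flat, nbins = nb * N), nb, N)
}

## binned counts for a single neuron (memory-safe for fine bins)
bin_spikes_one <- function(spikes, neuron, T, bin) {
  nb <- floor(T / bin)
  tm <- spikes$time_ms[spikes$neuron == neuron]
  tm <- tm[tm > 0 & tm <= nb * bin]
  tabulate(pmin(ceiling(tm / bin), nb), nbins = nb)
}

#' Empirical spike-train cross-covariance functions
#'
#' Bins the spike trains and estimates
#' \eqn{C_{ij}(s) = \langle y_i(t+s) y_j(t)\rangle - r_i r_j}
#' (units spikes^2/ms^2) on a lag grid, for the requested neuron pairs. By
#' construction the estimate satisfies C_ij(s) = C_ji(-s) exactly.
#'
#' @param sim a `spike_data`
#' @param pairs 2-column matrix of (i, j) neuron indices
#' @param bin bin width (ms)
#' @param max_lag maximum lag (ms); must be a multiple of `bin`
#' @return list with `lags` (ms) and `C` (matrix, one row per pair)
#' @export
estimate_cross_covariance <- function(sim, pairs, bin = 1, max_lag = 100) {
  stopifnot(max_lag %% bin == 0)
  if (nrow(sim$spikes) == 0) warning("empty spike trains: zero covariance")
  nb <- floor(sim$T / bin)
  L <- as.integer(max_lag / bin)
  lags <- (-L:L) * bin
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2)
  Cout <- matrix(0, nrow(pairs), 2 * L + 1)
  nfft <- stats::nextn(nb + L + 1, 2)
  get_fft <- function(n) {
    x <- bin_spikes_one(sim$spikes, n, sim$T, bin)
    stats::fft(c(x - mean(x), numeric(nfft - nb)))
  }
  for (k in seq_len(nrow(pairs))) {
    fi <- get_fft(pairs[k, 1])
    fj <- get_fft(pairs[k, 2])
    cc <- Re(stats::fft(fi * Conj(fj), inverse = TRUE)) / nfft
    ## cc[1 + s] = sum_t xi(t + s) xj(t) (circular; zero-padded)
    raw <- c(rev(cc[nfft - (0:(L - 1))]), cc[1:(L + 1)])
    nterms <- nb - abs(-L:L)
    Cout[k, ] <- raw / (nterms * bin^2)
  }
  list(lags = lags, C = Cout)
}

#' Spike-count correlation coefficients
#'
#' Pearson correlations of spike counts in disjoint windows, averaged over
#' all unordered neuron pairs and over directly connected pairs (pairs
#' joined by a synapse in either direction). Neurons that never spike are
#' excluded from the averages.
#'
#' @param sim a `spike_data`
#' @param W0 adjacency matrix used to define connected pairs
#' @param window window length (ms)
#' @return list with `all_pairs`, `connected_pairs`, `n_silent`, `window`
#' @export
spike_count_correlations <- function(sim, W0, window = 100) {
  counts <- bin_spikes(sim$spikes, sim$N, sim$T, window)
  if (nrow(counts) < 50)
    warning("fewer than 50 windows; correlation estimates will be noisy")
  active <- colSums(counts) > 0
  cc <- suppressWarnings(stats::cor(counts[, active]))
  conn <- ((W0 + t(W0)) > 0)[active, active]
  ut <- upper.tri(cc)
  list(all_pairs = mean(cc[ut], na.rm = TRUE),
       connected_pairs = mean(cc[ut & conn], na.rm = TRUE),
       n_silent = sum(!active), window = window)
}

#' Empirical firing rates
#'
#' @param sim a `spike_data`
#' @return per-neuron rates (spikes/ms)
#' @export
empirical_rates <- function(sim) {
  tabulate(sim$spikes$neuron, nbins = sim$N) / sim$T
}

#' Write spikes as two-column CSV
#'
#' @param sim a `spike_data`
#' @param path file path
#' @export
write_spikes_csv <- function(sim, path) {
  utils::write.csv(sim$spikes, path, row.names = FALSE)
  invisible(path)
}
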