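## Linear-response theory for network spike-train cross-covariances.
##
## In the frequency domain (convention: y(omega) = int y(t) e^{-2 pi i omega
## t} dt) the linear ansatz gives
##   C(omega) = (I - (W.K))^-1 C0(omega) (I - (W.K))^-*,
## with interaction kernel K_ij(omega) = A_i(omega) J(omega) and C0 the
## diagonal matrix of baseline power spectra. Cross-covariances are
## Hermitian in omega (C_ij(-omega) = conj(C_ij(omega))), so everything is
## computed on the nonnegative half-grid. Inverse transforms give
## C_ij(s) = <y_i(t+s) y_j(t)> - r_i r_j with C_ij(s) = C_ji(-s).

## spectral-radius guard for the linearization, checked exactly at omega = 0
## (where the low-pass kernel is largest) and via the bound
## max_i |A_i J| * rho(W) elsewhere.
check_linearization <- function(net, stats, tauS = 5) {
  i0 <- which(stats$grid$omega == 0)
  a0 <- Re(stats$A[, i0]) * tauS
  G0 <- net$W * a0   # rows scaled by A_i(0) J(0)
  ev <- eigen(G0, only.values = TRUE)$values
  rho0 <- max(Mod(ev))
  if (rho0 >= 1)
    stop(sprintf(paste0("linearization invalid: spectral radius of W.K(0) ",
                        "= %.3f >= 1 (weights too strong)"), rho0))
  rho0
}

#' Full linear-response cross-covariance solve
#'
#' Solves \eqn{C(\omega) = (I - WK)^{-1} C^0 (I - WK)^{-*}} at each
#' frequency by dense LU solves (no explicit inverse unless all pairs are
#' requested). Baseline covariance is diagonal: only internally generated
#' correlations are modeled.
#'
#' With `subset` a vector of neuron indices, only the covariance block among
#' those neurons is computed (sufficient for pair statistics, much cheaper
#' for large N).
#'
#' @param net a [weighted_network()]
#' @param stats output of [network_neuron_stats()] (per-neuron A, C0, rates)
#' @param subset optional neuron indices; default all
#' @param tauS synaptic time constant (ms)
#' @return object of class `covariance_set`: list with `omega_pos`, complex
#'   array `C` (ns x ns x n_omega, frequency domain, nonnegative
#'   frequencies), `neurons`, `rates`, `flavor`, `domega`
#' @export
full_covariance <- function(net, stats, subset = NULL, tauS = 5) {
  N <- net$N
  if (is.null(subset)) subset <- seq_len(N)
  check_linearization(net, stats, tauS)
  grid <- stats$grid
  om <- grid$omega_pos
  iom0 <- which(grid$omega == 0)  # index of omega=0 in the full grid
  nw <- length(om)
  ns <- length(subset)
  Carr <- array(0i, c(ns, ns, nw))
  I_N <- diag(N)
  Esub <- I_N[, subset, drop = FALSE]
  for (k in seq_len(nw)) {
    col <- iom0 + (k - 1)       # position of omega_pos[k] in the full grid
    a <- stats$A[, col] * synaptic_filter_ft(om[k], tauS)
    Mmat <- I_N - net$W * a     # rows of W scaled by A_i J
    ## rows of the resolvent restricted to `subset`:
    X <- t(solve(t(Mmat), Esub))            # ns x N
    c0 <- stats$C0[, col]
    Carr[, , k] <- (X * rep(c0, each = ns)) %*% Conj(t(X))
  }
  structure(list(omega_pos = om, C = Carr, neurons = subset,
                 rates = stats$rates[subset], flavor = "full",
                 domega = grid$domega),
            class = "covariance_set")
}

#' Length-one-path (truncated) cross-covariance
#'
#' Truncates the path expansion of the covariance at length-one paths:
#' \deqn{C_{ij} \approx W_{ij} K_{ij} C^0_{jj}
#'   + C^0_{ii} \bar K_{ji} W_{ji}
#'   + \sum_k W_{ik} K_{ik} C^0_{kk} \bar K_{jk} W_{jk},}
#' i.e. direct forward and backward connections plus common inputs; the
#' diagonal is the baseline spectrum C0_ii.
#'
#' @inheritParams full_covariance
#' @return a `covariance_set` with `flavor = "truncated"`
#' @export
truncated_covariance <- function(net, stats, subset = NULL, tauS = 5) {
  N <- net$N
  if (is.null(subset)) subset <- seq_len(N)
  grid <- stats$grid
  om <- grid$omega_pos
  iom0 <- which(grid$omega == 0)
  nw <- length(om)
  ns <- length(subset)
  Ws <- net$W[subset, subset, drop = FALSE]
  ## group presynaptic neurons by their (quantized) operating point so the
  ## common-input sum needs one Gram matrix per distinct baseline spectrum
  key <- apply(stats$C0[, c(iom0, iom0 + 5), drop = FALSE], 1,
               function(z) paste(signif(z, 12), collapse = "|"))
  groups <- split(seq_len(N), key)
  Gmats <- lapply(groups, function(idx) {
    Wg <- net$W[subset, idx, drop = FALSE]
    Wg %*% t(Wg)
  })
  Carr <- array(0i, c(ns, ns, nw))
  for (k in seq_len(nw)) {
    col <- iom0 + (k - 1)
    Jk <- synaptic_filter_ft(om[k], tauS)
    a <- stats$A[subset, col] * Jk          # A_i J for the subset
    c0 <- stats$C0[subset, col]
    ## forward: W_ij * (A_i J) * C0_jj
    fwd <- (Ws * a) * rep(stats$C0[subset, col], each = ns)
    bwd <- Conj(t(fwd))
    common <- matrix(0i, ns, ns)
    for (g in seq_along(groups)) {
      idx1 <- groups[[g]][1]
      common <- common + Gmats[[g]] * stats$C0[idx1, col]
    }
    common <- common * (a %o% Conj(a))
    Ck <- fwd + bwd + common
    diag(Ck) <- c0
    Carr[, , k] <- Ck
  }
  structure(list(omega_pos = om, C = Carr, neurons = subset,
                 rates = stats$rates[subset], flavor = "truncated",
                 domega = grid$domega),
            class = "covariance_set")
}

#' @export
print.covariance_set <- function(x, ...) {
  cat(sprintf("covariance_set (%s): %d neurons, %d frequencies (0..%.3f /ms)\n",
              x$flavor, length(x$neurons), length(x$omega_pos),
              max(x$omega_pos)))
  invisible(x)
}

## inverse transform of a Hermitian half-grid spectrum to the time domain:
## g(s) = domega * [ g(0) + 2 Re sum_{w>0} ghat(w) e^{2 pi i w s} ]
half_grid_inverse <- function(ghat, omega_pos, domega, s) {
  out <- numeric(length(s))
  for (m in seq_along(s)) {
    ph <- exp(2i * pi * omega_pos * s[m])
    out[m] <- domega * (Re(ghat[1]) +
                          2 * sum(Re(ghat[-1] * ph[-1])))
  }
  out
}

#' Transform a covariance set to the time domain
#'
#' Inverse Fourier transform under the fixed e^{-2 pi i omega t} convention.
#' The result is real by Hermitian symmetry; an error is raised if spectral
#' energy at the grid edge exceeds 1% of the peak (aliasing). For diagonal
#' entries the white floor r_i (the delta atom of a point process spectrum)
#' is subtracted before transforming.
#'
#' @param cov a `covariance_set`
#' @param lags lag grid (ms)
#' @return list with `lags` and array `C` (ns x ns x n_lags, spikes^2/ms^2)
#' @export
freq_to_time <- function(cov, lags = seq(-250, 250, by = 1)) {
  ns <- dim(cov$C)[1]
  nw <- dim(cov$C)[3]
  Ct <- array(0, c(ns, ns, length(lags)))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    g <- cov$C[i, j, ]
    if (i == j) g <- g - cov$rates[i]
    if (max(Mod(g)) > 0 && Mod(g[nw]) > 0.01 * max(Mod(g)))
      stop("aliasing: spectral energy at the grid edge exceeds 1% of peak; ",
           "increase omega_max")
    Ct[i, j, ] <- half_grid_inverse(g, cov$omega_pos, cov$domega, lags)
  }
  list(lags = lags, C = Ct)
}

#' STDP-rule-weighted covariance integrals
#'
#' Computes \eqn{\Gamma_{ij} = \int L(s) C_{ij}(s) ds} for every pair in a
#' covariance set, by the frequency-domain inner product
#' \eqn{\int \hat L(\omega) \overline{\hat C_{ij}(\omega)} d\omega}. These
#' are the quantities that drive the weight drift. Diagonal entries use the
#' full point-process spectrum (including the white floor).
#'
#' @param cov a `covariance_set`
#' @param rule an [stdp_rule()]
#' @return real matrix ns x ns (weight per ms, before the epsilon scaling)
#' @export
rule_weighted_integral <- function(cov, rule) {
  Lhat <- stdp_window_ft(rule, cov$omega_pos)
  nw <- length(cov$omega_pos)
  wts <- c(1, rep(2, nw - 1)) * cov$domega
  ns <- dim(cov$C)[1]
  G <- matrix(0, ns, ns)
  ## sum over the half grid: omega=0 term once, omega>0 terms twice (Re)
  for (k in seq_len(nw)) {
    G <- G + wts[k] * Re(Lhat[k] * Conj(cov$C[, , k]))
  }
  G
}
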