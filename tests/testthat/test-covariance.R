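## small ER network with stats, shared across blocks
small_net_stats <- function() cached("small_net_stats", {
  net <- weighted_network(make_erdos_renyi(30, 0.25, seed = 6), w = 1.2,
                          epsilon = 1 / (30 * 0.25))
  stats <- network_neuron_stats(net, noise_params(), eif_params(),
                                grid = frequency_grid(0.5, 1 / 512))
  list(net = net, stats = stats)
})

test_that("uncoupled network covariance equals the baseline spectra", {
  W0 <- structure(matrix(0, 3, 3), class = c("adjacency", "matrix"), p0 = 0.3)
  net <- weighted_network(W0, w = 0, epsilon = 1)
  stats <- network_neuron_stats(net, noise_params(), eif_params(),
                                grid = frequency_grid(0.5, 1 / 512))
  cv <- full_covariance(net, stats)
  i0 <- which(stats$grid$omega == 0)
  for (k in seq_along(cv$omega_pos)) {
    expect_equal(cv$C[, , k], diag(stats$C0[, i0 + k - 1] + 0i),
                 tolerance = 1e-12)
  }
})

test_that("feedforward pair: truncation is exact and matches the closed form", {
  W0 <- structure(matrix(c(0, 0, 1, 0), 2, 2),
                  class = c("adjacency", "matrix"), p0 = 0.25)
  net <- weighted_network(W0, w = 2, epsilon = 1)
  g <- frequency_grid(0.5, 1 / 512)
  stats <- network_neuron_stats(net, noise_params(), eif_params(), grid = g)
  cf <- full_covariance(net, stats)
  ct <- truncated_covariance(net, stats)
  expect_equal(cf$C[1, 2, ], ct$C[1, 2, ], tolerance = 1e-12)
  expect_equal(cf$C[2, 1, ], ct$C[2, 1, ], tolerance = 1e-12)
  i0 <- which(g$omega == 0)
  cols <- i0 + seq_along(g$omega_pos) - 1
  analytic <- 2 * stats$A[1, cols] * synaptic_filter_ft(g$omega_pos, 5) *
    stats$C0[2, cols]
  expect_equal(cf$C[1, 2, ], analytic, tolerance = 1e-12)
})

test_that("full covariance is Hermitian positive semidefinite", {
  ns <- small_net_stats()
  cv <- full_covariance(ns$net, ns$stats)
  for (k in seq(1, length(cv$omega_pos), by = 50)) {
    Ck <- cv$C[, , k]
    expect_equal(Ck, Conj(t(Ck)), tolerance = 1e-10)
    ev <- eigen(Ck, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * sum(Re(diag(Ck))))
  }
})

test_that("Neumann path expansion converges to the full solve", {
  ns <- small_net_stats()
  net <- ns$net; stats <- ns$stats
  g <- stats$grid
  i0 <- which(g$omega == 0)
  k <- 8  # a representative frequency
  col <- i0 + k - 1
  a <- stats$A[, col] * synaptic_filter_ft(g$omega_pos[k], 5)
  G <- net$W * a
  C0d <- diag(stats$C0[, col] + 0i)
  full <- full_covariance(net, stats)$C[, , k]
  ## partial sums of sum_i G^i C0 (sum_j G^j)^H
  Sn <- diag(nrow(G)) + 0i
  Gp <- diag(nrow(G)) + 0i
  errs <- numeric(3)
  for (n in 1:12) {
    Gp <- Gp %*% G
    Sn <- Sn + Gp
    approx_n <- Sn %*% C0d %*% Conj(t(Sn))
    if (n <= 3) errs[n] <- max(Mod(approx_n - full))
    if (n == 1) {
      ## n = 1 off-diagonal terms are exactly the truncated covariance
      tr <- truncated_covariance(net, stats)$C[, , k]
      offd <- !diag(TRUE, nrow(G))
      expect_equal(approx_n[offd], tr[offd], tolerance = 1e-10)
    }
  }
  expect_lt(max(Mod(approx_n - full)), 1e-10 * max(Mod(full)))
  expect_true(all(diff(errs) < 0))
})

test_that("overstrong coupling is rejected before and at linearization", {
  ## recurrent excitation strong enough to destabilize the rates is caught
  ## by the self-consistent solve
  N <- 10
  W0 <- matrix(0, N, N)
  for (j in 1:N) W0[(j %% N) + 1, j] <- 1
  W0 <- structure(W0, class = c("adjacency", "matrix"), p0 = 1 / N)
  net <- weighted_network(W0, w = matrix(16, N, N) * unclass(W0), wmax = 40,
                          epsilon = 1)
  expect_error(network_neuron_stats(net, noise_params(), eif_params(),
                                    grid = frequency_grid(0.25, 1 / 256)),
               "rate instability")
  ## and a unit spectral radius of W.K(0) (here constructed directly) is
  ## caught by the covariance solve
  g <- frequency_grid(0.25, 1 / 256)
  M <- length(g$omega)
  netw <- weighted_network(W0, w = matrix(25, N, N) * unclass(W0), wmax = 40,
                           epsilon = 1)
  fake <- list(rates = rep(0.008, N), mu_eff = rep(1, N),
               A = matrix(0.01 + 0i, N, M), C0 = matrix(0.008, N, M),
               grid = g, sigma = 9)
  expect_error(full_covariance(netw, fake), "linearization invalid")
})

test_that("inverse transform matches the analytic Lorentzian pair", {
  ## hat g(omega) = 2 a tau / (1 + (2 pi omega tau)^2)  <->  a exp(-|s|/tau)
  g <- frequency_grid(16, 1 / 1024)
  tau <- 12; a <- 3e-4
  ghat <- 2 * a * tau / (1 + (2 * pi * g$omega_pos * tau)^2)
  cov <- structure(list(omega_pos = g$omega_pos,
                        C = array(ghat + 0i, c(1, 1, length(ghat))),
                        neurons = 1, rates = 0, flavor = "full",
                        domega = g$domega), class = "covariance_set")
  lags <- seq(-60, 60, by = 1)
  Ct <- freq_to_time(cov, lags)$C[1, 1, ]
  expect_lt(max(abs(Ct - a * exp(-abs(lags) / tau))) / a, 1e-3)
})

test_that("time-domain covariances are real with the exchange symmetry", {
  ns <- small_net_stats()
  cv <- full_covariance(ns$net, ns$stats, subset = 1:4)
  td <- freq_to_time(cv, lags = seq(-100, 100, by = 1))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(td$C[i, j, ], rev(td$C[j, i, ]), tolerance = 1e-10)
  }
})

test_that("rule-weighted integrals satisfy Parseval against time-domain quadrature", {
  ## wide, fine grid so both quadratures resolve their integrands fully
  net <- small_net_stats()$net
  stats <- network_neuron_stats(net, noise_params(), eif_params(),
                                grid = frequency_grid(2, 1 / 1024))
  cv <- full_covariance(net, stats, subset = 1:3)
  rule <- make_fixture("stdp_balanced_minus")
  G <- rule_weighted_integral(cv, rule)
  lags <- seq(-250, 250, by = 0.25)
  td <- freq_to_time(cv, lags = lags)
  for (i in 1:2) for (j in 1:3) {
    if (i == j) next
    Cs <- td$C[i, j, ]
    L <- stdp_window(rule, lags)
    ## trapezoid on each side of the window's jump at s = 0
    pos <- lags > 0; neg <- lags < 0; z <- lags == 0
    td_int <- 0.25 * (sum(L[pos] * Cs[pos]) + sum(L[neg] * Cs[neg]) +
                        0.5 * Cs[z] * (rule$f_plus - rule$f_minus))
    expect_lt(abs(td_int - G[i, j]) / max(abs(G[i, j]), 1e-14), 1e-3)
  }
})

test_that("pure common input gives temporally symmetric covariance", {
  ## k -> i and k -> j, no i <-> j connection
  W0 <- matrix(0, 3, 3); W0[1, 3] <- W0[2, 3] <- 1
  W0 <- structure(W0, class = c("adjacency", "matrix"), p0 = 2 / 9)
  net <- weighted_network(W0, w = 2, epsilon = 1)
  stats <- network_neuron_stats(net, noise_params(), eif_params(),
                                grid = frequency_grid(0.5, 1 / 512))
  td <- freq_to_time(full_covariance(net, stats),
                     lags = seq(-80, 80, by = 1))
  c12 <- td$C[1, 2, ]
  expect_gt(max(c12), 0)
  expect_equal(c12, rev(c12), tolerance = 1e-10)
})

test_that("theory covariance matches simulation for a weakly coupled network", {
  ## average over many independent feedforward pairs to beat Monte-Carlo noise
  npair <- 60; N <- 2 * npair
  W0 <- matrix(0, N, N)
  for (k in 1:npair) W0[2 * k - 1, 2 * k] <- 1
  W0 <- structure(W0, class = c("adjacency", "matrix"), p0 = sum(W0) / N^2)
  net <- weighted_network(W0, w = 0.25, epsilon = 1)
  stats <- network_neuron_stats(net, noise_params(), eif_params(),
                                grid = frequency_grid(0.5, 1 / 512))
  th <- freq_to_time(full_covariance(net, stats, subset = 1:2),
                     lags = seq(-30, 50, by = 1))$C[1, 2, ]
  sim <- simulate_network(net, eif_params(), noise_params(),
                          cfg = sim_config(T = 2e5, seed = 31))
  pairs <- cbind(seq(1, N, 2), seq(2, N, 2))
  emp <- estimate_cross_covariance(sim, pairs, bin = 1, max_lag = 50)
  idx <- match(seq(-30, 50, 1), emp$lags)
  avg <- colMeans(emp$C)[idx]
  se <- apply(emp$C, 2, sd)[idx] / sqrt(npair)
  ## pointwise agreement within Monte-Carlo error across the lag axis
  z <- (avg - th) / se
  expect_lt(mean(abs(z) > 3), 0.05)
  ## and the rule-relevant integral agrees
  expect_lt(abs(sum(avg) - sum(th)) / sum(th), 0.2)
})
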