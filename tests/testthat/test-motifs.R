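test_that("STDP integral scalars obey their closed forms and sign structure", {
  ## exact balance: f+ tau+ = f- tau-
  r0 <- stdp_rule(f_plus = 2e-3, f_minus = 1.6e-3, tau_plus = 20,
                  tau_minus = 25)
  expect_equal(stdp_area(r0), 0)
  ## depression-doubled preset: S = -f+ tau+
  rd <- make_fixture("stdp_depression2")
  expect_equal(stdp_area(rd), -rd$f_plus * rd$tau_plus)
  ## balanced presets: S = +/- delta * eps * f+ tau+
  rb <- stdp_rule_balanced(-1, delta = 0.1, epsilon = 1 / 150)
  expect_equal(stdp_area(rb), -0.1 / 150 * rb$f_plus * rb$tau_plus,
               tolerance = 1e-12)
  ints <- balanced_ints()
  expect_gt(ints$S_F, 0)
  expect_lt(ints$S_B, 0)
  expect_gt(ints$S_C, 0)
  expect_gt(ints$S_F + 0.15 * ints$S_B, 0)
})

test_that("frequency-domain S_B agrees with direct time-domain convolution", {
  ## wide spectrum so the reconstructed time-domain kernels are clean
  st <- cached("wide_stats",
               frozen_operating_point(noise_params(), eif_params(), w = 2.5,
                                      grid = frequency_grid(4, 1 / 1024)))
  rule <- make_fixture("stdp_balanced_minus")
  ints <- stdp_integrals(rule, st)
  g <- st$grid
  ## time-domain kernels by inverse transform; extended grid for shifts
  ds <- 0.25
  lag <- seq(-300, 300, by = ds)
  lag_ext <- seq(-600, 600, by = ds)
  invft <- function(gh, s_grid) {
    vapply(s_grid, function(s)
      g$domega * sum(Re(gh * exp(2i * pi * g$omega * s))), 0)
  }
  K_ext <- invft(st$A * synaptic_filter_ft(g$omega, 5), lag_ext)
  C0_t <- invft(st$C0 - st$rate, lag)  # smooth part; the delta atom is r
  ## (C0 * K^-)(s) = r K(-s) + int c(u) K(u - s) du, by direct quadrature
  at_ext <- function(s) K_ext[round((s + 600) / ds) + 1]
  CK <- vapply(lag, function(s)
    st$rate * at_ext(-s) + ds * sum(C0_t * at_ext(lag - s)), 0)
  ## trapezoid split at the window's jump at s = 0
  L <- stdp_window(rule, lag)
  S_B_td <- ds * (sum((L * CK)[lag > 0]) + sum((L * CK)[lag < 0]) +
                    0.5 * CK[lag == 0] * (rule$f_plus - rule$f_minus))
  expect_lt(abs(S_B_td - ints$S_B) / abs(ints$S_B), 1e-3)
})

test_that("the reduced right-hand side matches an independent transcription", {
  ints <- balanced_ints()
  cfg <- motif_ode_config(p0 = 0.15, q0_div = 3e-4, q0_con = 2.5e-4,
                          q0_ch = -1e-5, q0_rec = 5e-5, epsilon = 1 / 150)
  set.seed(99)
  for (k in 1:10) {
    st <- random_motif_state()
    expect_equal(motif_rhs(st, cfg, ints), oracle_motif_rhs(st, cfg, ints),
                 tolerance = 1e-13)
  }
})

test_that("unstructured networks form an invariant set of the motif flow", {
  ints <- balanced_ints()
  cfg <- motif_ode_config(p0 = 0.15, epsilon = 1 / 150)  # q0 = 0
  st <- unstructured_state(p = 0.375)
  d <- motif_rhs(st, cfg, ints)
  ## the mean-weight drift collapses to the unstructured quadratic
  dp_expected <- cfg$p0 * ints$r^2 * ints$S +
    cfg$epsilon * (0.375 * (ints$S_F + cfg$p0 * ints$S_B) +
                     0.375^2 * ints$S_C)
  expect_equal(unname(d["p"]), dp_expected, tolerance = 1e-12)
  ## all measurable motif strengths and their mixed counterparts stay put
  for (v in c("q_div", "q_con", "q_ch", "qX_div", "qX_con", "qX_chA",
              "qX_chB"))
    expect_equal(unname(d[v]), 0)
  ## along a trajectory they remain zero to integrator tolerance
  tr <- integrate_motifs(st, cfg, ints, T_total = 20000, n_out = 21)
  for (v in c("q_div", "q_con", "q_ch", "qX_div", "qX_con", "qX_chA",
              "qX_chB"))
    expect_lt(max(abs(tr[[v]])), 1e-10)
})

test_that("chain identity q_ch = q_rec + q_op holds along trajectories", {
  W0 <- make_erdos_renyi(200, 0.15, seed = 13)
  net <- weighted_network(W0)
  cfg <- motif_ode_config_from_network(W0)
  tr <- integrate_motifs(motif_strengths(net), cfg, balanced_ints(),
                         T_total = 5000, n_out = 26)
  expect_lt(max(abs(tr$q_ch - tr$q_rec - tr$q_op)), 1e-12)
})

test_that("unbalanced trajectories integrate to the closed-form solutions", {
  ints <- balanced_ints()
  ints$S <- stdp_area(make_fixture("stdp_depression2"))
  ## rate-only system: closed forms are exact
  ints0 <- ints
  ints0$S_F <- ints0$S_B <- ints0$S_C <- 0
  cfg <- motif_ode_config(p0 = 0.15, q0_div = 3e-4, q0_con = 2.5e-4,
                          q0_ch = -2e-5, q0_rec = 5e-5, epsilon = 1 / 150)
  st0 <- motif_strengths(weighted_network(make_erdos_renyi(150, 0.15, 17)))
  Ts <- seq(0, 2000, by = 500)
  tr <- suppressWarnings(integrate_motifs(st0, cfg, ints0, T_total = 2000,
                                          n_out = 5))
  cl <- unbalanced_solution(Ts, st0, cfg, ints0)
  for (v in c("p", "q_div", "q_con", "q_ch", "qX_div", "qX_con", "qX_chA",
              "qX_chB")) {
    expect_equal(tr[[v]], cl[[v]], tolerance = 1e-7, ignore_attr = TRUE)
  }
  ## with the full O(eps) terms the deviation is small but nonzero
  tr_full <- suppressWarnings(integrate_motifs(st0, cfg, ints,
                                               T_total = 2000, n_out = 5))
  dev <- abs(tr_full$p - cl$p)
  expect_gt(max(dev), 0)
  expect_lt(max(dev) / abs(cl$p[1]), 0.05)
  ## closed form at t = 0 returns the initial state
  expect_equal(unbalanced_solution(0, st0, cfg, ints0)$q_div,
               st0$q_div, ignore_attr = TRUE)
  ## depression-dominated but expansive: the quadratic term eventually wins
  cl_long <- unbalanced_solution(c(0, 5e4), st0, cfg, ints0)
  expect_gt(cl_long$q_div[2], cl_long$q_div[1])
})

test_that("mean-weight fixed points and separatrix behave as the theory says", {
  ints <- balanced_ints()
  cfg <- motif_ode_config(p0 = 0.15, epsilon = 1 / 150)
  ## delta = 0 limit: roots at 0 and -(S_F + p0 S_B)/S_C
  ints0 <- ints; ints0$S <- 0
  fp0 <- mean_weight_fixed_points(cfg, ints0)
  expect_equal(sort(fp0$roots),
               sort(c(0, -(ints$S_F + 0.15 * ints$S_B) / ints$S_C)),
               tolerance = 1e-10)
  ## depression-dominated: one positive (unstable), one negative root
  fp <- mean_weight_fixed_points(cfg, ints)
  expect_length(fp$roots, 2)
  expect_lt(fp$roots[1], 0)
  expect_gt(fp$roots[2], 0)
  expect_equal(fp$stability, c("stable", "unstable"))
  expect_false(is.na(fp$separatrix))
  ## the separatrix rises with connection density
  seps <- sapply(c(0.1, 0.15, 0.2, 0.3), function(p0) {
    mean_weight_fixed_points(
      motif_ode_config(p0 = p0, epsilon = 1 / (1000 * p0)), ints)$separatrix
  })
  expect_true(all(diff(seps) > 0))
})

test_that("initial conditions straddling the separatrix diverge to opposite fates", {
  ints <- balanced_ints()
  cfg <- motif_ode_config(p0 = 0.15, epsilon = 1 / 150)
  ps <- mean_weight_fixed_points(cfg, ints)$separatrix
  up <- suppressWarnings(integrate_motifs(unstructured_state(ps * 1.3), cfg,
                                          ints, T_total = 3e5, n_out = 6))
  dn <- suppressWarnings(integrate_motifs(unstructured_state(ps * 0.7), cfg,
                                          ints, T_total = 3e5, n_out = 6))
  expect_true(all(diff(up$p) > 0))
  expect_true(all(diff(dn$p) < 0))
  expect_gt(up$p[6] - up$p[1], (up$p[2] - up$p[1]) * 4)  # accelerating away
})

test_that("nullcline plane scans expose promotion/suppression regions", {
  ints <- balanced_ints()
  W0 <- make_erdos_renyi(200, 0.15, seed = 23)
  cfg <- motif_ode_config_from_network(W0)
  st <- motif_strengths(weighted_network(W0))
  sc <- motif_plane_scan(st, cfg, ints, vars = c("q_div", "q_con"),
                         xlim = c(0, 5e-3), ylim = c(0, 5e-3), n = 7)
  expect_true(any(sc$d_q_div > 0) || any(sc$d_q_div < 0))
  ## q_div dynamics do not depend on q_con (vertical nullcline): the sign of
  ## d q_div is constant across q_con at fixed q_div
  for (x in unique(sc$q_div)) {
    s <- sign(sc$d_q_div[sc$q_div == x])
    expect_length(unique(s), 1)
  }
})
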