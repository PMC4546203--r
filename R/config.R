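## Run configuration: a nested list mirroring the parameter objects,
## serialized as YAML (or JSON). Unknown keys are rejected so that typos in
## config files fail loudly, and save -> load round-trips bit-exactly.

config_schema <- list(
  eif = c("C", "gL", "VL", "Delta", "VT", "Vth", "Vre", "tau_ref"),
  noise = c("mu", "sigma", "c", "common_kind", "ou_tau"),
  stdp = c("f_plus", "f_minus", "tau_plus", "tau_minus", "wmax"),
  sim = c("dt", "T", "seed", "plasticity_on", "record_weights_every",
          "record_spikes", "rate_cap"),
  network = c("N", "p0", "tauS", "w_init"),
  degree = c("gamma1", "gamma2", "L1", "L2", "rho", "mean_degree"),
  motif_ode = c("T_total", "rtol", "atol"))

#' Default run configuration
#'
#' All model parameters at their defaults: EIF membrane and noise parameters
#' of the standard operating point, N = 1000 at connection density 0.15,
#' Wmax = 5 uA/cm^2, tauS = 5 ms, and the default STDP windows.
#'
#' @return nested list of class `run_config`
#' @export
default_config <- function() {
  cfg <- list(
    eif = unclass(eif_params()),
    noise = unclass(noise_params()),
    stdp = unclass(stdp_rule()),
    sim = unclass(sim_config()),
    network = list(N = 1000, p0 = 0.15, tauS = 5, w_init = 2.5),
    degree = unclass(degree_dist_config()),
    motif_ode = list(T_total = 7200, rtol = 1e-8, atol = 1e-12))
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  bad_sec <- setdiff(names(cfg), names(config_schema))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

#' Load / save a run configuration
#'
#' Configurations are YAML files with the sections of [default_config()].
#' Missing keys are filled with defaults; unknown sections or keys are
#' rejected with an error naming them. `save_config()` followed by
#' `load_config()` reproduces the configuration exactly.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @return a `run_config`
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  validate_config(raw)
  cfg <- default_config()
  for (sec in names(raw))
    for (key in names(raw[[sec]]))
      cfg[[sec]][[key]] <- raw[[sec]][[key]]
  cfg
}

#' @rdname load_config
#' @param cfg a `run_config`
#' @export
save_config <- function(cfg, path) {
  validate_config(unclass(cfg))
  if (grepl("\\.json$", path))
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Canned fixtures
#'
#' Deterministic, named objects used throughout the examples and tests:
#' \describe{
#'   \item{`triad`}{3-neuron graph with synapses 2 -> 1 and 2 -> 3 (hand-
#'     enumerable motif counts).}
#'   \item{`pair_reciprocal`, `pair_feedforward`}{2-neuron circuits with
#'     `epsilon = 1` and mid-range weights, no common input.}
#'   \item{`pair_common_input`}{reciprocal pair driven with a 5% shared
#'     OU (5 ms) input component.}
#'   \item{`er_small`, `er_mid`, `er_large`}{Erdos-Renyi networks at
#'     N = 50, 100, 1000, density 0.15, uniform mid-range weights.}
#'   \item{`powerlaw_rho-0.1`, `powerlaw_rho0.1`, `powerlaw_rho0.5`}{
#'     N = 1000 correlated truncated power-law degree networks
#'     (gamma1 = 0.2, gamma2 = -1, L1 = N/10, L2 = N).}
#'   \item{`stdp_balanced_minus`, `stdp_balanced_plus`}{balanced rules,
#'     S = -/+ delta*eps*f+tau+ with delta = 0.1, eps = 1/150.}
#'   \item{`stdp_depression2`, `stdp_potentiation2`}{unbalanced rules with
#'     total depression (potentiation) twice the opposite area.}
#' }
#'
#' Regeneration from the same (name, seed) is bit-identical.
#'
#' @param name fixture name
#' @param seed integer seed for the stochastic fixtures
#' @return the fixture object (a network, rule or parameter list)
#' @export
make_fixture <- function(name, seed = 1) {
  fixtures <- c("triad", "pair_reciprocal", "pair_feedforward",
                "pair_common_input", "er_small", "er_mid", "er_large",
                "powerlaw_rho-0.1", "powerlaw_rho0.1", "powerlaw_rho0.5",
                "stdp_balanced_minus", "stdp_balanced_plus",
                "stdp_depression2", "stdp_potentiation2")
  if (!name %in% fixtures)
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "))
  adj <- function(M, p0) structure(M, class = c("adjacency", "matrix"),
                                   p0 = p0)
  pair <- function(W0) weighted_network(adj(W0, sum(W0) / 4), w = 2.5,
                                        epsilon = 1)
  pl <- function(rho) {
    cfg <- degree_dist_config(gamma1 = 0.2, gamma2 = -1, L1 = 100, L2 = 1000,
                              rho = rho, mean_degree = 150)
    make_degree_correlated(1000, cfg, seed)
  }
  switch(name,
    triad = adj(matrix(c(0, 0, 0, 1, 0, 1, 0, 0, 0), 3, 3), 2 / 9),
    pair_reciprocal = pair(matrix(c(0, 1, 1, 0), 2, 2)),
    pair_feedforward = pair(matrix(c(0, 0, 1, 0), 2, 2)),
    pair_common_input = list(
      net = pair(matrix(c(0, 1, 1, 0), 2, 2)),
      noise = noise_params(c = 0.05, common_kind = "OU", ou_tau = 5)),
    er_small = weighted_network(make_erdos_renyi(50, 0.15, seed)),
    er_mid = weighted_network(make_erdos_renyi(100, 0.15, seed)),
    er_large = weighted_network(make_erdos_renyi(1000, 0.15, seed)),
    `powerlaw_rho-0.1` = pl(-0.1),
    powerlaw_rho0.1 = pl(0.1),
    powerlaw_rho0.5 = pl(0.5),
    stdp_balanced_minus = stdp_rule_balanced(-1),
    stdp_balanced_plus = stdp_rule_balanced(+1),
    stdp_depression2 = stdp_rule_unbalanced("depression"),
    stdp_potentiation2 = stdp_rule_unbalanced("potentiation"))
}

#' Compare trajectories quantity by quantity
#'
#' Aligns two trajectory tables on their common time column and reports, for
#' every shared quantity, the maximum absolute error, the error relative to
#' the reference's dynamic range, and a pass/fail flag against the given
#' tolerance.
#'
#' @param ref,test data.frames sharing a time column and quantity columns
#' @param time_col name of the time column
#' @param tol relative tolerance (fraction of the reference dynamic range;
#'   a constant reference falls back to absolute comparison against `tol`)
#' @return data.frame: `quantity`, `max_abs_err`, `rel_err`, `pass`
#' @export
compare_runs <- function(ref, test, time_col = "time_s", tol = 0.1) {
  common_t <- intersect(ref[[time_col]], test[[time_col]])
  if (length(common_t) == 0) stop("no common time points")
  vars <- setdiff(intersect(names(ref), names(test)), time_col)
  if (length(vars) == 0) stop("no common quantities")
  out <- do.call(rbind, lapply(vars, function(v) {
    r <- ref[[v]][match(common_t, ref[[time_col]])]
    s <- test[[v]][match(common_t, test[[time_col]])]
    err <- max(abs(r - s))
    rng <- diff(range(r))
    rel <- if (rng > 0) err / rng else err
    data.frame(quantity = v, max_abs_err = err, rel_err = rel,
               pass = rel <= tol)
  }))
  rownames(out) <- NULL
  out
}
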