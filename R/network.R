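## Network generation and motif statistics.
##
## Orientation convention everywhere: entry (i, j) of an adjacency or weight
## matrix refers to the synapse j -> i (row = postsynaptic, column =
## presynaptic), matching the summation in the membrane equation.

#' Erdos-Renyi directed adjacency matrix
#'
#' Each off-diagonal entry is independently 1 with probability `p0`; the
#' diagonal is structurally zero (no autapses).
#'
#' @param N number of neurons (>= 2)
#' @param p0 connection probability in (0, 1\]
#' @param seed integer seed
#' @return binary N x N matrix of class `adjacency` with attribute `p0`
#' @export
make_erdos_renyi <- function(N, p0, seed = 1) {
  if (!(N >= 2) || !(p0 > 0 && p0 <= 1))
    stop("invalid parameters: need N >= 2 and 0 < p0 <= 1")
  set.seed(as.integer(seed))
  W0 <- matrix(as.numeric(stats::runif(N * N) < p0), N, N)
  diag(W0) <- 0
  structure(W0, class = c("adjacency", "matrix"), p0 = p0)
}

#' Degree-distribution configuration for heavy-tailed networks
#'
#' Describes marginal in- and out-degree densities that are a truncated power
#' law with exponent `gamma1` on \[0, L1\] and `gamma2` on \[L1, L2\]
#' (continuous at L1), coupled by a Gaussian copula with correlation `rho`.
#'
#' @param gamma1,gamma2 power-law exponents of the low- and high-degree pieces
#' @param L1,L2 truncation degrees, 0 <= L1 <= L2
#' @param rho in/out-degree copula correlation, |rho| < 1
#' @param mean_degree target mean degree (N * p0)
#' @return an object of class `degree_dist_config`
#' @export
degree_dist_config <- function(gamma1 = 0.2, gamma2 = -1, L1 = 100, L2 = 1000,
                               rho = 0, mean_degree = 150) {
  stopifnot(L1 >= 0, L2 >= L1, abs(rho) < 1, mean_degree > 0)
  cfg <- list(gamma1 = gamma1, gamma2 = gamma2, L1 = L1, L2 = L2, rho = rho,
              mean_degree = mean_degree)
  class(cfg) <- "degree_dist_config"
  cfg
}

## Inverse CDF of the normalized two-piece truncated power law, tabulated
## numerically. Returns a function u in [0,1] -> degree.
powerlaw_inverse_cdf <- function(cfg, n_tab = 4096) {
  d <- seq(0, cfg$L2, length.out = n_tab)
  dens <- ifelse(d <= cfg$L1, d^cfg$gamma1,
                 cfg$L1^(cfg$gamma1 - cfg$gamma2) * d^cfg$gamma2)
  dens[!is.finite(dens)] <- 0
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[n_tab]
  mean_d <- sum(d * dens) / sum(dens)
  list(qfun = stats::approxfun(cdf, d, ties = "ordered", rule = 2),
       mean = mean_d)
}

#' Directed network with correlated truncated power-law degrees
#'
#' Degree targets are drawn per neuron from the two-piece truncated power-law
#' density (continuous at `L1`), with in- and out-degrees coupled through a
#' Gaussian copula of correlation `rho`. Because the normalized continuous
#' density fixes its own mean, the drawn degrees are rescaled by
#' `mean_degree / mean` so the realized mean degree matches `N * p0`. Edges
#' are then sampled independently with Chung-Lu likelihoods proportional to
#' the product of target in-degree of the postsynaptic and out-degree of the
#' presynaptic neuron,
#' \deqn{P(j \to i) = d^{in}_i d^{out}_j / (N \bar d),}
#' clipped at 1 (a warning reports the clipped fraction).
#'
#' @param N number of neurons
#' @param cfg a [degree_dist_config()]
#' @param seed integer seed
#' @return binary N x N matrix of class `adjacency`, attributes `p0` (target
#'   density) and `degree_targets` (data.frame of in/out targets)
#' @export
make_degree_correlated <- function(N, cfg, seed = 1) {
  stopifnot(inherits(cfg, "degree_dist_config"), N >= 2)
  set.seed(as.integer(seed))
  icdf <- powerlaw_inverse_cdf(cfg)
  ## Gaussian copula: correlated standard normal pair -> uniforms -> quantiles
  z1 <- stats::rnorm(N)
  z2 <- cfg$rho * z1 + sqrt(1 - cfg$rho^2) * stats::rnorm(N)
  scale <- cfg$mean_degree / icdf$mean
  d_in <- round(icdf$qfun(stats::pnorm(z1)) * scale)
  d_out <- round(icdf$qfun(stats::pnorm(z2)) * scale)
  pbar <- outer(d_in, d_out) / (N * cfg$mean_degree)
  n_clip <- sum(pbar > 1)
  if (n_clip > 0) {
    warning(sprintf("edge likelihood clipped at 1 for %d of %d pairs (%.3f%%)",
                    n_clip, N^2, 100 * n_clip / N^2))
    pbar[pbar > 1] <- 1
  }
  W0 <- matrix(as.numeric(stats::runif(N * N) < pbar), N, N)
  diag(W0) <- 0
  structure(W0, class = c("adjacency", "matrix"), p0 = cfg$mean_degree / N,
            degree_targets = data.frame(d_in = d_in, d_out = d_out))
}

#' Weighted network
#'
#' Couples a binary adjacency matrix `W0` with a nonnegative weight matrix
#' `W` (peak EPSC amplitudes, uA/cm^2) supported on the edges of `W0`.
#' Weights, motif coordinates and STDP amplitudes are all measured on a
#' rescaled O(1) scale; the synaptic amplitudes actually applied in the
#' network are epsilon-scaled with `epsilon = 1/(N p0)`, which keeps the
#' total input per neuron constant as the connection density varies. `W`
#' stores the *actual* (epsilon-scaled) weights.
#'
#' @param W0 binary adjacency ((i, j) = synapse j -> i)
#' @param w either a scalar initial weight on the rescaled scale (every
#'   synapse gets `w * epsilon`) or a full matrix of actual weights
#' @param wmax weight bound on the rescaled scale (uA/cm^2)
#' @param epsilon scaling 1/(N p0); defaults from `attr(W0, "p0")`
#' @return object of class `weighted_network`: list with `W0`, `W`, `wmax`,
#'   `epsilon`, `N`, `p0`
#' @export
weighted_network <- function(W0, w = NULL, wmax = 5, epsilon = NULL) {
  N <- nrow(W0)
  stopifnot(ncol(W0) == N, all(W0 %in% c(0, 1)), all(diag(W0) == 0))
  p0 <- attr(W0, "p0")
  if (is.null(p0)) p0 <- sum(W0) / N^2
  if (is.null(epsilon)) epsilon <- 1 / (N * p0)
  if (is.null(w)) w <- wmax / 2
  W <- if (is.matrix(w)) w else W0 * (w * epsilon)
  if (any(W < 0) || any(W[W0 == 0] != 0))
    stop("weights must be nonnegative and supported on the adjacency")
  if (any(W > wmax * epsilon + 1e-12))
    stop("weights exceed wmax * epsilon")
  net <- list(W0 = unclass(W0), W = unclass(W), wmax = wmax,
              epsilon = epsilon, N = N, p0 = p0)
  class(net) <- "weighted_network"
  net
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: N = %d, %d synapses (density %.4f)\n",
              x$N, sum(x$W0), sum(x$W0) / x$N^2))
  cat(sprintf("  epsilon = %.5g, wmax = %g (actual bound %.5g uA/cm^2)\n",
              x$epsilon, x$wmax, x$wmax * x$epsilon))
  cat(sprintf("  mean weight p = %.4f (rescaled scale; range [0, %.3f])\n",
              motif_mean_weight(x), x$p0 * x$wmax))
  invisible(x)
}

## mean synaptic weight p on the rescaled scale
motif_mean_weight <- function(net) sum(net$W) / (net$epsilon * net$N^2)

#' Motif frequencies of a binary network
#'
#' Exact sums over all index pairs/triples of the adjacency matrix:
#' \deqn{p_0 = N^{-2}\sum W^0_{ij},\quad
#'  q_0^{div} = N^{-3}\sum W^0_{ik}W^0_{jk} - p_0^2,\quad
#'  q_0^{con} = N^{-3}\sum W^0_{ik}W^0_{ij} - p_0^2,}
#' \deqn{q_0^{ch} = N^{-3}\sum W^0_{ij}W^0_{jk} - p_0^2,\quad
#'  q_0^{rec} = N^{-2}\sum W^0_{ij}W^0_{ji} - p_0^2,}
#' i.e. above-chance frequencies of divergent, convergent, chain and
#' reciprocal two-synapse motifs. The triple sums reduce to moments of in-
#' and out-degrees.
#'
#' @param W0 binary adjacency matrix
#' @return list with `p0`, `q0_div`, `q0_con`, `q0_ch`, `q0_rec`
#' @export
motif_frequencies <- function(W0) {
  W0 <- unclass(W0)
  N <- nrow(W0)
  indeg <- rowSums(W0)   # synapses onto i
  outdeg <- colSums(W0)  # synapses made by j
  p0 <- sum(W0) / N^2
  list(p0 = p0,
       q0_div = sum(outdeg^2) / N^3 - p0^2,
       q0_con = sum(indeg^2) / N^3 - p0^2,
       q0_ch = sum(indeg * outdeg) / N^3 - p0^2,
       q0_rec = sum(W0 * t(W0)) / N^2 - p0^2)
}

#' Weighted motif strengths and mixed motifs
#'
#' Computes the 12 motif coordinates of the reduced plasticity theory from a
#' weighted network, on the epsilon-rescaled scale: the mean weight `p`; the
#' two-synapse motif strengths `q_div`, `q_con`, `q_ch` (with `q_ch` split
#' into disynaptic loops `q_rec` and open chains `q_op`, so that
#' `q_ch = q_rec + q_op` holds exactly); the mixed (weight x adjacency)
#' motifs `qX_rec`, `qX_div`, `qX_con`, `qX_chA`, `qX_chB`, which measure
#' mean synaptic strength conditioned on motif membership; and `qX2_rec`,
#' the conditioned second moment of weights in disynaptic loops.
#'
#' @param net a [weighted_network()]
#' @return object of class `motif_state` (named list of the 12 coordinates)
#' @export
motif_strengths <- function(net) {
  N <- net$N
  W1 <- net$W / net$epsilon   # rescaled O(1) weights
  W0 <- net$W0
  inw <- rowSums(W1); outw <- colSums(W1)
  in0 <- rowSums(W0); out0 <- colSums(W0)
  p <- sum(W1) / N^2
  p0 <- sum(W0) / N^2
  q_rec <- sum(W1 * t(W1)) / N^3
  q_ch <- sum(inw * outw) / N^3 - p^2
  st <- list(
    p = p,
    q_div = sum(outw^2) / N^3 - p^2,
    q_con = sum(inw^2) / N^3 - p^2,
    q_ch = q_ch,
    q_rec = q_rec,
    q_op = q_ch - q_rec,
    qX_rec = sum(W1 * t(W0)) / N^2 - p * p0,
    qX_div = sum(outw * out0) / N^3 - p * p0,
    qX_con = sum(inw * in0) / N^3 - p * p0,
    qX_chA = sum(outw * in0) / N^3 - p * p0,
    qX_chB = sum(out0 * inw) / N^3 - p * p0,
    qX2_rec = sum(W1^2 * t(W0)) / N^3)
  class(st) <- "motif_state"
  st
}

#' @export
print.motif_state <- function(x, ...) {
  v <- unlist(unclass(x))
  cat("motif_state (epsilon-rescaled scale):\n")
  print(signif(v, 4))
  invisible(x)
}

#' Read/write dense matrices as CSV
#'
#' Adjacency and weight matrices are stored as headerless dense CSV preceded
#' by a single comment line `# N=<N> kind=<kind>`; entry (i, j) is the
#' synapse j -> i.
#'
#' @param M matrix
#' @param path file path
#' @param kind label written into the header comment
#' @return `read_matrix_csv` returns the matrix with attribute `kind`
#' @export
write_matrix_csv <- function(M, path, kind = "W") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%d kind=%s", nrow(M), kind), con)
  utils::write.table(unclass(M), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kind <- sub(".*kind=", "", hdr)
  M <- as.matrix(utils::read.table(path, sep = ",", skip = 1))
  dimnames(M) <- NULL
  attr(M, "kind") <- kind
  M
}

#' Serialize a motif state to JSON
#'
#' @param state a `motif_state`
#' @param path file path (JSON)
#' @export
write_motif_state <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_motif_state
#' @export
read_motif_state <- function(path) {
  st <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(st) <- "motif_state"
  st
}
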