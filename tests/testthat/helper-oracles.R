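## Shared oracles and cached expensive objects for the test suite.

## Brute-force O(N^3) triple-loop motif frequencies (independent of the
## vectorized implementation).
brute_motif_frequencies <- function(W0) {
  N <- nrow(W0)
  p0 <- sum(W0) / N^2
  sdiv <- scon <- sch <- 0
  for (i in 1:N) for (j in 1:N) for (k in 1:N) {
    sdiv <- sdiv + W0[i, k] * W0[j, k]
    scon <- scon + W0[i, k] * W0[i, j]
    sch <- sch + W0[i, j] * W0[j, k]
  }
  srec <- 0
  for (i in 1:N) for (j in 1:N) srec <- srec + W0[i, j] * W0[j, i]
  list(p0 = p0, q0_div = sdiv / N^3 - p0^2, q0_con = scon / N^3 - p0^2,
       q0_ch = sch / N^3 - p0^2, q0_rec = srec / N^2 - p0^2)
}

## Brute-force motif strengths per the epsilon-rescaled definitions.
brute_motif_strengths <- function(net) {
  N <- net$N
  W <- net$W / net$epsilon
  W0 <- net$W0
  p <- sum(W) / N^2
  p0 <- sum(W0) / N^2
  sdiv <- scon <- sch <- srec <- sXdiv <- sXcon <- sXchA <- sXchB <- 0
  sX2rec <- 0
  for (i in 1:N) for (j in 1:N) for (k in 1:N) {
    sdiv <- sdiv + W[i, k] * W[j, k]
    scon <- scon + W[i, k] * W[i, j]
    sch <- sch + W[i, j] * W[j, k]
    srec <- srec + (i == k) * W[i, j] * W[j, k]
    sXdiv <- sXdiv + W[i, k] * W0[j, k]
    sXcon <- sXcon + W[i, k] * W0[i, j]
    sXchA <- sXchA + W[i, j] * W0[j, k]
    sXchB <- sXchB + W0[i, j] * W[j, k]
    sX2rec <- sX2rec + (i == k) * W[i, j]^2 * W0[j, i]
  }
  sXrec <- 0
  for (i in 1:N) for (j in 1:N) sXrec <- sXrec + W[i, j] * W0[j, i]
  q_ch <- sch / N^3 - p^2
  q_rec <- srec / N^3
  list(p = p, q_div = sdiv / N^3 - p^2, q_con = scon / N^3 - p^2,
       q_ch = q_ch, q_rec = q_rec, q_op = q_ch - q_rec,
       qX_rec = sXrec / N^2 - p * p0, qX_div = sXdiv / N^3 - p * p0,
       qX_con = sXcon / N^3 - p * p0, qX_chA = sXchA / N^3 - p * p0,
       qX_chB = sXchB / N^3 - p * p0, qX2_rec = sX2rec / N^3)
}

## Independent transcription of the reduced motif right-hand side, organized
## as a generic template (rate + S_F + S_B + S_C blocks per coordinate) so
## that a transcription slip in the main implementation would not be
## reproduced here.
oracle_motif_rhs <- function(state, cfg, ints) {
  s <- unlist(unclass(state))
  with(as.list(c(s, unclass(cfg))), {
    r2S <- ints$r^2 * ints$S
    FB <- function(f, b, cc)
      f * ints$S_F + b * ints$S_B + cc * ints$S_C / p0
    e <- epsilon
    A <- qX_chA; B <- qX_chB; D <- q_div + p^2; P <- p * p0
    d <- c(
      p = p0 * r2S + e * FB(p, qX_rec + P, p0 * D + p * (qX_con + B)),
      q_div = 2 * r2S * qX_div +
        2 * e * FB(q_div, p0 * q_ch + p * qX_div,
                   q_ch * (qX_con + P) + qX_div * D),
      q_con = 2 * r2S * qX_con +
        2 * e * FB(q_con, p0 * q_ch + p * qX_con,
                   q_con * (B + P) + qX_con * D),
      q_ch = r2S * (A + B) +
        e * FB(2 * q_ch, p0 * (q_con + q_div) + p * (A + B),
               D * (A + B) + q_ch * (B + P) + q_con * (qX_con + P)),
      q_rec = 2 * e * (r2S * p0 * (qX_rec + P) + ints$S_F * q_rec +
                         ints$S_B * qX2_rec),
      q_op = NA,
      qX_rec = r2S * q0_rec +
        e * FB(qX_rec, (1 - p0) * (qX_rec + P),
               q0_rec * D + B * (B + P) + qX_con * (qX_con + P)),
      qX_div = r2S * q0_div +
        e * FB(qX_div, p * q0_div + p0 * B, q0_div * D + B * (qX_con + P)),
      qX_con = r2S * q0_con +
        e * FB(qX_con, p * q0_con + p0 * A, q0_con * D + qX_con * (B + P)),
      qX_chA = r2S * q0_ch +
        e * FB(qX_chA, p * q0_ch + p0 * qX_con,
               q0_ch * D + qX_con * (qX_con + P)),
      qX_chB = r2S * q0_ch +
        e * FB(qX_chB, p * q0_ch + p0 * qX_div, q0_ch * D + B * (B + P)),
      qX2_rec = 2 * e * (r2S * p0 * (qX_rec + P) + ints$S_F * qX2_rec +
                           ints$S_B * q_rec))
    d["q_op"] <- d["q_ch"] - d["q_rec"]
    d[c("p", "q_div", "q_con", "q_ch", "q_rec", "q_op", "qX_rec", "qX_div",
        "qX_con", "qX_chA", "qX_chB", "qX2_rec")]
  })
}

## A motif state with all coordinates zero except the mean weight.
unstructured_state <- function(p) {
  v <- as.list(stats::setNames(rep(0, 12),
    c("p", "q_div", "q_con", "q_ch", "q_rec", "q_op", "qX_rec", "qX_div",
      "qX_con", "qX_chA", "qX_chB", "qX2_rec")))
  v$p <- p
  structure(v, class = "motif_state")
}

## random motif state for property tests
random_motif_state <- function() {
  v <- as.list(stats::setNames(stats::rnorm(12, sd = 0.05),
    c("p", "q_div", "q_con", "q_ch", "q_rec", "q_op", "qX_rec", "qX_div",
      "qX_con", "qX_chA", "qX_chB", "qX2_rec")))
  v$p <- abs(v$p) + 0.2
  v$q_ch <- v$q_rec + v$q_op
  structure(v, class = "motif_state")
}

## Cached expensive shared objects (one computation per test run).
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

frozen_stats <- function() cached("frozen_stats",
  frozen_operating_point(noise_params(), eif_params(), w = 2.5,
                         grid = frequency_grid(1, 1 / 2048)))

balanced_ints <- function() cached("balanced_ints",
  stdp_integrals(make_fixture("stdp_balanced_minus"), frozen_stats()))
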