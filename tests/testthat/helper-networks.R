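# Fixture factories shared across test files. Everything is built in code;
# no stored data.

# Linear chain 1-2-...-n with unit rates in both directions.
chain_network <- function(n = 3, rate = 1) {
  K <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    K[i + 1, i] <- rate
    K[i, i + 1] <- rate
  }
  rate_network(K)
}

# Two-state network with asymmetric rates k12 (1 -> 2) and k21 (2 -> 1).
two_state <- function(k12 = 1, k21 = 1) {
  K <- matrix(0, 2, 2)
  K[2, 1] <- k12
  K[1, 2] <- k21
  rate_network(K)
}

# Directed 3-cycle with different clockwise / counter-clockwise rates;
# irreversible unless cw == ccw.
three_cycle <- function(cw = 2, ccw = 1) {
  K <- matrix(0, 3, 3)
  K[2, 1] <- cw; K[3, 2] <- cw; K[1, 3] <- cw
  K[3, 1] <- ccw; K[1, 2] <- ccw; K[2, 3] <- ccw
  rate_network(K)
}

# Dense-linear-solve MFPT oracle, independent of the spectral and GT code
# paths: T = tau_S G_S p0 evaluated with a direct solve on the full Q.
mfpt_oracle <- function(net, A, p0_full) {
  S <- setdiff(seq_len(net$n), A)
  BSS <- net$B[S, S, drop = FALSE]
  visits <- solve(diag(length(S)) - BSS, p0_full[S])
  sum(net$tau[S] * visits)
}

# Splitting-probability oracle: probability of absorbing in A1 (vs A2)
# from each source, via the fundamental matrix.
splitting_oracle <- function(net, A1, A2, src) {
  A <- c(A1, A2)
  S <- setdiff(seq_len(net$n), A)
  G <- solve(diag(length(S)) - net$B[S, S, drop = FALSE])
  # absorption into A1: sum over first-entry jumps S -> A1
  hitA1 <- colSums(net$B[A1, S, drop = FALSE] %*% G)
  hitA1[match(src, S)]
}

# The spec-level study conditions for the metastable four-community
# fixture: 2 x 2 wells, 15 nodes each, inter-community barriers deep
# enough that every community has lambda0 * tau_m <= 1e-2.
metastable_cfg <- function() {
  landscape_config(grid = c(2, 2), nodes_per_community = 15,
                   inter_barrier_min = 4.5)
}

# Restricted initial distribution helper: delta at node b (full length).
delta_at <- function(n, b) {
  p <- rep(0, n); p[b] <- 1; p
}
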