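test_that("single-node elimination matches the hand-worked chain renormalization", {
  net <- chain_network(3)
  out <- eliminate_node(net$B, net$tau, 2)
  expect_equal(out$B, matrix(1 / 2, 2, 2), ignore_attr = TRUE)
  expect_equal(out$tau, c(3 / 2, 3 / 2), ignore_attr = TRUE)
  # single-neighbour collapse: B'[i,i] = B[i,z] B[z,i], tau'_i = tau_i + tau_z B[z,i]
  netp <- two_state(2, 3)
  o2 <- eliminate_node(netp$B, netp$tau, 2)
  expect_equal(o2$B[1, 1], 1)
  expect_equal(o2$tau[1], netp$tau[1] + netp$tau[2] * 1, ignore_attr = TRUE)
  # a node never entered from i leaves row i untouched
  K <- matrix(0, 4, 4)
  K[2, 1] <- 1; K[1, 2] <- 1; K[3, 2] <- 1; K[2, 3] <- 1; K[4, 3] <- 1; K[3, 4] <- 1
  net4 <- rate_network(K)
  o4 <- eliminate_node(net4$B, net4$tau, 4)
  expect_equal(o4$B[1, ], net4$B[1, 1:3])
  expect_equal(o4$tau[1], net4$tau[1])
})

test_that("isolated nodes cannot be eliminated", {
  B <- matrix(c(1, 0, 0, 1), 2, 2)   # two absorbing self-loop states
  expect_error(eliminate_node(B, c(1, 1), 1), "isolated")
})

test_that("block elimination reproduces sequential elimination in any order", {
  # 4-chain, Z = {2, 3}: block vs sequential, both orders
  net <- chain_network(4)
  nm <- as.character(1:4)
  B <- net$B; dimnames(B) <- list(nm, nm)
  tau <- net$tau; names(tau) <- nm
  blk <- eliminate_block(B, tau, c(2, 3))
  s1 <- eliminate_node(B, tau, 2)
  s1 <- eliminate_node(s1$B, s1$tau, match("3", colnames(s1$B)))
  s2 <- eliminate_node(B, tau, 3)
  s2 <- eliminate_node(s2$B, s2$tau, match("2", colnames(s2$B)))
  expect_lt(max(abs(blk$B - s1$B)), 1e-12)
  expect_lt(max(abs(blk$tau - s1$tau)), 1e-12)
  expect_lt(max(abs(blk$B - s2$B)), 1e-12)
  # Z = {2} equals eliminate_node; Z = empty is the identity
  one <- eliminate_block(B, tau, 2)
  ref <- eliminate_node(B, tau, 2)
  expect_equal(one$B, ref$B)
  expect_equal(one$tau, ref$tau)
  nothing <- eliminate_block(B, tau, integer(0))
  expect_identical(nothing$B, B)
})

test_that("order invariance holds on random reversible networks", {
  for (seed in 1:8) {
    net <- random_reversible_network(15, seed = seed)
    nm <- as.character(1:15)
    B <- net$B; dimnames(B) <- list(nm, nm)
    tau <- net$tau; names(tau) <- nm
    set.seed(seed + 100)
    Z <- sample(15, 6)
    blk <- eliminate_block(B, tau, Z)
    seq_out <- list(B = B, tau = tau)
    for (z in sample(Z)) {    # random single-node order
      zi <- match(as.character(z), colnames(seq_out$B))
      seq_out <- eliminate_node(seq_out$B, seq_out$tau, zi)
    }
    expect_lt(max(abs(blk$B - seq_out$B)), 1e-10)
    expect_lt(max(abs(blk$tau - seq_out$tau)), 1e-10)
  }
})

test_that("ill-conditioned blocks fall back to state-by-state elimination", {
  net <- random_reversible_network(12, seed = 2)
  nm <- as.character(1:12)
  B <- net$B; dimnames(B) <- list(nm, nm)
  tau <- net$tau; names(tau) <- nm
  Z <- 3:8
  robust <- eliminate_block(B, tau, Z, cond_threshold = 1)  # always fall back
  direct <- eliminate_block(B, tau, Z, cond_threshold = 1e10)
  expect_lt(max(abs(robust$B - direct$B)), 1e-10)
  expect_lt(max(abs(robust$tau - direct$tau)), 1e-10)
})

test_that("partial GT retains boundary plus b0 and eliminates the rest", {
  net <- chain_network(4)
  part <- build_partition(net, c(1, 1, 2, 2))
  red <- partial_gt(net, part)
  # boundary {2}, {3}; b0 = 1 and 3 (ties to smallest id): node 4 goes
  expect_equal(red$retained, c(1L, 2L, 3L))
  expect_equal(red$eliminated, 4L)
  # partition with every node boundary: nothing eliminated
  K <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; K[j, i] <- 1; K[i, j] <- 1 }
  cyc <- rate_network(K)
  p3 <- build_partition(cyc, rep(1:3, 2))
  red3 <- partial_gt(cyc, p3)
  expect_equal(red3$n, 6L)
  expect_equal(red3$B, cyc$B, ignore_attr = TRUE)
  expect_equal(red3$tau, cyc$tau, ignore_attr = TRUE)
})

test_that("renormalized stationary distribution obeys the waiting-time identity", {
  # 3-chain, eliminate node 2: pi^Z = pi tau^Z / tau = (1/2, 1/2)
  net <- chain_network(3)
  part <- build_partition(net, c(1, 1, 2))
  red <- partial_gt(net, part, retain = c(1, 3))
  expect_equal(red$pi, c(1 / 2, 1 / 2), tolerance = 1e-12)
  # Z empty: pi^Z = pi
  redid <- partial_gt(net, build_partition(net, 1:3), retain = 1:3)
  expect_equal(redid$pi, net$pi)
  # random reduction: pi^Z equals the null space of the renormalized Q
  for (seed in 1:5) {
    net <- random_reversible_network(8, seed = seed)
    set.seed(seed)
    Z <- sample(8, 3)
    part <- build_partition(net, rep(1, 8))
    red <- partial_gt(net, part, retain = setdiff(1:8, Z))
    ns <- qr.solve(rbind(red$Q, rep(1, red$n)), c(rep(0, red$n), 1))
    expect_lt(max(abs(red$pi - ns)), 1e-10)
    expect_lt(abs(sum(net$pi[red$retained] * red$tau / red$tau_orig) - 1), 1e-10)
  }
})

test_that("GT preserves MFPTs from any retained source to any retained target", {
  for (seed in 1:10) {
    n <- 8 + (seed * 5) %% 40
    net <- random_reversible_network(n, seed = seed)
    set.seed(seed + 500)
    A <- sample(n, 2)
    b <- sample(setdiff(1:n, A), 1)
    Z <- sample(setdiff(1:n, c(A, b)), min(n - 4, max(1, n %/% 2)))
    t_full <- mfpt_oracle(net, A, delta_at(n, b))
    red <- partial_gt(net, build_partition(net, rep(1, n)),
                      retain = setdiff(1:n, Z))
    t_red <- mfpt_oracle(red, match(A, red$retained),
                         delta_at(red$n, match(b, red$retained)))
    expect_lt(abs(t_red - t_full) / t_full, 1e-8)
  }
})

test_that("GT preserves splitting probabilities between two retained targets", {
  for (seed in 1:5) {
    n <- 14
    net <- random_reversible_network(n, seed = seed + 20)
    set.seed(seed)
    picks <- sample(n, 3)
    a1 <- picks[1]; a2 <- picks[2]; b <- picks[3]
    Z <- sample(setdiff(1:n, picks), 6)
    p_full <- splitting_oracle(net, a1, a2, b)
    red <- partial_gt(net, build_partition(net, rep(1, n)),
                      retain = setdiff(1:n, Z))
    p_red <- splitting_oracle(red, match(a1, red$retained),
                              match(a2, red$retained), match(b, red$retained))
    expect_lt(abs(p_full - p_red), 1e-10)
  }
})

test_that("waiting times are monotonically inflated by elimination", {
  net <- random_reversible_network(20, seed = 4)
  set.seed(4)
  Z <- sample(20, 8)
  red <- partial_gt(net, build_partition(net, rep(1, 20)),
                    retain = setdiff(1:20, Z))
  expect_true(all(red$tau >= red$tau_orig - 1e-14))
  # strict for neighbours of an eliminated node
  nb <- which(rowSums(net$K[, Z, drop = FALSE] > 0) > 0)
  nb <- intersect(nb, red$retained)
  expect_true(all(red$tau[match(nb, red$retained)] >
                    red$tau_orig[match(nb, red$retained)]))
})

test_that("reversibility closes under GT: renormalized chain keeps detailed balance", {
  for (seed in 1:5) {
    net <- random_reversible_network(12, seed = seed + 7)
    set.seed(seed)
    red <- partial_gt(net, build_partition(net, rep(1, 12)),
                      retain = setdiff(1:12, sample(12, 5)))
    flux <- sweep(red$B, 2, red$pi / red$tau, `*`)
    expect_lt(max(abs(flux - t(flux))) / max(flux), 1e-10)
    expect_lt(max(abs(colSums(red$B) - 1)), 1e-10)
  }
})

test_that("a community that would retain nothing raises an error", {
  net <- chain_network(4)
  part <- build_partition(net, c(1, 1, 2, 2))
  expect_error(partial_gt(net, part, retain = c(1, 2)), "retain no nodes")
})
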