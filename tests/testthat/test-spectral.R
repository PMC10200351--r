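test_that("absorbing subsystem of the 3-chain has the known spectrum and Green's matrix", {
  net <- chain_network(3)
  sub <- absorbing_subsystem(net, 3)
  expect_equal(sub$Q_S, matrix(c(-1, 1, 1, -2), 2, 2), ignore_attr = TRUE)
  expect_equal(sub$lambda, c((3 - sqrt(5)) / 2, (3 + sqrt(5)) / 2),
               tolerance = 1e-12)
  expect_equal(sub$G_S, matrix(c(2, 2, 1, 2), 2, 2), ignore_attr = TRUE,
               tolerance = 1e-12)
  # biorthonormality of the mapped eigenvectors
  expect_equal(sub$wL %*% sub$wR, diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # scalar case: single state with escape rate k
  netk <- two_state(4, 1)
  subk <- absorbing_subsystem(netk, 2)
  expect_equal(subk$lambda, 4)
  expect_equal(subk$G_S, matrix(1, 1, 1), ignore_attr = TRUE)
})

test_that("Green's matrix entries count expected visits (simulation check)", {
  net <- chain_network(3)
  sub <- absorbing_subsystem(net, 3)
  set.seed(99)
  visits <- replicate(4000, {
    tr <- kmc_trajectory(net, 1, target = 3)
    c(sum(tr[, "node"] == 1), sum(tr[, "node"] == 2))
  })
  m <- rowMeans(visits)
  se <- apply(visits, 1, stats::sd) / sqrt(ncol(visits))
  expect_lt(abs(m[1] - sub$G_S[1, 1]), 3 * se[1])
  expect_lt(abs(m[2] - sub$G_S[2, 1]), 3 * se[2])
})

test_that("FPT distribution: exponential limit, mean, completeness", {
  netk <- two_state(2.5, 1)
  subk <- absorbing_subsystem(netk, 2)
  d <- fpt_distribution(subk, c(1, 0))
  ts <- c(0.1, 0.5, 2)
  expect_equal(fpt_density(d, ts), 2.5 * exp(-2.5 * ts), tolerance = 1e-12)
  net <- chain_network(3)
  sub <- absorbing_subsystem(net, 3)
  d3 <- fpt_distribution(sub, c(1, 0, 0))
  expect_equal(d3$mean, 3, tolerance = 1e-12)
  expect_equal(sum(d3$c), 1, tolerance = 1e-8)
  # completeness for arbitrary supported initial distributions
  for (seed in 1:5) {
    netr <- random_reversible_network(12, seed = seed)
    subr <- absorbing_subsystem(netr, c(1, 2))
    p0 <- rep(0, 12); p0[3:12] <- runif(10); p0 <- p0 / sum(p0)
    dr <- fpt_distribution(subr, p0)
    expect_equal(sum(dr$c), 1, tolerance = 1e-8)
    # density normalization: integral of p equals 1
    expect_equal(sum(dr$c), dr$normalization)
    grid <- evaluate_fpt(dr, n = 2000, span = c(1e-4, 1e4))
    expect_true(all(grid$p > -1e-12))
  }
})

test_that("log-time density integrates to one and matches t p(t)", {
  net <- chain_network(3)
  d <- fpt_distribution(absorbing_subsystem(net, 3), c(1, 0, 0))
  y <- seq(-12, 8, length.out = 4001)
  P <- fpt_log_density(d, y)
  expect_equal(sum(P) * diff(y)[1], 1, tolerance = 1e-6)
  expect_equal(P, fpt_density(d, exp(y)) * exp(y), tolerance = 1e-10)
})

test_that("MFPT agrees between linear solve, spectral mean and hand solution", {
  net <- chain_network(3)
  sub <- absorbing_subsystem(net, 3)
  expect_equal(mfpt(sub, c(1, 0, 0)), 3, tolerance = 1e-12)
  # start adjacent to target through one edge of rate k
  netk <- two_state(3, 1)
  expect_equal(mfpt(absorbing_subsystem(netk, 2), c(1, 0)), 1 / 3,
               tolerance = 1e-12)
  # spectral vs linear route on random networks
  for (seed in 1:5) {
    netr <- random_reversible_network(15, seed = seed + 40)
    subr <- absorbing_subsystem(netr, c(4, 9))
    p0 <- delta_at(15, 1)
    expect_equal(mfpt(subr, p0), fpt_distribution(subr, p0)$mean,
                 tolerance = 1e-6)
  }
})

test_that("GT route and spectral route agree on a multi-community network", {
  gen <- generate_landscape(metastable_cfg(), seed = 3)
  net <- gen$net; part <- gen$partition
  A <- part$communities[["1"]]
  b <- part$b0[["4"]]
  t_spec <- mfpt(absorbing_subsystem(net, A), delta_at(net$n, b))
  # GT oracle: eliminate everything except b and A
  red <- partial_gt(net, build_partition(net, rep(1, net$n)),
                    retain = c(b, A))
  t_gt <- mfpt_oracle(red, match(A, red$retained),
                      delta_at(red$n, match(b, red$retained)))
  expect_lt(abs(t_spec - t_gt) / t_gt, 1e-8)
})

test_that("mixing time, spectral gap and quasi-stationary distribution", {
  # two symmetric states, internal rate a, escape eps each:
  # lambda0 = eps, lambda1 = 2a + eps, tau_m = 1/(2a)
  a <- 1.7; eps <- 0.05
  K <- matrix(0, 4, 4)
  K[2, 1] <- a; K[1, 2] <- a
  K[3, 1] <- eps; K[1, 3] <- eps
  K[4, 2] <- eps; K[2, 4] <- eps
  K[4, 3] <- 1; K[3, 4] <- 1
  net <- rate_network(K)
  mx <- mixing_time(net, c(1, 2))
  expect_equal(mx$lambda0, eps, tolerance = 1e-10)
  expect_equal(mx$lambda1, 2 * a + eps, tolerance = 1e-10)
  expect_equal(mx$tau_mix, 1 / (2 * a), tolerance = 1e-10)
  # eps -> 0: quasi-stationary distribution tends to local equilibrium
  expect_equal(mx$qsd, c(1 / 2, 1 / 2), tolerance = 1e-6)
  # 3-chain X = {1, 2}: tau_m = 1/sqrt(5), QSD = (phi, 1 - phi)
  net3 <- chain_network(3)
  mx3 <- mixing_time(net3, c(1, 2))
  expect_equal(mx3$tau_mix, 1 / sqrt(5), tolerance = 1e-10)
  expect_equal(mx3$qsd, c((sqrt(5) - 1) / 2, (3 - sqrt(5)) / 2),
               tolerance = 1e-10)
})

test_that("initial distributions: Boltz, Min, Uni and the Mix limits", {
  gen <- generate_landscape(metastable_cfg(), seed = 5)
  net <- gen$net; part <- gen$partition
  nodes <- part$communities[["2"]]
  pb <- make_initial("Boltz", net, part, "2")
  expect_equal(sum(pb$p), 1)
  expect_equal(pb$p[nodes], net$pi[nodes] / sum(net$pi[nodes]))
  pm <- make_initial("Min", net, part, "2")
  expect_equal(which(pm$p == 1), part$b0[["2"]], ignore_attr = TRUE)
  pu <- make_initial("Uni", net, part, "2")
  expect_equal(unique(pu$p[nodes]), 1 / length(nodes))
  # Mix with tau_m = 0 reduces to Uni
  p0 <- make_initial("Mix", net, part, "2", tau_m = 0)
  expect_equal(p0$p, pu$p)
  # Mix as tau_m -> infinity tends to the quasi-stationary distribution
  mx <- mixing_time(net, nodes)
  pinf <- make_initial("Mix", net, part, "2", tau_m = 50 / mx$lambda1)
  expect_equal(pinf$p[nodes], mx$qsd, tolerance = 1e-6, ignore_attr = TRUE)
  # Mix carries its time shift into the distribution mean
  pmix <- make_initial("Mix", net, part, "2")
  expect_equal(pmix$tshift, mx$tau_mix, tolerance = 1e-10)
  d <- escape_time_distribution(net, part, "2", pmix)
  expect_equal(d$mean, sum(d$c / d$lambda) + mx$tau_mix)
})

test_that("escape distributions: Boltz vs Min near-identical under metastability, Uni leaks early", {
  # two deep wells joined by high barriers: lambda0 tau_m well below 1e-3
  gen <- generate_landscape(landscape_config(
    grid = c(2, 1), nodes_per_community = 15, inter_barrier_min = 5), seed = 7)
  net <- gen$net; part <- gen$partition
  rep_meta <- metastability_report(net, part)
  cm <- rep_meta$community[which.min(rep_meta$metastability)]
  expect_lt(min(rep_meta$metastability), 1e-3)
  db <- escape_time_distribution(net, part, cm, make_initial("Boltz", net, part, cm))
  dm <- escape_time_distribution(net, part, cm, make_initial("Min", net, part, cm))
  # compare the log-time densities (the distributions as plotted): under
  # strong metastability the curves coincide to below 1% of the peak
  y <- seq(log(1e-2 / max(db$lambda)), log(1e2 / min(db$lambda)),
           length.out = 600)
  Pb <- fpt_log_density(db, y); Pm <- fpt_log_density(dm, y)
  expect_lt(max(abs(Pb - Pm)), 1e-2 * max(Pb))
  # and the means agree to the metastability scale
  expect_lt(abs(db$mean - dm$mean) / db$mean, 1e-3)
  # Uni puts weight on boundary nodes: strictly higher short-time density
  du <- escape_time_distribution(net, part, cm, make_initial("Uni", net, part, cm))
  expect_gt(sum(du$lambda * du$c), sum(db$lambda * db$c))  # p(0) comparison
})

test_that("precision guard rejects subsystems with catastrophic cancellation", {
  # an initial distribution off the subsystem support is rejected
  net <- chain_network(3)
  sub <- absorbing_subsystem(net, 3)
  expect_error(fpt_distribution(sub, c(0, 0, 1)), "supported on S")
  expect_error(absorbing_subsystem(net, integer(0)), "nonempty")
  expect_error(mixing_time(net, 2), "at least 2")
})
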