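# Stochastic trajectory generation: rejection-free kinetic Monte Carlo on
# full or GT-reduced networks, and an absorbing-Markov-chain basin-escape
# sampler that draws the exit node from exact GT absorption probabilities.
#
# Self-loops on reduced networks are folded analytically: a state with
# self-loop probability s and per-visit waiting time tau is left after a
# geometric number of visits, and the total sojourn time is exponential
# with mean tau / (1 - s). The fold preserves both the mean and the full
# sojourn distribution, and avoids iterated self-jumps.

#' Sample a single kinetic Monte Carlo trajectory
#'
#' Rejection-free kMC: from the current node j the next node is drawn from
#' column j of the branching matrix (self-loops folded, see above) and the
#' sojourn time from an exponential with mean `tau[j]` (or
#' `tau[j]/(1 - B[j,j])` with a self-loop). Runs until the stop condition.
#'
#' @param net a [rate_network()] or `reduced_network`.
#' @param start starting node index.
#' @param max_time stop when cumulative time would exceed this (the final
#'   state is recorded at its jump time; the trajectory then holds).
#' @param target optional integer vector: stop upon first arrival in this
#'   set.
#' @param seed optional integer seed for reproducibility.
#' @return matrix with columns `node` and `time` (cumulative, starting at
#'   0); attribute `hit_target` says whether the target was reached.
#' @export
kmc_trajectory <- function(net, start, max_time = Inf, target = integer(0),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(start >= 1, start <= net$n)
  cum <- build_jump_tables(net)
  nodes <- integer(256); times <- numeric(256)
  nodes[1] <- start; times[1] <- 0
  k <- 1L; t <- 0; cur <- start
  hit <- cur %in% target
  while (!hit && t < max_time) {
    s <- cum$self[cur]
    dt <- stats::rexp(1, rate = (1 - s) / net$tau[cur])
    if (t + dt > max_time) break
    u <- stats::runif(1)
    nxt <- cum$targets[[cur]][findInterval(u, cum$cdf[[cur]]) + 1L]
    t <- t + dt; cur <- nxt
    k <- k + 1L
    if (k > length(nodes)) {
      length(nodes) <- 2L * length(nodes); length(times) <- 2L * length(times)
    }
    nodes[k] <- cur; times[k] <- t
    hit <- cur %in% target
  }
  out <- cbind(node = nodes[seq_len(k)], time = times[seq_len(k)])
  attr(out, "hit_target") <- hit
  out
}

# Per-column jump tables: off-diagonal targets, their cumulative
# probabilities (conditioned on leaving), and self-loop probability.
build_jump_tables <- function(net) {
  if (!is.null(net$.jump_tables)) return(net$.jump_tables)
  n <- net$n
  targets <- vector("list", n); cdf <- vector("list", n)
  self <- numeric(n)
  for (j in seq_len(n)) {
    p <- net$B[, j]
    self[j] <- p[j]
    p[j] <- 0
    nz <- which(p > 0)
    if (!length(nz)) stop(sprintf("node %d has zero escape probability", j))
    w <- p[nz] / sum(p[nz])
    targets[[j]] <- nz
    cs <- cumsum(w)
    cdf[[j]] <- cs[-length(cs)]
  }
  list(targets = targets, cdf = cdf, self = self)
}

#' Simulate an ensemble of kMC trajectories
#'
#' Each trajectory uses its own RNG stream seeded as `seed + i`, so
#' ensembles are reproducible and can be regenerated trajectory-by-
#' trajectory. Starting nodes are drawn from `init` under `seed` before the
#' per-trajectory streams start.
#'
#' @param net a [rate_network()].
#' @param n_traj number of trajectories.
#' @param init an `initial_distribution` from [make_initial()], a
#'   probability vector over nodes, or a single node index.
#' @param max_time,target stop conditions, as in [kmc_trajectory()].
#' @param seed integer base seed.
#' @return An object of class `trajectory_ensemble`: list with
#'   `trajectories` (list of node/time matrices), `seed`, `n_traj`,
#'   `max_time`, `target`, `tshift` (carried from `init`).
#' @export
simulate_ensemble <- function(net, n_traj, init, max_time = Inf,
                              target = integer(0), seed = 1) {
  tshift <- 0
  if (inherits(init, "initial_distribution")) {
    tshift <- init$tshift
    init <- init$p
  }
  set.seed(seed)
  starts <- if (length(init) == 1) {
    rep(as.integer(init), n_traj)
  } else {
    sample(seq_len(net$n), n_traj, replace = TRUE, prob = init)
  }
  trajs <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    trajs[[i]] <- kmc_trajectory(net, starts[i], max_time = max_time,
                                 target = target,
                                 seed = (seed + i) %% .Machine$integer.max)
  }
  structure(list(trajectories = trajs, seed = seed, n_traj = n_traj,
                 max_time = max_time, target = target, tshift = tshift),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  steps <- vapply(x$trajectories, nrow, integer(1))
  cat(sprintf("<trajectory_ensemble> %d trajectories, %d total steps (median %d)\n",
              x$n_traj, sum(steps), as.integer(stats::median(steps))))
  invisible(x)
}

#' Draw one basin escape via the absorbing-Markov-chain route
#'
#' Formulates escape from a community as an absorbing Markov chain: all
#' community states except `start` are GT-eliminated (with the rest of the
#' network absorbing), the residual self-loop at `start` is renormalized
#' away, and the exit node is drawn from the resulting exact absorption
#' probabilities. The escape time is drawn as an exponential with mean
#' equal to the renormalized waiting time of `start`, which equals the
#' exact mean escape time (a GT invariant). The single-exponential shape is
#' an approximation that becomes exact in the metastable limit, where
#' escape is dominated by the slowest community eigenmode.
#'
#' @param net a [rate_network()].
#' @param partition a [build_partition()] result.
#' @param community community name.
#' @param start starting node (must belong to the community).
#' @param seed optional integer seed.
#' @return list with `exit_node`, `time`, and `p_exit` (the absorption
#'   probability vector over exterior nodes) plus `mean_time` (the exact
#'   mean escape time).
#' @export
basin_escape_sample <- function(net, partition, community, start, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- partition$communities[[as.character(community)]]
  if (is.null(nodes)) stop(sprintf("unknown community '%s'", community))
  if (!(start %in% nodes)) stop("start node is outside the community")
  esc <- basin_escape_kernel(net, nodes, start)
  exit <- esc$targets[sample.int(length(esc$targets), 1, prob = esc$p)]
  list(exit_node = exit, time = stats::rexp(1, rate = 1 / esc$mean_time),
       p_exit = stats::setNames(esc$p, esc$targets), mean_time = esc$mean_time)
}

# GT-eliminate community \ {start}; renormalize the start self-loop away.
# Returns exterior jump targets, absorption probabilities and the exact
# mean escape time (renormalized waiting time of start).
basin_escape_kernel <- function(net, community, start) {
  nm <- as.character(seq_len(net$n))
  B <- net$B; dimnames(B) <- list(nm, nm)
  tau <- net$tau; names(tau) <- nm
  Z <- setdiff(community, start)
  if (length(Z)) {
    out <- eliminate_block(B, tau, Z)
    B <- out$B; tau <- out$tau
  }
  si <- match(as.character(start), colnames(B))
  p <- B[, si]
  surv <- sum(p[-si])
  if (surv <= 0) stop("community has no escape route")
  mean_time <- tau[si] / surv
  p <- p[-si] / surv
  keep <- p > 0
  list(targets = as.integer(names(p))[keep], p = unname(p[keep]),
       mean_time = unname(mean_time))
}

#' Community occupation probabilities of a trajectory ensemble
#'
#' For each time on the grid, the fraction of trajectories whose current
#' node (piecewise-constant interpolation of the jump sequence) belongs to
#' each community. Trajectories that stopped early (absorbed or censored)
#' are held at their final node.
#'
#' @param ens a [simulate_ensemble()] result.
#' @param partition a [build_partition()] result; for ensembles run on a
#'   reduced network, pass the labels of the retained nodes (see
#'   `partition_for_reduced()`).
#' @param time_grid numeric vector of times.
#' @return matrix `length(time_grid) x n_communities` of fractions; rows
#'   sum to 1.
#' @export
occupation_probability <- function(ens, partition, time_grid) {
  labs <- as.character(partition$labels)
  comms <- names(partition$communities)
  occ <- matrix(0, length(time_grid), length(comms),
                dimnames = list(NULL, comms))
  for (tr in ens$trajectories) {
    idx <- findInterval(time_grid, tr[, "time"])
    idx[idx < 1] <- 1
    node_at <- tr[idx, "node"]
    lab <- labs[node_at]
    for (ci in seq_along(comms))
      occ[, ci] <- occ[, ci] + (lab == comms[ci])
  }
  occ / ens$n_traj
}

#' Restrict a partition to the retained nodes of a reduced network
#'
#' @param partition the full-network [build_partition()] result.
#' @param reduced a [partial_gt()] result.
#' @return a `community_partition`-like object over the reduced node
#'   indexing, suitable for [occupation_probability()].
#' @export
partition_for_reduced <- function(partition, reduced) {
  labs <- partition$labels[reduced$retained]
  comms <- lapply(names(partition$communities),
                  function(nm) which(as.character(labs) == nm))
  names(comms) <- names(partition$communities)
  structure(list(labels = labs, communities = comms,
                 boundary = NULL, interior = NULL, b0 = NULL),
            class = "community_partition")
}

#' Empirical first-passage time histogram in log time
#'
#' Collects the first-passage times of an ensemble run with a target set,
#' bins `log(FPT)` and reports censored trajectories (those that hit the
#' time limit without absorbing) separately.
#'
#' @param ens a [simulate_ensemble()] result (run with a `target`).
#' @param breaks number of bins or a break vector for [graphics::hist()]
#'   semantics (applied to `log(FPT)`).
#' @return list with `fpt` (vector of first-passage times, shifted by the
#'   ensemble `tshift`), `censored` (count), `mids`, `density` (histogram
#'   of `y = log t`, normalized to unit area).
#' @export
empirical_fpt <- function(ens, breaks = 50) {
  if (ens$n_traj == 0) stop("empty ensemble")
  hitflag <- vapply(ens$trajectories, function(tr)
    isTRUE(attr(tr, "hit_target")), logical(1))
  if (!any(hitflag)) stop("all trajectories censored: no first-passage times")
  fpt <- vapply(ens$trajectories[hitflag],
                function(tr) tr[nrow(tr), "time"], numeric(1)) + ens$tshift
  h <- graphics::hist(log(fpt), breaks = breaks, plot = FALSE)
  list(fpt = fpt, censored = sum(!hitflag), mids = h$mids,
       density = h$density)
}
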