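# Synthetic multi-community model landscapes.
#
# Nodes are states scattered around the wells of a two-dimensional
# multi-well potential (default 3x3 = nine wells). Node energies follow the
# well base plus a quadratic confinement term; edges are placed by a random
# geometric rule thinned/augmented to a target mean degree, with a spanning
# tree guaranteeing intra-well connectivity. Adjacent wells are joined
# through their closest node pairs, which are the ground-truth boundary
# nodes. Each edge carries a shared transition-state energy
# E+ = max(E_i, E_j) + barrier, giving Arrhenius rates that satisfy
# detailed balance exactly with pi ~ exp(-E/T).

#' Configuration for the multi-well landscape generator
#'
#' @param grid wells laid out on a `grid[1] x grid[2]` lattice (default
#'   3 x 3, i.e. nine communities).
#' @param nodes_per_community states per well (default 110, giving ~1000
#'   nodes on the default grid).
#' @param target_mean_degree average node degree the edge-placement rule
#'   aims for (default 8.7).
#' @param well_depth_range interval from which well base energies are drawn
#'   uniformly (energy units, k_B = 1).
#' @param intra_barrier_scale,inter_barrier_scale mean of the exponential
#'   barrier draw added above `max(E_i, E_j)` for intra- and inter-community
#'   edges; the inter scale must be at least the intra scale so communities
#'   are metastable by construction.
#' @param barrier_min minimum barrier added to every transition state.
#' @param inter_barrier_min minimum barrier for inter-community transition
#'   states; setting it well above `barrier_min` bounds the slowest escape
#'   eigenvalue away from the mixing rate, making every community
#'   metastable by construction.
#' @param temperature,prefactor Arrhenius parameters (k_B = h = 1).
#' @param well_spacing lattice constant between well centres.
#' @param well_width standard deviation of node positions about the centre.
#' @param curvature quadratic energy gain per squared distance from the
#'   well centre.
#' @param energy_noise s.d. of Gaussian noise on node energies.
#' @param inter_edges_per_pair closest cross-well node pairs joined between
#'   adjacent wells.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(grid = c(3, 3), nodes_per_community = 110,
                             target_mean_degree = 8.7,
                             well_depth_range = c(0, 2),
                             intra_barrier_scale = 0.8,
                             inter_barrier_scale = 3,
                             barrier_min = 0.3,
                             inter_barrier_min = 2,
                             temperature = 1, prefactor = 1,
                             well_spacing = 4, well_width = 0.7,
                             curvature = 1, energy_noise = 0.1,
                             inter_edges_per_pair = 10) {
  stopifnot(intra_barrier_scale > 0, inter_barrier_scale >= intra_barrier_scale,
            barrier_min >= 0, inter_barrier_min >= barrier_min,
            temperature > 0, prefactor > 0,
            nodes_per_community >= 2)
  structure(as.list(environment()), class = "landscape_config")
}

#' Generate a multi-community model network
#'
#' Builds a kinetic transition network emulating a molecular energy
#' landscape: a Poisson-like degree distribution, Arrhenius rates obeying
#' detailed balance, and metastable communities whose stability grows as
#' the temperature falls. See the package vignette for what the generator
#' does and does not emulate.
#'
#' @param cfg a [landscape_config()].
#' @param seed integer seed.
#' @return list with `net` (a [rate_network()]), `partition` (ground-truth
#'   [build_partition()] result), `assignment` (label vector), `positions`
#'   (n x 2 matrix) and `edges` (data.frame i, j, E_ts, inter flag).
#' @export
generate_landscape <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "landscape_config"))
  set.seed(seed)
  M <- prod(cfg$grid)
  n <- M * cfg$nodes_per_community
  centers <- as.matrix(expand.grid(x = seq_len(cfg$grid[1]),
                                   y = seq_len(cfg$grid[2]))) * cfg$well_spacing
  bases <- stats::runif(M, cfg$well_depth_range[1], cfg$well_depth_range[2])

  assignment <- rep(seq_len(M), each = cfg$nodes_per_community)
  pos <- centers[assignment, , drop = FALSE] +
    matrix(stats::rnorm(2 * n, sd = cfg$well_width), n, 2)
  d2 <- rowSums((pos - centers[assignment, , drop = FALSE])^2)
  E <- bases[assignment] + cfg$curvature * d2 +
    abs(stats::rnorm(n, sd = cfg$energy_noise))

  # --- intra-community edges: geometric candidates, thinned/augmented to
  # the per-community share of the degree budget, spanning tree enforced
  n_adj <- sum(vapply(seq_len(M), function(m) {
    cm <- centers[m, ]
    sum(colSums(abs(t(centers) - cm)) == cfg$well_spacing &
          seq_len(M) > m)
  }, numeric(1)))
  e_inter <- n_adj * cfg$inter_edges_per_pair
  e_total <- round(n * cfg$target_mean_degree / 2)
  e_intra_total <- e_total - e_inter
  if (e_intra_total < n - M)
    stop("unreachable mean degree: fewer edges than a spanning forest needs")
  e_per_comm <- floor(e_intra_total / M)
  max_per_comm <- choose(cfg$nodes_per_community, 2)
  if (e_per_comm > max_per_comm)
    stop("unreachable mean degree: more edges requested than node pairs exist")

  ei <- integer(0); ej <- integer(0); inter <- logical(0)
  for (m in seq_len(M)) {
    nodes <- which(assignment == m)
    dm <- as.matrix(stats::dist(pos[nodes, , drop = FALSE]))
    g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g)
    me <- igraph::as_edgelist(mst, names = FALSE)
    key <- paste(pmin(me[, 1], me[, 2]), pmax(me[, 1], me[, 2]))
    # candidate non-tree pairs, nearest first with random jitter so the
    # degree distribution stays Poisson-like rather than lattice-like
    pr <- which(upper.tri(dm), arr.ind = TRUE)
    pkey <- paste(pr[, 1], pr[, 2])
    cand <- pr[!(pkey %in% key), , drop = FALSE]
    w <- dm[cand] * stats::rexp(nrow(cand))
    need <- e_per_comm - nrow(me)
    if (need > 0) {
      take <- cand[order(w)[seq_len(min(need, nrow(cand)))], , drop = FALSE]
      me <- rbind(me, take)
    }
    ei <- c(ei, nodes[me[, 1]]); ej <- c(ej, nodes[me[, 2]])
    inter <- c(inter, rep(FALSE, nrow(me)))
  }

  # --- inter-community edges: closest node pairs of adjacent wells
  for (m1 in seq_len(M - 1)) for (m2 in seq((m1 + 1), M)) {
    if (sum(abs(centers[m1, ] - centers[m2, ])) != cfg$well_spacing) next
    n1 <- which(assignment == m1); n2 <- which(assignment == m2)
    cross <- outer(seq_along(n1), seq_along(n2), function(a, b)
      sqrt(rowSums((pos[n1[a], , drop = FALSE] - pos[n2[b], , drop = FALSE])^2)))
    ord <- order(cross)[seq_len(cfg$inter_edges_per_pair)]
    ai <- ((ord - 1) %% length(n1)) + 1
    bi <- ((ord - 1) %/% length(n1)) + 1
    ei <- c(ei, n1[ai]); ej <- c(ej, n2[bi])
    inter <- c(inter, rep(TRUE, length(ord)))
  }

  # --- transition-state energies and Arrhenius rates
  scale <- ifelse(inter, cfg$inter_barrier_scale, cfg$intra_barrier_scale)
  bmin <- ifelse(inter, cfg$inter_barrier_min, cfg$barrier_min)
  Ets <- pmax(E[ei], E[ej]) + bmin + stats::rexp(length(ei), 1 / scale)
  lograte <- arrhenius_rates(E, cbind(ei, ej), Ets,
                             temperature = cfg$temperature,
                             prefactor = cfg$prefactor)
  K <- matrix(0, n, n)
  K[cbind(ej, ei)] <- exp(lograte$log_k_ij)   # i -> j
  K[cbind(ei, ej)] <- exp(lograte$log_k_ji)   # j -> i
  net <- rate_network(K, energies = E, temperature = cfg$temperature)
  partition <- build_partition(net, assignment)
  list(net = net, partition = partition, assignment = assignment,
       positions = pos,
       edges = data.frame(i = ei, j = ej, E_ts = Ets, inter = inter))
}

#' Arrhenius rates from node and transition-state energies
#'
#' For an edge (i, j) with shared transition-state energy \eqn{E^\dagger
#' \ge \max(E_i, E_j)}, the directional rates are
#' \eqn{k_{i \to j} = \nu \exp(-(E^\dagger - E_i)/T)} and symmetrically for
#' \eqn{j \to i}. The shared barrier makes detailed balance with
#' \eqn{\pi \propto e^{-E/T}} an algebraic identity. Rates are returned as
#' natural logs so that deep barriers at low temperature do not underflow.
#'
#' @param E node energy vector.
#' @param edges two-column matrix of node index pairs (i, j).
#' @param E_ts transition-state energy per edge.
#' @param temperature,prefactor Arrhenius parameters.
#' @return data.frame with `log_k_ij` (rate i -> j) and `log_k_ji`.
#' @export
arrhenius_rates <- function(E, edges, E_ts, temperature = 1, prefactor = 1) {
  edges <- as.matrix(edges)
  bad <- E_ts < pmax(E[edges[, 1]], E[edges[, 2]])
  if (any(bad))
    stop(sprintf("transition-state energy below endpoint energy on %d edge(s)",
                 sum(bad)))
  data.frame(
    log_k_ij = log(prefactor) - (E_ts - E[edges[, 1]]) / temperature,
    log_k_ji = log(prefactor) - (E_ts - E[edges[, 2]]) / temperature)
}

#' Per-community metastability report
#'
#' Tabulates, for every community, the mixing time \eqn{\tau_m =
#' 1/(\lambda_1 - \lambda_0)}, the slowest escape eigenvalue
#' \eqn{\lambda_0}, the metastability measure \eqn{\lambda_0 \tau_m} and
#' the mean escape time from local equilibrium. Communities covering the
#' whole network (no escape) report infinite escape time.
#'
#' @param net a [rate_network()].
#' @param partition a [build_partition()] result.
#' @return data.frame with one row per community.
#' @export
metastability_report <- function(net, partition) {
  rows <- lapply(names(partition$communities), function(nm) {
    nodes <- partition$communities[[nm]]
    if (length(nodes) == net$n || length(nodes) < 2) {
      if (length(nodes) == net$n)
        return(data.frame(community = nm, n_nodes = length(nodes),
                          tau_mix = NA_real_, lambda0 = 0,
                          metastability = 0, mean_escape = Inf))
      sub <- absorbing_subsystem_nodes(net, nodes)
      return(data.frame(community = nm, n_nodes = 1L, tau_mix = 0,
                        lambda0 = sub$lambda[1], metastability = 0,
                        mean_escape = 1 / sub$lambda[1]))
    }
    mx <- mixing_time(net, nodes)
    p0 <- make_initial("Boltz", net, partition, nm)
    sub <- absorbing_subsystem_nodes(net, nodes)
    data.frame(community = nm, n_nodes = length(nodes),
               tau_mix = mx$tau_mix, lambda0 = mx$lambda0,
               metastability = mx$metastability,
               mean_escape = mfpt(sub, p0))
  })
  do.call(rbind, rows)
}

#' Random reversible test network
#'
#' A small connected network with random node energies, a random-graph
#' edge set (spanning tree plus random extra edges) and Arrhenius rates,
#' hence exactly reversible. Used as the property-test fixture factory.
#'
#' @param n number of nodes (>= 2).
#' @param seed integer seed.
#' @param mean_degree target mean degree.
#' @param energy_range,barrier_scale,temperature energy parameters.
#' @return a [rate_network()].
#' @export
random_reversible_network <- function(n, seed = 1, mean_degree = 4,
                                      energy_range = c(0, 3),
                                      barrier_scale = 0.8, temperature = 1) {
  set.seed(seed)
  E <- stats::runif(n, energy_range[1], energy_range[2])
  # spanning tree over a random permutation, then extra random pairs
  perm <- sample.int(n)
  ei <- perm[-1]
  ej <- perm[vapply(seq(2, n), function(k) sample.int(k - 1, 1), integer(1))]
  extra <- max(0, round(n * mean_degree / 2) - (n - 1))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  key <- paste(pmin(ei, ej), pmax(ei, ej))
  pool <- pairs[!(paste(pairs[, 1], pairs[, 2]) %in% key), , drop = FALSE]
  if (extra > 0 && nrow(pool) > 0) {
    take <- pool[sample.int(nrow(pool), min(extra, nrow(pool))), , drop = FALSE]
    ei <- c(ei, take[, 1]); ej <- c(ej, take[, 2])
  }
  Ets <- pmax(E[ei], E[ej]) + 0.05 + stats::rexp(length(ei), 1 / barrier_scale)
  lr <- arrhenius_rates(E, cbind(ei, ej), Ets, temperature = temperature)
  K <- matrix(0, n, n)
  K[cbind(ej, ei)] <- exp(lr$log_k_ij)
  K[cbind(ei, ej)] <- exp(lr$log_k_ji)
  rate_network(K, energies = E, temperature = temperature)
}
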