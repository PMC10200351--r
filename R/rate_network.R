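#' @keywords internal
"_PACKAGE"

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Construct a kinetic transition network from a rate matrix
#'
#' A `rate_network` represents a continuous-time Markov chain on a discrete
#' state space. The rate matrix `K` follows the column convention used
#' throughout the energy-landscape literature: `K[i, j]` is the transition
#' rate from state `j` to state `i` (units 1/time), with zero diagonal. From
#' `K` the constructor derives the mean waiting times
#' \eqn{\tau_j = 1/\sum_{\gamma \ne j} K_{\gamma j}}, the column-stochastic
#' branching (jump-chain) matrix \eqn{B = K D^{-1}} with
#' \eqn{B_{ij} = K_{ij}\tau_j}, the generator \eqn{Q = K - D} whose columns
#' sum to zero, and the stationary distribution \eqn{\pi}.
#'
#' When node energies are supplied the stationary distribution is computed in
#' log space as normalized Boltzmann weights \eqn{\pi_i \propto e^{-E_i/T}},
#' which survives temperatures at which `exp(-E/T)` underflows; otherwise it
#' is obtained from the null space of `Q`.
#'
#' @param K square numeric matrix of rates, `K[i, j]` = rate j -> i,
#'   non-negative off-diagonal, zero diagonal.
#' @param energies optional numeric vector of node energies (k_B = 1).
#' @param temperature temperature used with `energies` to form Boltzmann
#'   weights; ignored when `energies` is `NULL`.
#' @param node_ids optional vector of external node labels (defaults to
#'   `1:n`); kept so that networks read from files report the original ids.
#' @param check if `TRUE` (default), validate connectivity, column
#'   stochasticity of `B` and the stationary condition.
#' @return An object of class `rate_network`: a list with elements `n`,
#'   `node_ids`, `K`, `tau`, `B`, `Q`, `pi`, `energies`, `temperature`,
#'   `reversible` (logical, detailed-balance flag) and `db_residual`
#'   (maximum relative detailed-balance flux residual).
#' @export
rate_network <- function(K, energies = NULL, temperature = 1,
                         node_ids = NULL, check = TRUE) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop("K must be square")
  if (any(diag(K) != 0)) stop("K must have zero diagonal")
  offdiag <- K[row(K) != col(K)]
  if (any(offdiag < 0)) stop("off-diagonal rates must be non-negative")
  if (is.null(node_ids)) node_ids <- seq_len(n)
  if (check) {
    asym <- (K > 0) != (t(K) > 0)
    if (any(asym)) {
      bad <- which(asym, arr.ind = TRUE)[1, ]
      stop(sprintf("connectivity must be symmetric: edge %s-%s present in one direction only",
                   node_ids[bad[2]], node_ids[bad[1]]))
    }
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      (K > 0) * 1, mode = "undirected", diag = FALSE))
    if (comp$no > 1) {
      sizes <- table(comp$membership)
      stop(sprintf("network is disconnected: %d components of sizes %s",
                   comp$no, paste(sizes, collapse = ", ")))
    }
  }
  esc <- colSums(K)
  if (any(esc <= 0)) stop("every node must have positive total escape rate")
  tau <- 1 / esc
  B <- sweep(K, 2, tau, `*`)
  Q <- K
  diag(Q) <- -esc

  net <- structure(list(
    n = n, node_ids = node_ids, K = K, tau = tau, B = B, Q = Q,
    pi = NULL, energies = energies, temperature = temperature,
    reversible = NA, db_residual = NA_real_
  ), class = "rate_network")

  net$pi <- stationary_distribution(net)
  net$db_residual <- check_detailed_balance(net)
  net$reversible <- net$db_residual <= 1e-10
  if (check) {
    cs <- colSums(B)
    if (max(abs(cs - 1)) > 1e-12)
      stop("branching matrix columns do not sum to 1")
  }
  net
}

#' @export
print.rate_network <- function(x, ...) {
  cat(sprintf("<rate_network> %d nodes, %d bidirectional edges\n",
              x$n, sum(x$K[upper.tri(x$K)] > 0 | t(x$K)[upper.tri(x$K)] > 0)))
  cat(sprintf("  reversible: %s (detailed-balance residual %.2e)\n",
              x$reversible, x$db_residual))
  if (!is.null(x$energies))
    cat(sprintf("  energies in [%.3g, %.3g], T = %.3g\n",
                min(x$energies), max(x$energies), x$temperature))
  invisible(x)
}

#' Stationary distribution of a rate network
#'
#' Solves the global-balance condition \eqn{Q\pi = 0}, \eqn{\sum_i \pi_i = 1}.
#' When node energies are available the solution is formed directly as
#' Boltzmann weights in log space, \eqn{\pi_i = e^{-E_i/T} / \sum_j
#' e^{-E_j/T}}, evaluated with a log-sum-exp shift so that deep wells at low
#' temperature do not underflow; the result is cross-checked against the
#' global-balance residual. Without energies the null space of `Q` is found
#' by a bordered linear solve.
#'
#' @param net a [rate_network()].
#' @return numeric probability vector `pi` with `Q %*% pi = 0`, positive
#'   entries, unit sum.
#' @export
stationary_distribution <- function(net) {
  stopifnot(inherits(net, "rate_network"))
  n <- net$n
  if (!is.null(net$energies)) {
    lw <- -net$energies / net$temperature
    pi <- exp(lw - logsumexp(lw))
    # Boltzmann weights must actually solve global balance for this K
    res <- max(abs(net$Q %*% pi)) / max(abs(net$K %*% pi))
    if (res > 1e-8)
      warning(sprintf(
        "Boltzmann weights violate global balance (residual %.2e); falling back to null-space solve",
        res))
    else return(pi)
  }
  M <- rbind(net$Q, rep(1, n))
  pi <- qr.solve(M, c(rep(0, n), 1))
  if (any(pi <= 0)) stop("stationary distribution has non-positive entries (non-ergodic chain?)")
  # uniqueness: a second eigenvalue of Q at zero means a reducible chain
  resid <- max(abs(net$Q %*% pi))
  if (resid > 1e-8 * max(abs(net$Q)))
    stop("null-space solve did not converge: zero eigenvalue may be degenerate (non-ergodic chain)")
  pi / sum(pi)
}

#' Detailed-balance residual
#'
#' Detailed balance requires pairwise flux balance
#' \eqn{K_{ji}\pi_i = K_{ij}\pi_j} for every pair of states, a stronger
#' condition than the global balance \eqn{Q\pi = 0}. Returns the maximum
#' absolute flux imbalance over all pairs, relative to the largest pairwise
#' flux. The chain is flagged reversible when the residual is at most
#' `1e-10`.
#'
#' @param net a [rate_network()].
#' @return scalar: max over pairs of `|K[j,i] pi[i] - K[i,j] pi[j]|` divided
#'   by the maximum pairwise flux.
#' @export
check_detailed_balance <- function(net) {
  stopifnot(inherits(net, "rate_network"))
  pi <- if (is.null(net$pi)) stationary_distribution(net) else net$pi
  flux <- net$K %*% diag(pi)        # flux[i,j] = K_ij pi_j, flow j -> i
  max(abs(flux - t(flux))) / max(flux)
}

#' Community partition of a rate network
#'
#' Builds the boundary/interior decomposition of a node-to-community
#' assignment (a participation function mapping every node to exactly one of
#' M non-overlapping communities). Boundary nodes are the nodes with at
#' least one direct edge to a node of a different community; interior nodes
#' have none. For each community the representative node `b0` is the node of
#' maximal stationary probability over the whole community (boundary
#' included), ties broken by smallest node index.
#'
#' @param net a [rate_network()].
#' @param assignment vector of community labels, one per node (any atomic
#'   labels; coerced to factor levels in order of first appearance of
#'   `sort(unique(.))`).
#' @return An object of class `community_partition`: list with `labels`
#'   (per-node label vector), `communities` (named list of node index
#'   vectors), `boundary`, `interior` (named lists), and `b0` (named integer
#'   vector of representative nodes).
#' @export
build_partition <- function(net, assignment) {
  stopifnot(inherits(net, "rate_network"))
  if (length(assignment) != net$n)
    stop("assignment must give one community label per node")
  labs <- sort(unique(assignment))
  communities <- lapply(labs, function(l) which(assignment == l))
  names(communities) <- as.character(labs)
  if (any(lengths(communities) == 0)) stop("empty community in assignment")
  adj <- net$K > 0
  boundary <- lapply(communities, function(nodes) {
    other <- setdiff(seq_len(net$n), nodes)
    nodes[colSums(adj[other, nodes, drop = FALSE]) > 0]
  })
  interior <- Map(setdiff, communities, boundary)
  b0 <- vapply(communities, function(nodes) {
    nodes[which.max(net$pi[nodes])]   # which.max takes the first maximum
  }, integer(1))
  structure(list(labels = assignment, communities = communities,
                 boundary = boundary, interior = interior, b0 = b0),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities over %d nodes\n",
              length(x$communities), length(x$labels)))
  for (nm in names(x$communities))
    cat(sprintf("  %s: %d nodes, %d boundary, b0 = %d\n", nm,
                length(x$communities[[nm]]), length(x$boundary[[nm]]),
                x$b0[[nm]]))
  invisible(x)
}
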