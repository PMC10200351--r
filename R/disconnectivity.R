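# Effective free energies for (reduced) networks and disconnectivity
# trees. For a renormalized chain with stationary distribution pi^Z,
# branching matrix B^Z and waiting times tau^Z, the retained minima get
#   f_w    = -k_B T log(pi^Z_w)
# and every edge a transition-state free energy defined to reproduce the
# renormalized rate through k = (k_B T / h) exp(-(f+ - f_w)/k_B T):
#   f+_ww' = f_w' - k_B T log(B^Z_ww' / tau^Z_w') + k_B T log(k_B T / h),
# (k_B = h = 1 in the reduced unit system). The same f+ computed from the
# reverse direction agrees exactly iff the chain satisfies detailed
# balance with pi^Z, which is asserted.

#' Effective free energies of a (reduced) network
#'
#' @param net a [rate_network()] or [partial_gt()] result with `pi`, `B`
#'   and `tau` available.
#' @param temperature temperature T (k_B = 1); defaults to the network's.
#' @return An object of class `free_energy_graph`: list with `f` (node free
#'   energies), `edges` (data.frame `i`, `j`, `f_ts`, plus both directional
#'   forms and their disagreement) and `temperature`.
#' @export
effective_free_energies <- function(net, temperature = NULL) {
  T <- if (is.null(temperature)) net$temperature else temperature
  f <- -T * log(net$pi)
  up <- which(upper.tri(net$B) & (net$B > 0 | t(net$B) > 0), arr.ind = TRUE)
  keep <- net$B[up] > 0 & t(net$B)[up] > 0
  up <- up[keep, , drop = FALSE]       # edges with zero branching are omitted
  i <- up[, "row"]; j <- up[, "col"]
  # forward form via the j -> i rate B_ij/tau_j, reverse form via i -> j;
  # the barrier is defined so that k = (k_B T/h) exp(-(f+ - f_src)/k_B T)
  # reproduces the (renormalized) rate exactly
  f_fwd <- f[j] - T * log(net$B[cbind(i, j)] / net$tau[j]) + T * log(T)
  f_rev <- f[i] - T * log(net$B[cbind(j, i)] / net$tau[i]) + T * log(T)
  mism <- abs(f_fwd - f_rev) / pmax(abs(f_fwd), 1)
  if (length(mism) && max(mism) > 1e-10)
    warning(sprintf(
      "directional transition-state free energies disagree (max rel %.2e): chain violates detailed balance",
      max(mism)))
  structure(list(
    f = f,
    edges = data.frame(i = i, j = j, f_ts = (f_fwd + f_rev) / 2,
                       f_ts_fwd = f_fwd, f_ts_rev = f_rev,
                       mismatch = abs(f_fwd - f_rev)),
    temperature = T), class = "free_energy_graph")
}

#' Reconstruct rates from a free-energy graph
#'
#' Inverts the transition-state definition:
#' \eqn{k_{j \to i} = T \exp(-(f^\dagger_{ij} - f_j)/T)} (k_B = h = 1).
#' Used to verify that the free-energy representation reproduces the
#' renormalized rates exactly.
#'
#' @param fe a [effective_free_energies()] result.
#' @return data.frame with `i`, `j`, `k_ij` (rate i -> j) and `k_ji`.
#' @export
rates_from_free_energies <- function(fe) {
  T <- fe$temperature
  data.frame(i = fe$edges$i, j = fe$edges$j,
             k_ij = T * exp(-(fe$edges$f_ts - fe$f[fe$edges$i]) / T),
             k_ji = T * exp(-(fe$edges$f_ts - fe$f[fe$edges$j]) / T))
}

#' Superbasin membership at an energy threshold
#'
#' Superbasins at threshold \eqn{\theta} are the connected components of
#' the graph keeping only edges with \eqn{f^\dagger \le \theta}.
#'
#' @param fe a [effective_free_energies()] result (or any list with `f` and
#'   `edges$i/j/f_ts`).
#' @param threshold energy threshold.
#' @return integer membership vector (component ids).
#' @export
superbasins <- function(fe, threshold) {
  n <- length(fe$f)
  keep <- fe$edges$f_ts <= threshold
  g <- igraph::graph_from_edgelist(
    cbind(fe$edges$i[keep], fe$edges$j[keep]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Disconnectivity tree of a free-energy graph
#'
#' Sweeps an ascending sequence of threshold levels; at each level the
#' superbasins are the connected components of the sub-threshold edge set,
#' and components merging between consecutive levels create internal tree
#' nodes at the merge level. Leaves are the minima. Leaf x-positions order
#' subtrees deterministically by basin size (larger first), then smallest
#' member id.
#'
#' @param fe a [effective_free_energies()] result.
#' @param levels number of uniform levels spanning `[min f, max f_ts]`
#'   (default 50), or an explicit increasing vector of thresholds.
#' @return An object of class `disconnectivity_tree`: list with `merges`
#'   (data.frame `level`, `left`, `right` referencing tree node ids;
#'   negative ids are leaves), `leaf_order`, `leaf_x`, `f`, `levels`.
#' @export
disconnectivity_tree <- function(fe, levels = 50) {
  n <- length(fe$f)
  if (length(levels) == 1) {
    lo <- min(fe$f); hi <- max(fe$edges$f_ts)
    levels <- seq(lo, hi, length.out = levels)
  }
  if (is.unsorted(levels, strictly = TRUE))
    stop("levels must be strictly increasing")
  if (min(levels) > min(fe$f) || max(levels) < max(fe$edges$f_ts))
    stop("levels must span [min f, max f_ts]")
  # union-find over ascending levels
  comp <- seq_len(n)               # current tree-node id of each minimum
  next_id <- n
  merges <- list()
  eord <- order(fe$edges$f_ts)
  ei <- fe$edges$i[eord]; ej <- fe$edges$j[eord]; ef <- fe$edges$f_ts[eord]
  ptr <- 1L
  members <- lapply(seq_len(n), identity)   # minima per live tree node
  for (lev in levels) {
    while (ptr <= length(ef) && ef[ptr] <= lev) {
      a <- comp[ei[ptr]]; b <- comp[ej[ptr]]
      if (a != b) {
        next_id <- next_id + 1L
        merges[[length(merges) + 1L]] <-
          data.frame(level = lev, left = a, right = b, id = next_id)
        mem <- c(members[[a]], members[[b]])
        members[[next_id]] <- mem
        comp[mem] <- next_id
      }
      ptr <- ptr + 1L
    }
  }
  merges <- if (length(merges)) do.call(rbind, merges) else
    data.frame(level = numeric(0), left = integer(0), right = integer(0),
               id = integer(0))
  # deterministic leaf order: recursive, larger subtree first then min id
  ord_leaves <- function(id) {
    if (id <= n) return(id)
    row <- merges[merges$id == id, ]
    kids <- c(row$left, row$right)
    sz <- vapply(kids, function(k) length(members[[k]]), integer(1))
    mn <- vapply(kids, function(k) min(members[[k]]), integer(1))
    kids <- kids[order(-sz, mn)]
    unlist(lapply(kids, ord_leaves))
  }
  roots <- unique(comp)
  roots <- roots[order(-vapply(roots, function(k) length(members[[k]]),
                               integer(1)))]
  leaf_order <- unlist(lapply(roots, ord_leaves))
  structure(list(merges = merges, leaf_order = leaf_order,
                 leaf_x = match(seq_len(n), leaf_order),
                 f = fe$f, levels = levels, n_leaves = n),
            class = "disconnectivity_tree")
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  cat(sprintf("<disconnectivity_tree> %d minima, %d merges over %d levels\n",
              x$n_leaves, nrow(x$merges), length(x$levels)))
  invisible(x)
}

#' Minima of monotonic sequence basins
#'
#' Returns the nodes whose energy is strictly below that of every directly
#' connected neighbour. Ties are resolved by node id (the smaller id counts
#' as lower), so exactly one of an energy-tied connected pair survives.
#'
#' @param net a [rate_network()] (adjacency is taken from nonzero rates).
#' @param energies energy per node; defaults to `net$energies`, falling
#'   back to effective free energies `-T log pi`.
#' @return integer vector of node indices.
#' @export
monotonic_sequence_minima <- function(net, energies = NULL) {
  if (is.null(energies))
    energies <- if (!is.null(net$energies)) net$energies else
      -net$temperature * log(net$pi)
  adj <- net$K > 0
  diag(adj) <- FALSE
  which(vapply(seq_len(net$n), function(i) {
    nb <- which(adj[, i] | adj[i, ])
    all(energies[i] < energies[nb] |
          (energies[i] == energies[nb] & i < nb))
  }, logical(1)))
}
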