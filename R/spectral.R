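# Spectral first-passage analysis of absorbing subsystems.
#
# For a target set A and non-absorbing set S = Omega \ A, the subsystem
# generator Q_S (diagonal includes all escape, so probability leaks into A)
# yields the first-passage time density
#   p(t) = sum_l lambda_l c_l exp(-lambda_l t),
#   c_l  = 1_S (w^R_l (x) w^L_l) P_S(0),
# where {-lambda_l} is the spectrum of Q_S. For reversible chains the
# eigenproblem is solved on the symmetric similarity transform
# Pi^{-1/2} Q_S Pi^{1/2}, which guarantees a real spectrum and orthonormal
# vectors; the mapped left/right eigenvectors are biorthonormal by
# construction.

#' Build an absorbing subsystem for first-passage analysis
#'
#' @param net a [rate_network()] (full or GT-reduced; self-loops in the
#'   branching matrix are handled).
#' @param A integer vector of absorbing target nodes.
#' @return An object of class `absorbing_subsystem`: list with `S`, `A`,
#'   `Q_S`, `B_SS`, `G_S` (fundamental matrix \eqn{[I_S - B_{SS}]^{-1}},
#'   whose (s, s') entry is the expected number of visits to s starting
#'   from s' before absorption), `tau_S`, `lambda` (positive, ascending),
#'   `wR` (matrix, columns are right eigenvectors), `wL` (matrix, rows are
#'   left eigenvectors, biorthonormalized `wL %*% wR = I`).
#' @export
absorbing_subsystem <- function(net, A) {
  stopifnot(inherits(net, "rate_network"))
  A <- sort(unique(as.integer(A)))
  if (length(A) == 0) stop("A must be nonempty")
  S <- setdiff(seq_len(net$n), A)
  if (length(S) == 0) stop("S must be nonempty")
  # every node of S must reach A (connectivity is symmetric, so the
  # undirected component containing A suffices): BFS from A
  adj <- net$K > 0
  reach <- rep(FALSE, net$n); reach[A] <- TRUE
  frontier <- A
  while (length(frontier)) {
    notr <- which(!reach)
    if (!length(notr)) break
    hit <- colSums(adj[frontier, notr, drop = FALSE]) > 0
    nxt <- notr[hit]
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(reach[S]))
    stop(sprintf("nodes with no path to A: %s",
                 paste(net$node_ids[S[!reach[S]]], collapse = ", ")))

  Q_S <- net$Q[S, S, drop = FALSE]
  B_SS <- net$B[S, S, drop = FALSE]
  G_S <- solve(diag(length(S)) - B_SS)
  pi_S <- net$pi[S]
  if (isTRUE(net$reversible)) {
    sq <- sqrt(pi_S)
    M <- Q_S * outer(1 / sq, sq)           # Pi^{-1/2} Q_S Pi^{1/2}
    M <- (M + t(M)) / 2                    # symmetrize roundoff
    es <- eigen(M, symmetric = TRUE)
    ord <- order(-es$values)               # lambda ascending
    lambda <- -es$values[ord]
    V <- es$vectors[, ord, drop = FALSE]
    wR <- V * sq                           # diag(sqrt(pi)) V
    wL <- t(V / sq)                        # V^T diag(1/sqrt(pi))
  } else {
    es <- eigen(Q_S)
    if (any(abs(Im(es$values)) > 1e-10 * max(abs(es$values))))
      warning("complex eigenvalues in non-reversible subsystem; using real parts")
    ord <- order(-Re(es$values))
    lambda <- -Re(es$values)[ord]
    wR <- Re(es$vectors)[, ord, drop = FALSE]
    wL <- solve(wR)                        # rows biorthonormal to columns of wR
  }
  if (any(lambda <= 0))
    stop("non-positive decay eigenvalue: subsystem is not absorbing")
  structure(list(S = S, A = A, Q_S = Q_S, B_SS = B_SS, G_S = G_S,
                 tau_S = net$tau[S], pi_S = pi_S,
                 lambda = lambda, wR = wR, wL = wL,
                 node_ids = net$node_ids),
            class = "absorbing_subsystem")
}

# Coerce an initial distribution (initial_distribution object, full-length
# vector, or vector over S) to a probability vector over sub$S.
as_p0 <- function(sub, p0) {
  tshift <- 0
  if (inherits(p0, "initial_distribution")) {
    tshift <- p0$tshift
    p0 <- p0$p
  }
  nS <- length(sub$S)
  if (length(p0) == nS) {
    v <- p0
  } else {
    if (any(p0[-sub$S] != 0))
      stop("initial distribution must be supported on S")
    v <- p0[sub$S]
  }
  if (any(v < 0) || abs(sum(v) - 1) > 1e-8)
    stop("initial distribution must be nonnegative with unit sum")
  list(p = v / sum(v), tshift = tshift)
}

#' First-passage time distribution from spectral modes
#'
#' Computes the mode weights \eqn{c_\ell = 1_S (w^R_\ell \otimes
#' w^L_\ell) P_S(0)} and returns an object evaluating the density
#' \eqn{p(t) = \sum_\ell \lambda_\ell c_\ell e^{-\lambda_\ell t}}, the
#' log-time density \eqn{P(y) = \sum_\ell \lambda_\ell e^{y - \lambda_\ell
#' e^y} c_\ell} with \eqn{y = \ln t}, the survival function and the mean
#' \eqn{\sum_\ell c_\ell/\lambda_\ell}.
#'
#' The expansion is complete, so \eqn{\sum_\ell c_\ell = 1}; a deviation
#' beyond `1e-6`, or any \eqn{|c_\ell| > 10^3} (wild cancellation), is the
#' finite-precision failure mode of ill-conditioned chains and raises an
#' error instead of returning an inaccurate distribution.
#'
#' @param sub an [absorbing_subsystem()].
#' @param p0 initial distribution: an `initial_distribution`, a vector over
#'   the full network supported on S, or a vector over S.
#' @return An object of class `fpt_distribution`: list with `lambda`, `c`,
#'   `mean`, `tshift` (nonzero for mixing-time-evolved initial conditions)
#'   and `normalization` (\eqn{\sum c_\ell}).
#' @export
fpt_distribution <- function(sub, p0) {
  stopifnot(inherits(sub, "absorbing_subsystem"))
  ip <- as_p0(sub, p0)
  cl <- colSums(sub$wR) * as.vector(sub$wL %*% ip$p)
  if (max(abs(cl)) > 1e3)
    stop(sprintf("spectral mode weight of magnitude %.3g: precision lost to cancellation; use the GT route",
                 max(abs(cl))))
  s <- sum(cl)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("spectral expansion normalization residual %.3e exceeds 1e-6: precision lost; use the GT route",
                 s - 1))
  structure(list(lambda = sub$lambda, c = cl,
                 mean = sum(cl / sub$lambda) + ip$tshift,
                 tshift = ip$tshift, normalization = s),
            class = "fpt_distribution")
}

#' @export
print.fpt_distribution <- function(x, ...) {
  cat(sprintf("<fpt_distribution> %d modes, mean = %.6g, sum(c) - 1 = %+.2e\n",
              length(x$lambda), x$mean, x$normalization - 1))
  if (x$tshift > 0) cat(sprintf("  time shift (mixing evolution): %.4g\n", x$tshift))
  invisible(x)
}

#' @rdname fpt_distribution
#' @param d an `fpt_distribution`.
#' @param t,y evaluation points (times, or log-times `y = log t`).
#' @export
fpt_density <- function(d, t) {
  t0 <- pmax(t - d$tshift, 0)
  out <- colSums(d$lambda * d$c * exp(-outer(d$lambda, t0)))
  out[t < d$tshift] <- 0
  out
}

#' @rdname fpt_distribution
#' @export
fpt_log_density <- function(d, y) {
  if (d$tshift > 0) {
    # density of y = log t with the shifted time variable
    t <- exp(y)
    return(fpt_density(d, t) * t)
  }
  ey <- exp(y)
  colSums(d$c * d$lambda * exp(outer(rep(1, length(d$lambda)), y) -
                                 outer(d$lambda, ey)))
}

#' @rdname fpt_distribution
#' @export
fpt_cdf <- function(d, t) {
  t0 <- pmax(t - d$tshift, 0)
  1 - colSums(d$c * exp(-outer(d$lambda, t0)))
}

#' Evaluate a first-passage distribution on a log-spaced grid
#'
#' @param d an `fpt_distribution`.
#' @param n number of grid points (default 400).
#' @param span multiplicative span `(lo, hi)` relative to the fastest and
#'   slowest mode: the grid covers `lo / max(lambda)` to `hi / min(lambda)`.
#' @return data.frame with columns `t`, `p` (density), `y = log(t)`,
#'   `P` (log-time density) and `F` (CDF).
#' @export
evaluate_fpt <- function(d, n = 400, span = c(1e-2, 1e2)) {
  lo <- span[1] / max(d$lambda) + d$tshift
  hi <- span[2] / min(d$lambda) + d$tshift
  t <- exp(seq(log(lo), log(hi), length.out = n))
  data.frame(t = t, p = fpt_density(d, t), y = log(t),
             P = fpt_log_density(d, log(t)), F = fpt_cdf(d, t))
}

#' Mean first-passage time of an absorbing subsystem
#'
#' Computed by the robust linear-solve route \eqn{\tau_S G_S P_S(0)}
#' (expected visits weighted by waiting times) and cross-checked, when the
#' eigendecomposition is available and well conditioned, against the
#' spectral mean \eqn{\sum_\ell c_\ell / \lambda_\ell}; disagreement beyond
#' `1e-6` relative triggers a warning recommending the GT route.
#'
#' @param sub an [absorbing_subsystem()].
#' @param p0 initial distribution (see [fpt_distribution()]).
#' @return scalar mean first-passage time (including any mixing time shift
#'   carried by `p0`).
#' @export
mfpt <- function(sub, p0) {
  ip <- as_p0(sub, p0)
  t_lin <- as.vector(sub$tau_S %*% (sub$G_S %*% ip$p)) + ip$tshift
  spec <- tryCatch(fpt_distribution(sub, p0)$mean, error = function(e) NULL)
  if (!is.null(spec) && abs(spec - t_lin) > 1e-6 * abs(t_lin))
    warning(sprintf("spectral mean %.8g disagrees with linear solve %.8g; prefer the GT route",
                    spec, t_lin))
  t_lin
}

#' Mixing time, spectral gap and quasi-stationary distribution of a node set
#'
#' For a community X, the subsystem generator Q_X (escape included in the
#' diagonal) has reversed-sign spectrum \eqn{0 < \lambda_0 \le \lambda_1
#' \le \dots}; the mixing time is \eqn{\tau_m = 1/(\lambda_1 - \lambda_0)}
#' and the quasi-stationary distribution is the dominant right eigenvector
#' normalized to unit sum. The product \eqn{\lambda_0 \tau_m} measures
#' metastability: values much below 1 mean internal relaxation completes
#' long before escape, so escape statistics become insensitive to the
#' initial distribution within X.
#'
#' @param net a [rate_network()].
#' @param X integer vector of nodes (at least 2).
#' @return list with `tau_mix`, `lambda0`, `lambda1`, `qsd` (vector over X)
#'   and `metastability` (\eqn{\lambda_0\tau_m}).
#' @export
mixing_time <- function(net, X) {
  X <- sort(unique(as.integer(X)))
  if (length(X) < 2) stop("X must contain at least 2 nodes")
  sub <- absorbing_subsystem_nodes(net, X)
  lambda <- sub$lambda
  if (lambda[2] - lambda[1] < 1e-14)
    stop("degenerate spectrum: lambda1 == lambda0 within 1e-14")
  qsd <- sub$wR[, 1]
  qsd <- qsd / sum(qsd)
  list(tau_mix = 1 / (lambda[2] - lambda[1]), lambda0 = lambda[1],
       lambda1 = lambda[2], qsd = qsd,
       metastability = lambda[1] / (lambda[2] - lambda[1]))
}

# Absorbing subsystem with S given directly (absorbing target = complement,
# which may be empty escape through D only). Used by mixing_time and the
# escape-time machinery, where X is the community.
absorbing_subsystem_nodes <- function(net, X) {
  A <- setdiff(seq_len(net$n), X)
  if (length(A) == 0) stop("X must not cover the whole network (no escape)")
  absorbing_subsystem(net, A)
}

#' Initial distributions for first-passage and escape problems
#'
#' The four standard initializations within a source community X:
#' * `"Boltz"`: local equilibrium, \eqn{\pi} restricted to X, renormalized;
#' * `"Min"`: delta at the maximum-stationary-probability node b0(X);
#' * `"Uni"`: uniform over X;
#' * `"Mix"`: the uniform density evolved under the community subsystem for
#'   one mixing time, \eqn{p_X(\tau_m) = \sum_\ell e^{-\tau_m \lambda_\ell}
#'   w^R_\ell (w^L_\ell \cdot p_X(0))}, then renormalized. The probability
#'   lost to escape during the evolution is discarded by the
#'   renormalization, and downstream distributions are reported shifted by
#'   \eqn{\tau_m} (the `tshift` field).
#'
#' @param kind one of `"Boltz"`, `"Min"`, `"Uni"`, `"Mix"`.
#' @param net a [rate_network()].
#' @param partition a [build_partition()] result.
#' @param community community name (or index into the partition).
#' @param tau_m mixing time for `"Mix"`; by default computed via
#'   [mixing_time()] on the community.
#' @return An object of class `initial_distribution`: list with `kind`,
#'   `p` (full-length vector, supported on the community), `nodes` and
#'   `tshift`.
#' @export
make_initial <- function(kind = c("Boltz", "Min", "Uni", "Mix"),
                         net, partition, community, tau_m = NULL) {
  kind <- match.arg(kind)
  nm <- as.character(community)
  nodes <- partition$communities[[nm]]
  if (is.null(nodes)) stop(sprintf("unknown community '%s'", nm))
  p <- rep(0, net$n)
  tshift <- 0
  if (kind == "Boltz") {
    p[nodes] <- net$pi[nodes] / sum(net$pi[nodes])
  } else if (kind == "Min") {
    p[partition$b0[[nm]]] <- 1
  } else if (kind == "Uni") {
    p[nodes] <- 1 / length(nodes)
  } else {
    if (is.null(tau_m)) tau_m <- mixing_time(net, nodes)$tau_mix
    if (tau_m == 0) {
      p[nodes] <- 1 / length(nodes)
    } else {
      sub <- absorbing_subsystem_nodes(net, nodes)
      u <- rep(1 / length(nodes), length(nodes))
      amp <- exp(-tau_m * sub$lambda) * as.vector(sub$wL %*% u)
      if (any(!is.finite(amp)) || max(abs(amp)) > 1e6)
        stop("ill-conditioned community eigensystem for Mix; use Boltz instead")
      v <- as.vector(sub$wR %*% amp)
      if (min(v) < -1e-10 * max(abs(v)))
        stop("Mix propagation produced negative probabilities (precision loss); use Boltz instead")
      v <- pmax(v, 0)
      p[nodes] <- v / sum(v)
      tshift <- tau_m
    }
  }
  structure(list(kind = kind, p = p, nodes = nodes, tshift = tshift),
            class = "initial_distribution")
}

#' First-escape time distribution from a community
#'
#' Escape from community X is first passage to the complement of X:
#' equivalent to [fpt_distribution()] on the subsystem with `S = X` and
#' everything else absorbing.
#'
#' @param net a [rate_network()].
#' @param partition a [build_partition()] result.
#' @param community community name.
#' @param p0 an `initial_distribution` (or vector); see [make_initial()].
#' @return an `fpt_distribution`.
#' @export
escape_time_distribution <- function(net, partition, community, p0) {
  nodes <- partition$communities[[as.character(community)]]
  if (is.null(nodes)) stop(sprintf("unknown community '%s'", community))
  sub <- absorbing_subsystem_nodes(net, nodes)
  fpt_distribution(sub, p0)
}
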