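# File formats
# ------------
# nodes.tsv : header `id  energy` or `id  log_stat_prob` (tab-separated).
# edges.tsv : header `i  j  rate_ij  rate_ji` where column 3 is the rate
#             i -> j and column 4 the rate j -> i. A "log dialect" uses
#             headers `log_rate_ij  log_rate_ji` and stores natural logs of
#             the rates, which survives magnitudes like exp(-E/T) at low T.
# communities.dat : one community label per line; line n refers to node n
#             of nodes.tsv.
# Node ids in files are arbitrary integer labels (1-based by convention);
# internally nodes are contiguous 1..n in file order and the id mapping is
# kept in `node_ids`.

#' Load a kinetic transition network from node and edge tables
#'
#' Reads the two-file convention described in the package README: a node
#' table with one row per state (column `energy` or `log_stat_prob`) and an
#' edge table with one row per bidirectional edge carrying both directional
#' rates, either linear (`rate_ij`, `rate_ji`) or as natural logs
#' (`log_rate_ij`, `log_rate_ji`).
#'
#' @param node_table path to nodes.tsv.
#' @param edge_table path to edges.tsv.
#' @param temperature temperature used to turn energies into Boltzmann
#'   weights (k_B = 1).
#' @return a [rate_network()]; node energies (or log stationary
#'   probabilities, converted to energies via `E = -T log pi`) are attached.
#' @export
load_network <- function(node_table, edge_table, temperature = 1) {
  nodes <- utils::read.delim(node_table, header = TRUE, sep = "\t",
                             check.names = FALSE)
  edges <- utils::read.delim(edge_table, header = TRUE, sep = "\t",
                             check.names = FALSE)
  if (!"id" %in% names(nodes)) stop("node table must have an 'id' column")
  ids <- nodes$id
  if (anyDuplicated(ids)) stop("duplicate node ids in node table")
  n <- length(ids)
  idx <- seq_len(n); names(idx) <- as.character(ids)

  energies <- NULL
  if ("energy" %in% names(nodes)) {
    energies <- nodes$energy
  } else if ("log_stat_prob" %in% names(nodes)) {
    energies <- -temperature * nodes$log_stat_prob
  }

  logd <- all(c("log_rate_ij", "log_rate_ji") %in% names(edges))
  if (!logd && !all(c("rate_ij", "rate_ji") %in% names(edges)))
    stop("edge table must have columns rate_ij/rate_ji or log_rate_ij/log_rate_ji")
  rij <- if (logd) exp(edges$log_rate_ij) else edges$rate_ij
  rji <- if (logd) exp(edges$log_rate_ji) else edges$rate_ji
  if (!logd && any(c(rij, rji) <= 0))
    stop("non-positive rate in edge table")

  ei <- as.character(edges$i); ej <- as.character(edges$j)
  unknown <- setdiff(c(ei, ej), names(idx))
  if (length(unknown))
    stop(sprintf("edge references undeclared node(s): %s",
                 paste(unknown, collapse = ", ")))
  a <- idx[ei]; b <- idx[ej]
  if (any(a == b)) stop("self-edge in edge table")
  key <- paste(pmin(a, b), pmax(a, b))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate edge between nodes %s and %s",
                 ids[as.integer(strsplit(d, " ")[[1]][1])],
                 ids[as.integer(strsplit(d, " ")[[1]][2])]))
  }
  K <- matrix(0, n, n)
  K[cbind(b, a)] <- rij   # rate i -> j enters K[j, i]
  K[cbind(a, b)] <- rji
  rate_network(K, energies = energies, temperature = temperature,
               node_ids = ids)
}

#' Write a network to node and edge tables
#'
#' Inverse of [load_network()]: rates are printed with 17 significant
#' digits so that a load/write round trip reproduces them exactly. With
#' `dialect = "log"` natural logs of the rates are written instead, which
#' is the recommended form for strongly metastable networks.
#'
#' @param net a [rate_network()].
#' @param node_table,edge_table output paths.
#' @param dialect `"linear"` (default) or `"log"`.
#' @export
write_network <- function(net, node_table, edge_table, dialect = c("linear", "log")) {
  dialect <- match.arg(dialect)
  ids <- net$node_ids
  nd <- if (!is.null(net$energies)) {
    data.frame(id = ids, energy = net$energies)
  } else {
    data.frame(id = ids, log_stat_prob = log(net$pi))
  }
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  nd[[2]] <- fmt(nd[[2]])
  utils::write.table(nd, node_table, sep = "\t", quote = FALSE, row.names = FALSE)

  up <- which(upper.tri(net$K) & (net$K > 0 | t(net$K) > 0), arr.ind = TRUE)
  i <- up[, "row"]; j <- up[, "col"]   # i < j
  rij <- net$K[cbind(j, i)]            # rate i -> j
  rji <- net$K[cbind(i, j)]
  ed <- if (dialect == "log") {
    data.frame(i = ids[i], j = ids[j],
               log_rate_ij = fmt(log(rij)), log_rate_ji = fmt(log(rji)))
  } else {
    data.frame(i = ids[i], j = ids[j],
               rate_ij = fmt(rij), rate_ji = fmt(rji))
  }
  utils::write.table(ed, edge_table, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(net)
}

#' Read a community assignment file
#'
#' One community label per line; line n is the label of the n-th node of
#' the node table the network was loaded from.
#'
#' @param path path to communities.dat.
#' @param net optional [rate_network()]; when given the line count is
#'   checked against `net$n`.
#' @return integer/character vector of labels.
#' @export
read_communities <- function(path, net = NULL) {
  labs <- scan(path, what = character(), quiet = TRUE)
  if (!is.null(net) && length(labs) != net$n)
    stop(sprintf("communities file has %d lines but network has %d nodes",
                 length(labs), net$n))
  suppressWarnings({
    num <- as.integer(labs)
    if (!anyNA(num)) labs <- num
  })
  labs
}

#' @rdname read_communities
#' @param labels label vector to write.
#' @export
write_communities <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(labels)
}

#' Read the three-file stationary-probability/transition-state convention
#'
#' Some energy-landscape codes exchange networks as three plain files:
#' `stat_prob.dat` (one log stationary probability per node per line),
#' `ts_conns.dat` (two node ids per line, one line per bidirectional edge)
#' and `ts_weights.dat` (log transition rates, two lines per edge: first
#' the rate first-id -> second-id, then the reverse). This reader converts
#' that convention into a [rate_network()], taking `E = -T log pi` as the
#' node energy.
#'
#' @param stat_prob,ts_conns,ts_weights file paths.
#' @param temperature temperature (k_B = 1).
#' @return a [rate_network()].
#' @export
read_ktn_files <- function(stat_prob, ts_conns, ts_weights, temperature = 1) {
  lp <- scan(stat_prob, what = double(), quiet = TRUE)
  n <- length(lp)
  conns <- matrix(scan(ts_conns, what = integer(), quiet = TRUE),
                  ncol = 2, byrow = TRUE)
  lw <- scan(ts_weights, what = double(), quiet = TRUE)
  if (length(lw) != 2 * nrow(conns))
    stop("ts_weights must have two lines per edge of ts_conns")
  if (any(conns < 1 | conns > n)) stop("edge references undeclared node")
  K <- matrix(0, n, n)
  for (m in seq_len(nrow(conns))) {
    i <- conns[m, 1]; j <- conns[m, 2]
    K[j, i] <- exp(lw[2 * m - 1])   # i -> j
    K[i, j] <- exp(lw[2 * m])       # j -> i
  }
  rate_network(K, energies = -temperature * lp, temperature = temperature)
}
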