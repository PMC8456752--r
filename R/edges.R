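# Edge-index conventions
#
# The whole package uses ONE edge ordering: nodes are 0-based indices
# 0..V-1 (V = 116 for the AAL parcellation), and the E = V(V-1)/2 unique
# (strict upper-triangle) edges are enumerated row-major:
#   (0,1), (0,2), ..., (0,V-1), (1,2), ..., (V-2,V-1)
# giving 0-based edge ids 0..E-1. Saliency maps, permutation codecs and
# occlusion masks all share this ordering; misalignment between them would
# silently corrupt edge-space saliency, so every conversion goes through
# the functions here.

#' Number of unique edges for a V-node graph
#' @param n_nodes number of nodes (default 116).
#' @return integer V(V-1)/2.
#' @export
n_edges <- function(n_nodes = 116L) {
  as.integer(n_nodes * (n_nodes - 1L) / 2L)
}

#' Edge id of a node pair
#'
#' Maps unordered 0-based node pairs to 0-based edge ids under the
#' row-major upper-triangle convention. Vectorised; `edge_index(i, j)` and
#' `edge_index(j, i)` agree.
#'
#' @param i,j 0-based node indices (vectors, recycled).
#' @param n_nodes number of nodes.
#' @return 0-based edge ids.
#' @export
edge_index <- function(i, j, n_nodes = 116L) {
  stopifnot(all(i >= 0), all(j >= 0), all(i < n_nodes), all(j < n_nodes))
  if (any(i == j)) stop2("self-pairs (i == j) have no edge id")
  lo <- pmin(i, j); hi <- pmax(i, j)
  as.integer(lo * (2 * n_nodes - lo - 1) / 2 + (hi - lo - 1))
}

#' Node pairs of all edges, in edge-id order
#'
#' @param n_nodes number of nodes.
#' @return integer matrix E x 2 of 0-based `(i, j)` with `i < j`; row `e+1`
#'   is edge id `e`.
#' @export
edge_pairs <- function(n_nodes = 116L) {
  i <- rep.int(0:(n_nodes - 2L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(0:(n_nodes - 2L), function(a) (a + 1L):(n_nodes - 1L)),
              use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

# linear (column-major, 1-based) indices of the strict upper triangle of a
# V x V matrix, in edge-id (row-major) order; used to lift edge vectors
# in and out of matrices without loops
edge_linear_index <- function(n_nodes = 116L) {
  p <- edge_pairs(n_nodes)
  p[, "i"] + p[, "j"] * n_nodes + 1L
}

#' Place an edge-ordered vector into a symmetric matrix
#'
#' @param values length-E vector in edge-id order.
#' @param n_nodes number of nodes.
#' @param diag value placed on the diagonal (default 0).
#' @return symmetric `n_nodes x n_nodes` matrix.
#' @export
edges_to_matrix <- function(values, n_nodes = 116L, diag = 0) {
  stopifnot(length(values) == n_edges(n_nodes))
  m <- matrix(diag, n_nodes, n_nodes)
  m[edge_linear_index(n_nodes)] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Extract the edge-ordered vector from a symmetric matrix
#'
#' Inverse of [edges_to_matrix()] (up to the discarded diagonal).
#'
#' @param m square matrix.
#' @return length-E vector in edge-id order.
#' @export
matrix_to_edges <- function(m) {
  v <- nrow(m)
  stopifnot(is.matrix(m), ncol(m) == v)
  m[edge_linear_index(v)]
}

#' A-priori network definition
#'
#' @param name network name (e.g. `"SAL"`).
#' @param nodes 0-based node indices (distinct, within `[0, n_nodes)`).
#' @param labels optional region labels.
#' @param n_nodes parcellation size.
#' @return object of class `network_definition`.
#' @export
network_definition <- function(name, nodes, labels = NULL, n_nodes = 116L) {
  nodes <- as.integer(nodes)
  if (anyDuplicated(nodes)) stop2("network '", name, "': duplicated nodes")
  if (any(nodes < 0 | nodes >= n_nodes))
    stop2("network '", name, "': node indices must lie in [0, ", n_nodes, ")")
  structure(list(name = name, nodes = sort(nodes), labels = labels,
                 n_nodes = as.integer(n_nodes)),
            class = "network_definition")
}

#' @export
print.network_definition <- function(x, ...) {
  cat("<network_definition>", x$name, "-", length(x$nodes), "nodes of",
      x$n_nodes, "\n")
  invisible(x)
}

#' Inner edges of a network
#'
#' Edge ids of all edges with both endpoints inside the network: a 10-node
#' network has 10*9/2 = 45 inner edges.
#'
#' @param net a [network_definition()].
#' @return sorted 0-based edge ids.
#' @export
inner_edges <- function(net) {
  nd <- net$nodes
  if (length(nd) < 2L) return(integer(0))
  cmb <- utils::combn(nd, 2L)
  sort(edge_index(cmb[1L, ], cmb[2L, ], net$n_nodes))
}

#' Connecting edges of a network
#'
#' Edge ids of all edges with at least one endpoint inside the network
#' (inner edges included): a 10-node network in 116 nodes has
#' 10*115 - 45 = 1105 connecting edges.
#'
#' @param net a [network_definition()].
#' @return sorted 0-based edge ids.
#' @export
connecting_edges <- function(net) {
  p <- edge_pairs(net$n_nodes)
  hit <- (p[, "i"] %in% net$nodes) | (p[, "j"] %in% net$nodes)
  which(hit) - 1L
}

#' Fraction of all unique edges covered by an edge set
#'
#' @param edges 0-based edge ids.
#' @param n_nodes parcellation size.
#' @return percentage of the V(V-1)/2 unique edges, rounded to 2 decimals.
#' @export
edge_fraction <- function(edges, n_nodes = 116L) {
  e <- n_edges(n_nodes)
  stopifnot(all(edges >= 0), all(edges < e), !anyDuplicated(edges))
  round(100 * length(edges) / e, 2L)
}

#' AAL-116 parcel labels
#'
#' The bundled 116-region automated-anatomical-labeling lookup
#' (0-based index, region label) that fixes node identity package-wide.
#'
#' @param path optional override TSV (columns `index`, `label`).
#' @return data.frame with columns `index` (0-based) and `label`.
#' @export
aal116_labels <- function(path = NULL) {
  path <- path %||% system.file("extdata", "aal116_labels.tsv",
                                package = "connectoscramble", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("index", "label") %in% names(d)))
  d
}

#' Load a-priori network definitions
#'
#' Reads a YAML mapping of network name to AAL region labels and resolves
#' labels to node indices via the bundled (or user-supplied) label table.
#' The default shipped file defines three 10-node networks: default mode
#' (DMN), central executive (CEN) and salience (SAL).
#'
#' @param path optional YAML override.
#' @param labels optional label table override (see [aal116_labels()]).
#' @return named list of [network_definition()] objects.
#' @export
load_networks <- function(path = NULL, labels = aal116_labels()) {
  path <- path %||% system.file("extdata", "networks.yaml",
                                package = "connectoscramble", mustWork = TRUE)
  if (!file.exists(path)) stop2("networks file not found: ", path)
  y <- yaml::read_yaml(path)
  lapply(stats::setNames(names(y), names(y)), function(nm) {
    regs <- unlist(y[[nm]])
    idx <- labels$index[match(regs, labels$label)]
    if (anyNA(idx))
      stop2("network '", nm, "': unknown region label(s): ",
            paste(regs[is.na(idx)], collapse = ", "))
    network_definition(nm, idx, labels = regs, n_nodes = max(labels$index) + 1L)
  })
}
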