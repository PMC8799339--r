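#' Node degree
#'
#' Number of incident edges per node. Edge confidences are ignored: once the
#' confidence filter has been applied, the PPI is treated as pure topology.
#'
#' @param net An undirected simple `igraph` network.
#' @return Named integer vector, one entry per node (isolated nodes get 0).
#' @export
node_degree <- function(net) {
  check_network(net)
  d <- igraph::degree(net)
  names(d) <- node_names(net)
  d
}

#' Normalized closeness centrality
#'
#' `(m - 1) / sum_u d(v, u)` with unweighted shortest-path distances, so a
#' node adjacent to every other node scores 1. Requires a connected network.
#'
#' @inheritParams node_degree
#' @return Named numeric vector.
#' @export
node_closeness <- function(net) {
  check_network(net, connected = TRUE)
  cl <- igraph::closeness(net, normalized = TRUE, weights = NA)
  names(cl) <- node_names(net)
  cl
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness: the sum over unordered node pairs
#' (s, t), both distinct from v, of the fraction of shortest s-t paths
#' passing through v. Unweighted distances.
#'
#' @inheritParams node_degree
#' @return Named numeric vector.
#' @export
node_betweenness <- function(net) {
  check_network(net, connected = TRUE)
  b <- igraph::betweenness(net, directed = FALSE, weights = NA, normalized = FALSE)
  names(b) <- node_names(net)
  b
}

#' Eccentricity
#'
#' Maximum unweighted shortest-path distance from each node to any other
#' node. Raw values (larger = more peripheral); see [iiem()] for how the
#' orientation of this indicator is handled.
#'
#' @inheritParams node_degree
#' @return Named integer vector.
#' @export
node_eccentricity <- function(net) {
  check_network(net, connected = TRUE)
  d <- igraph::distances(net, weights = NA)
  ecc <- apply(d, 1, max)
  names(ecc) <- node_names(net)
  ecc
}

#' PageRank by power iteration
#'
#' PageRank on the undirected graph's random walk with uniform teleport:
#' `x <- (1 - damping)/m + damping * (P x + dangling mass / m)` iterated until
#' the L1 change drops below `tol`. Scores sum to 1.
#'
#' @inheritParams node_degree
#' @param damping Teleport damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-8.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual, never a silent partial answer.
#' @return Named numeric vector summing to 1.
#' @export
node_pagerank <- function(net, damping = 0.85, tol = 1e-8, max_iter = 200) {
  check_network(net)
  m <- igraph::vcount(net)
  if (m == 0) stop("pagerank of an empty network")
  stopifnot(damping > 0, damping < 1, tol > 0, max_iter >= 1)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  deg <- igraph::degree(net)
  x <- rep(1 / m, m)
  dangling <- deg == 0
  inv_deg <- ifelse(dangling, 0, 1 / deg)
  for (it in seq_len(max_iter)) {
    spread <- as.numeric(A %*% (x * inv_deg))
    x_new <- (1 - damping) / m + damping * (spread + sum(x[dangling]) / m)
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < tol) {
      names(x) <- node_names(net)
      return(x)
    }
  }
  stop(sprintf("pagerank did not converge in %d iterations (L1 residual %.3g)",
               max_iter, delta))
}

#' Centrality indicator matrix
#'
#' Assembles the five raw per-node network indicators used for
#' entropy-weighted importance scoring into an m x 5 matrix: degree,
#' closeness, betweenness, eccentricity, and PageRank, in that fixed column
#' order. Rows are sorted by node label for determinism.
#'
#' @inheritParams node_pagerank
#' @return Numeric matrix with node labels as row names and
#'   `c("degree", "closeness", "betweenness", "eccentricity", "pagerank")`
#'   as column names.
#' @export
indicator_matrix <- function(net, damping = 0.85, tol = 1e-8, max_iter = 200) {
  check_network(net, connected = TRUE)
  if (igraph::vcount(net) < 2) stop("indicator matrix needs at least 2 nodes")
  x <- cbind(
    degree = node_degree(net),
    closeness = node_closeness(net),
    betweenness = node_betweenness(net),
    eccentricity = node_eccentricity(net),
    pagerank = node_pagerank(net, damping = damping, tol = tol, max_iter = max_iter)
  )
  x[order(rownames(x)), , drop = FALSE]
}
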