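#' Enumerate maximal cliques
#'
#' All maximal cliques of size >= 2 (Bron-Kerbosch with pivoting, via
#' igraph). Every returned set is a clique, none is contained in another,
#' and their union covers every edge.
#'
#' @param net An undirected simple `igraph` network.
#' @return List of character vectors of node labels, each sorted; the list
#'   is sorted for determinism.
#' @export
maximal_cliques <- function(net) {
  check_network(net)
  if (igraph::ecount(net) == 0) return(list())
  nm <- node_names(net)
  cl <- igraph::max_cliques(net, min = 2)
  out <- lapply(cl, function(v) sort(nm[as.integer(v)]))
  key <- vapply(out, paste, "", collapse = "\r")
  out[order(lengths(out), key)]
}

#' Maximal Clique Centrality
#'
#' `MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!` -- the
#' hub score popularized by the CytoHubba plugin. A node whose neighborhood
#' contains no internal edges has only its edges as maximal cliques, so its
#' MCC equals its degree; an isolated node scores 0.
#'
#' Scores are held in doubles: they are exact for maximal cliques of up to
#' 19 nodes (`18! < 2^53`); beyond that, relative ranking remains reliable
#' but the integers are no longer exact.
#'
#' @inheritParams maximal_cliques
#' @return Named numeric vector of MCC scores, one per node.
#' @export
mcc_score <- function(net) {
  check_network(net)
  scores <- stats::setNames(numeric(igraph::vcount(net)), node_names(net))
  for (cl in maximal_cliques(net)) {
    scores[cl] <- scores[cl] + factorial(length(cl) - 1)
  }
  scores
}

#' Top-k nodes by score
#'
#' The k highest-scoring nodes, ties broken by label ascending (the ordering
#' is otherwise unspecified in hub-ranking tools; a deterministic rule is
#' needed for reproducible intersections). Isolated nodes (score 0) are
#' excluded from the ranking.
#'
#' @param scores Named numeric vector (e.g. from [mcc_score()]).
#' @param k Number of nodes to return, >= 1. If fewer than k nodes carry a
#'   positive score, all of them are returned with a warning.
#' @return Character vector of node labels in rank order.
#' @export
top_k <- function(scores, k) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (!is.numeric(k) || length(k) != 1 || k < 1) stop("k must be >= 1")
  scores <- scores[scores > 0]
  ord <- names(scores)[order(-scores, names(scores))]
  if (length(ord) < k) {
    warning(sprintf("only %d scored nodes available for top %d", length(ord), k))
    return(ord)
  }
  ord[seq_len(k)]
}
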