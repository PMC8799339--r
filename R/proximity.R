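#' Map a gene set onto a network
#'
#' Intersects a gene set with the node labels of a background network,
#' reporting coverage. Set-to-set distances can only be computed over
#' mapped members.
#'
#' @param set Character vector of gene symbols (normalized via [gene_set()]).
#' @param net Background `igraph` network.
#' @return List with `mapped` (symbols found in the network), `missing`,
#'   and `coverage` (fraction mapped).
#' @export
map_to_network <- function(set, net) {
  set <- gene_set(set)
  nodes <- node_names(net)
  mapped <- intersect(set, nodes)
  list(mapped = mapped,
       missing = setdiff(set, nodes),
       coverage = if (length(set) == 0) 0 else length(mapped) / length(set))
}

#' Shortest-path distances between two node sets
#'
#' Unweighted BFS distances for every source x target pair on the background
#' network. Unreachable pairs are reported as `Inf`.
#'
#' @param net Background `igraph` network.
#' @param sources,targets Character vectors of node labels already present
#'   in the network (see [map_to_network()]).
#' @return Numeric matrix of hop counts with sources as rows and targets as
#'   columns.
#' @export
set_distances <- function(net, sources, targets) {
  check_network(net)
  nodes <- node_names(net)
  if (!all(sources %in% nodes) || !all(targets %in% nodes)) {
    stop("sources/targets must be mapped to network nodes first (map_to_network)")
  }
  if (length(sources) == 0 || length(targets) == 0) {
    stop("no mapped source or target nodes")
  }
  igraph::distances(net, v = sources, to = targets, weights = NA)
}

#' Mean cross-set distance d_AB
#'
#' Arithmetic mean of the shortest-path distance over all `|A| * |B|`
#' ordered pairs (a, b). Pairs where a and b are the same node (possible
#' when the sets overlap) are excluded, so that the self-separation
#' invariant `S_AA = 0` holds; pairs in different connected components
#' (infinite distance) are likewise excluded from both numerator and
#' denominator. The count of finite pairs used is available from [s_ab()]
#' diagnostics.
#'
#' @param net Background `igraph` network.
#' @param A,B Character vectors of mapped node labels.
#' @return Mean hop count (a single number).
#' @export
d_cross <- function(net, A, B) {
  d <- set_distances(net, A, B)
  keep <- is.finite(d) & outer(A, B, "!=")
  if (identical(sort(A), sort(B)) && !any(keep)) return(0)
  fin <- d[keep]
  if (length(fin) == 0) stop("no finite-distance pairs between the two sets")
  mean(fin)
}

#' Mean within-set distance d_AA
#'
#' Average distance between the members of one set. The default
#' (`method = "allpairs"`) is the mean over all unordered distinct pairs,
#' mirroring the all-pairs form of the cross-set distance; singleton and
#' empty sets return 0 by convention. `method = "closest"` instead averages,
#' over each member, the distance to its nearest other member -- the
#' convention used by the separation measure in the network-medicine
#' literature.
#'
#' @param net Background `igraph` network.
#' @param A Character vector of mapped node labels.
#' @param method `"allpairs"` (default) or `"closest"`.
#' @return Mean hop count.
#' @export
d_within <- function(net, A, method = c("allpairs", "closest")) {
  method <- match.arg(method)
  if (length(A) < 2) return(0)
  d <- set_distances(net, A, A)
  if (method == "allpairs") {
    vals <- d[upper.tri(d)]
    fin <- vals[is.finite(vals)]
    if (length(fin) == 0) stop("no finite within-set pairs")
    mean(fin)
  } else {
    diag(d) <- Inf
    nn <- apply(d, 1, min)
    fin <- nn[is.finite(nn)]
    if (length(fin) == 0) stop("no finite within-set pairs")
    mean(fin)
  }
}

#' Network-proximity separation score S_AB
#'
#' Separation of a component's target set A from the key gene set B on a
#' background interactome:
#' `S_AB = d_AB - (d_AA + d_BB) / 2`,
#' where `d_AB` is the all-pairs mean cross-set distance and `d_AA`, `d_BB`
#' are mean within-set distances (see [d_within()] for the two conventions).
#' `S_AB < 0` means the two sets are closer to each other than internally --
#' the component is called a (potential) regulator of the key set;
#' `S_AB >= 0` means the sets are topologically separated.
#'
#' @param net Background `igraph` network.
#' @param A Component target set (gene symbols; mapped internally).
#' @param B Key gene set.
#' @param component_id Optional identifier carried into the result.
#' @param within Within-set distance convention, `"allpairs"` (default) or
#'   `"closest"`.
#' @return An object of class `proximity_result`: a list with
#'   `component_id`, `d_AB`, `d_AA`, `d_BB`, `S_AB`, `n_A_mapped`,
#'   `n_B_mapped`, `n_pairs_finite`, and `call`
#'   (`"regulator"` or `"separated"`).
#' @export
s_ab <- function(net, A, B, component_id = NA_character_,
                 within = c("allpairs", "closest")) {
  within <- match.arg(within)
  check_network(net)
  mA <- map_to_network(A, net)
  mB <- map_to_network(B, net)
  if (length(mA$mapped) == 0) stop("no component targets map to the network")
  if (length(mB$mapped) == 0) stop("no key genes map to the network")
  dmat <- set_distances(net, mA$mapped, mB$mapped)
  keep <- is.finite(dmat) & outer(mA$mapped, mB$mapped, "!=")
  if (setequal(mA$mapped, mB$mapped) && !any(keep)) {
    fin <- 0
  } else {
    fin <- dmat[keep]
    if (length(fin) == 0) stop("no finite-distance pairs between the two sets")
  }
  dAB <- mean(fin)
  dAA <- d_within(net, mA$mapped, method = within)
  dBB <- d_within(net, mB$mapped, method = within)
  S <- dAB - (dAA + dBB) / 2
  structure(
    list(component_id = component_id,
         d_AB = dAB, d_AA = dAA, d_BB = dBB, S_AB = S,
         n_A_mapped = length(mA$mapped), n_B_mapped = length(mB$mapped),
         n_pairs_finite = length(fin),
         call = if (S < 0) "regulator" else "separated"),
    class = "proximity_result"
  )
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("S_AB = %.4f (d_AB %.3f, d_AA %.3f, d_BB %.3f) -> %s\n",
              x$S_AB, x$d_AB, x$d_AA, x$d_BB, x$call))
  invisible(x)
}

#' @export
as.data.frame.proximity_result <- function(x, ...) {
  data.frame(component_id = x$component_id, d_AB = x$d_AB, d_AA = x$d_AA,
             d_BB = x$d_BB, S_AB = x$S_AB, n_A_mapped = x$n_A_mapped,
             n_B_mapped = x$n_B_mapped, n_pairs_finite = x$n_pairs_finite,
             call = x$call, stringsAsFactors = FALSE)
}

#' Proximity of every component to the key gene set
#'
#' Computes [s_ab()] for each component in a component-target map.
#' Components none of whose targets map onto the background network are
#' skipped with a warning. Results are sorted by `S_AB` ascending, so the
#' most proximal (most strongly regulating) components come first.
#'
#' @param net Background `igraph` network.
#' @param map Named list of component target sets
#'   (see [read_component_map()]).
#' @param B Key gene set.
#' @param within Within-set distance convention passed to [s_ab()].
#' @return `data.frame` with one row per scored component (columns as in
#'   [as.data.frame.proximity_result()]).
#' @export
batch_proximity <- function(net, map, B, within = c("allpairs", "closest")) {
  within <- match.arg(within)
  stopifnot(is.list(map), !is.null(names(map)))
  mB <- map_to_network(B, net)
  if (length(mB$mapped) == 0) stop("key gene set does not map to the network")
  rows <- list()
  for (id in names(map)) {
    mA <- map_to_network(map[[id]], net)
    if (length(mA$mapped) == 0) {
      warning(sprintf("component %s: no targets map to the network; skipped", id))
      next
    }
    rows[[id]] <- as.data.frame(s_ab(net, mA$mapped, mB$mapped,
                                     component_id = id, within = within))
  }
  if (length(rows) == 0) stop("no component could be scored")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$S_AB, out$component_id), , drop = FALSE]
}
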