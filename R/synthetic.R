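# Synthetic benchmark instances with known ground truth. Labels are
# synthetic ("G000001", ...) on purpose: no real gene symbols, so generated
# instances carry no implied biological claims.

# Run code under a temporary RNG state so generators are pure functions of
# (parameters, seed) and never disturb the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

node_labels <- function(n, offset = 0) sprintf("G%06d", offset + seq_len(n))

#' Generate a random background network
#'
#' Scale-free (Barabasi-Albert preferential attachment) or Erdos-Renyi
#' G(n, p) graphs with synthetic node labels and edge confidences drawn
#' Uniform(0.4, 1.0), so that confidence-threshold filtering can be
#' exercised. Only the largest connected component is returned; the draw is
#' repeated (deterministically) until it retains at least 90% of the
#' requested nodes.
#'
#' @param n_nodes Number of nodes to generate, >= 3.
#' @param model `"scale_free"` (default) or `"erdos_renyi"`.
#' @param param Edges attached per new node (scale-free, default 2) or edge
#'   probability (Erdos-Renyi).
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @return An undirected simple `igraph` network with `weight` edge
#'   confidences.
#' @export
gen_network <- function(n_nodes, model = c("scale_free", "erdos_renyi"),
                        param = 2, seed = 1) {
  model <- match.arg(model)
  if (!is.numeric(n_nodes) || n_nodes < 3) stop("n_nodes must be >= 3")
  if (model == "scale_free" && (param < 1 || param != round(param))) {
    stop("scale_free attachment parameter must be a positive integer")
  }
  if (model == "erdos_renyi" && (param <= 0 || param > 1)) {
    stop("erdos_renyi edge probability must lie in (0, 1]")
  }
  with_seed(seed, {
    for (attempt in 1:25) {
      g <- switch(model,
        scale_free = igraph::sample_pa(n_nodes, m = param, directed = FALSE),
        erdos_renyi = igraph::sample_gnp(n_nodes, p = param)
      )
      igraph::V(g)$name <- node_labels(n_nodes)
      g <- igraph::simplify(g)
      if (igraph::ecount(g) > 0) {
        igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.4, 1.0)
      }
      if (igraph::vcount(g) == 0) next
      lcc <- largest_component(g)
      if (igraph::vcount(lcc) >= 0.9 * n_nodes) return(lcc)
    }
    stop("could not generate a network whose largest component covers 90% of nodes; increase param")
  })
}

#' Generate a planted-hub network
#'
#' A benchmark graph with known ground-truth hubs: `n_hubs` nodes forming a
#' clique (a densely interconnected module), plus `n_periphery` nodes each
#' attached to `periphery_attach` randomly chosen hubs. The hubs dominate
#' every centrality indicator by construction, so key-target discovery
#' should recover exactly them.
#'
#' @param n_hubs Number of planted hub nodes (default 10).
#' @param n_periphery Number of peripheral nodes (default 190).
#' @param periphery_attach Hubs each peripheral node attaches to
#'   (default 2).
#' @param seed Integer seed.
#' @return List with `network` (an `igraph`; all edge confidences 1.0) and
#'   `hubs` (the planted hub labels).
#' @export
gen_hub_network <- function(n_hubs = 10, n_periphery = 190,
                            periphery_attach = 2, seed = 1) {
  stopifnot(n_hubs >= 2, n_periphery >= 1,
            periphery_attach >= 1, periphery_attach <= n_hubs)
  hubs <- node_labels(n_hubs)
  periph <- node_labels(n_periphery, offset = n_hubs)
  with_seed(seed, {
    hub_edges <- t(utils::combn(hubs, 2))
    per_edges <- do.call(rbind, lapply(periph, function(p) {
      cbind(p, sample(hubs, periphery_attach))
    }))
    el <- rbind(hub_edges, per_edges)
    g <- igraph::graph_from_data_frame(
      data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
      directed = FALSE, vertices = c(hubs, periph)
    )
    igraph::E(g)$weight <- 1.0
    list(network = g, hubs = hubs)
  })
}

#' Generate database-like gene sets with controlled overlap
#'
#' Emulates querying three disease-gene databases: three sets drawn from a
#' common universe whose pairwise Jaccard overlap is controlled by a shared
#' core. The realized pairwise Jaccard index lands within about 0.1 of the
#' request (rounding aside).
#'
#' @param universe Character vector of available symbols.
#' @param sizes Integer vector of 3 set sizes.
#' @param overlap Requested pairwise Jaccard overlap in \[0, 1\].
#' @param seed Integer seed.
#' @return List of 3 gene sets.
#' @export
gen_db_sets <- function(universe, sizes, overlap, seed = 1) {
  stopifnot(length(sizes) == 3, all(sizes >= 1),
            overlap >= 0, overlap <= 1)
  universe <- gene_set(universe)
  core_sizes <- vapply(utils::combn(sizes, 2, simplify = FALSE),
                       function(p) overlap * sum(p) / (1 + overlap), 0)
  core <- round(mean(core_sizes))
  if (core > min(sizes)) {
    stop(sprintf("infeasible overlap %.2f for sizes %s: shared core %d exceeds the smallest set",
                 overlap, paste(sizes, collapse = "/"), core))
  }
  need <- core + sum(sizes - core)
  if (need > length(universe)) {
    stop(sprintf("infeasible: need %d distinct symbols, universe has %d",
                 need, length(universe)))
  }
  with_seed(seed, {
    pool <- sample(universe)
    shared <- pool[seq_len(core)]
    pool <- pool[-seq_len(core)]
    sets <- vector("list", 3)
    for (k in 1:3) {
      extra <- sizes[k] - core
      sets[[k]] <- gene_set(c(shared, pool[seq_len(extra)]),
                            label = sprintf("db%d", k))
      if (extra > 0) pool <- pool[-seq_len(extra)]
    }
    sets
  })
}

#' Generate a component-target map with known classes
#'
#' Builds drug-component target sets at controlled graph distance from a
#' key gene set, with ground-truth labels:
#' * `proximal` -- targets sampled from the closed 1-neighborhood of the
#'   key set, excluding key genes themselves;
#' * `distal` -- targets sampled from nodes at distance >= 3 from every key
#'   gene;
#' * `direct` -- components containing at least one key gene, the rest of
#'   their targets proximal.
#'
#' Each generated component is re-validated against the network's
#' shortest-path distances before being returned.
#'
#' @param net Background `igraph` network.
#' @param key_set Key gene labels (must map onto the network).
#' @param n_proximal,n_distal,n_direct Component counts per class.
#' @param targets_per_component Targets per component (default 5).
#' @param seed Integer seed.
#' @return List with `map` (named list of target sets) and `truth`
#'   (`data.frame` of `component_id`, `class`).
#' @export
gen_components <- function(net, key_set, n_proximal, n_distal, n_direct = 0,
                           targets_per_component = 5, seed = 1) {
  check_network(net)
  key <- gene_set(key_set)
  nodes <- node_names(net)
  if (!all(key %in% nodes)) stop("key_set must map onto the network")
  stopifnot(n_proximal >= 0, n_distal >= 0, n_direct >= 0,
            targets_per_component >= 1)
  dmat <- igraph::distances(net, to = key, weights = NA)
  mind <- apply(dmat, 1, min)
  prox_pool <- setdiff(names(mind)[mind == 1], key)
  distal_pool <- names(mind)[mind >= 3]
  tpc <- targets_per_component
  if ((n_proximal > 0 || n_direct > 0) && length(prox_pool) < tpc) {
    stop(sprintf("insufficient proximal nodes: pool %d, need %d per component",
                 length(prox_pool), tpc))
  }
  if (n_distal > 0 && length(distal_pool) < tpc) {
    stop(sprintf("insufficient distal nodes (distance >= 3): pool %d, need %d per component (achievable maximum %d targets)",
                 length(distal_pool), tpc, length(distal_pool)))
  }
  with_seed(seed, {
    map <- list()
    truth <- data.frame(component_id = character(0), class = character(0),
                        stringsAsFactors = FALSE)
    add <- function(id, targets, cls) {
      map[[id]] <<- gene_set(targets)
      truth <<- rbind(truth, data.frame(component_id = id, class = cls,
                                        stringsAsFactors = FALSE))
    }
    k <- 0
    for (i in seq_len(n_proximal)) {
      k <- k + 1
      add(sprintf("C%03d", k), sample(prox_pool, tpc), "proximal")
    }
    for (i in seq_len(n_distal)) {
      k <- k + 1
      add(sprintf("C%03d", k), sample(distal_pool, tpc), "distal")
    }
    for (i in seq_len(n_direct)) {
      k <- k + 1
      add(sprintf("C%03d", k),
          c(sample(key, 1), sample(prox_pool, tpc - 1)), "direct")
    }
    # generation-time validation against the distance matrix
    for (i in seq_len(nrow(truth))) {
      id <- truth$component_id[i]
      tg <- map[[id]]
      ok <- switch(truth$class[i],
        proximal = all(mind[tg] == 1),
        distal = all(mind[tg] >= 3),
        direct = any(tg %in% key)
      )
      if (!ok) stop("internal error: generated component violates its truth class")
    }
    list(map = map, truth = truth)
  })
}

#' Generate a complete synthetic study instance
#'
#' One seeded object carrying everything the pipeline consumes, with known
#' ground truth throughout:
#' a scale-free background graph with a planted high-centrality key-gene
#' module (a clique of `n_hubs` nodes wired into the background through
#' `n_bridges` bridge nodes, each bridge contacting a Binomial share
#' `bridge_attach` of the module -- emulating pathway/complex
#' co-membership), three database-like gene sets with controlled overlap,
#' and a component-target map with `proximal` / `distal` / `direct` truth
#' labels relative to the planted module.
#'
#' @param seed Integer seed (the instance is a pure function of it and the
#'   parameters).
#' @param n_nodes Total node count (default 200).
#' @param n_hubs Planted module size (default 10).
#' @param n_bridges Bridge nodes linking module to background (default 40).
#' @param bridge_attach Probability a bridge contacts each module member
#'   (default 0.7).
#' @param attach Preferential-attachment edges per background node
#'   (default 2).
#' @param n_proximal,n_distal,n_direct Component counts (defaults 20/20/0).
#' @param targets_per_component Targets per component (default 5).
#' @param db_sizes,db_overlap Database-set sizes and pairwise Jaccard
#'   overlap (defaults 80/100/60 at 0.3).
#' @return An object of class `synthetic_instance`: a list with `network`,
#'   `planted_hubs`, `key_set` (identical to the planted module here),
#'   `db_sets`, `components` (the map), `truth`, and `seed`.
#' @export
gen_instance <- function(seed = 1, n_nodes = 200, n_hubs = 10,
                         n_bridges = 40, bridge_attach = 0.7, attach = 2,
                         n_proximal = 20, n_distal = 20, n_direct = 0,
                         targets_per_component = 5,
                         db_sizes = c(80, 100, 60), db_overlap = 0.3) {
  stopifnot(n_hubs >= 2, n_bridges >= 1, n_nodes > n_hubs + n_bridges,
            bridge_attach > 0, bridge_attach <= 1)
  n_bg <- n_nodes - n_hubs
  hubs <- node_labels(n_hubs, offset = n_bg)
  net <- with_seed(seed, {
    g0 <- igraph::sample_pa(n_bg, m = attach, directed = FALSE)
    igraph::V(g0)$name <- node_labels(n_bg)
    g0 <- igraph::simplify(g0)
    bridges <- sample(igraph::V(g0)$name, n_bridges,
                      prob = igraph::degree(g0))
    g <- igraph::add_vertices(g0, n_hubs, name = hubs)
    hub_edges <- t(utils::combn(hubs, 2))
    bridge_edges <- do.call(rbind, lapply(bridges, function(b) {
      k <- 0
      while (k == 0) k <- stats::rbinom(1, n_hubs, bridge_attach)
      cbind(b, sample(hubs, k))
    }))
    el <- rbind(hub_edges, bridge_edges)
    g <- igraph::add_edges(g, as.vector(t(el)))
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.4, 1.0)
    g
  })
  db <- gen_db_sets(node_names(net), sizes = db_sizes, overlap = db_overlap,
                    seed = seed + 1)
  comps <- gen_components(net, hubs, n_proximal = n_proximal,
                          n_distal = n_distal, n_direct = n_direct,
                          targets_per_component = targets_per_component,
                          seed = seed + 2)
  structure(
    list(network = net, planted_hubs = hubs, key_set = hubs,
         db_sets = db, components = comps$map, truth = comps$truth,
         seed = seed),
    class = "synthetic_instance"
  )
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf("Synthetic instance (seed %d): %d nodes, %d edges, %d planted hubs\n",
              x$seed, igraph::vcount(x$network), igraph::ecount(x$network),
              length(x$planted_hubs)))
  cat(sprintf("  components: %s\n",
              paste(sprintf("%d %s", table(x$truth$class),
                            names(table(x$truth$class))), collapse = ", ")))
  invisible(x)
}
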