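#' Read a STRING-style weighted edge list
#'
#' Parses a tab-separated edge list (`node1<TAB>node2[<TAB>score]`) into an
#' undirected simple [igraph][igraph::graph] network. Edges whose confidence
#' score falls below `score_threshold` are discarded, mirroring the STRING
#' combined-score cutoff conventionally applied before PPI analysis
#' (0.7 = "high confidence"). Self-loops are dropped; duplicate unordered
#' pairs are collapsed keeping the maximum score. Node symbols are uppercased.
#'
#' @param path Path to a TSV file with 2 or 3 columns. A missing third column
#'   defaults every edge score to 1.0.
#' @param score_threshold Confidence cutoff in \[0,1\]; default 0.7.
#' @param inclusive If `TRUE` (default) edges with score equal to the
#'   threshold are kept (`score >= threshold`); if `FALSE`, strictly greater.
#' @return An undirected simple `igraph` object with a `weight` edge
#'   attribute holding the confidence scores. An empty file yields an empty
#'   graph.
#' @seealso [read_sif()], [write_edge_list()], [largest_component()]
#' @export
read_edge_list <- function(path, score_threshold = 0.7, inclusive = TRUE) {
  stopifnot(is.character(path), length(path) == 1)
  if (!is.numeric(score_threshold) || score_threshold < 0 || score_threshold > 1) {
    stop("score_threshold must be a number in [0, 1]")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    return(empty_network())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  bad <- which(ncol < 2 | ncol > 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed edge-list line %d: expected 2 or 3 tab-separated fields, got %d",
                 bad[1], ncol[bad[1]]))
  }
  a <- toupper(trimws(vapply(parts, `[[`, "", 1)))
  b <- toupper(trimws(vapply(parts, `[[`, "", 2)))
  w <- rep(1.0, length(parts))
  has3 <- ncol == 3
  if (any(has3)) {
    raw <- vapply(parts[has3], `[[`, "", 3)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      stop(sprintf("malformed edge-list line %d: score '%s' is not numeric",
                   which(has3)[which(is.na(val))[1]], raw[which(is.na(val))[1]]))
    }
    w[has3] <- val
  }
  out_of_range <- which(w < 0 | w > 1)
  if (length(out_of_range) > 0) {
    stop(sprintf("edge-list line %d: score %g outside [0, 1]",
                 out_of_range[1], w[out_of_range[1]]))
  }
  build_network(a, b, w, score_threshold, inclusive)
}

#' Read a network in SIF format
#'
#' Reads a simple interaction format file (`node1 <interaction> node2`,
#' whitespace-separated). All edges receive confidence 1.0; the interaction
#' type is discarded. SIF input is read-only: networks are written back as
#' TSV edge lists only.
#'
#' @inheritParams read_edge_list
#' @return An undirected simple `igraph` object.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(empty_network())
  parts <- strsplit(trimws(lines), "\\s+")
  ncol <- lengths(parts)
  bad <- which(ncol != 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed SIF line %d: expected 'node1 interaction node2'", bad[1]))
  }
  a <- toupper(vapply(parts, `[[`, "", 1))
  b <- toupper(vapply(parts, `[[`, "", 3))
  build_network(a, b, rep(1.0, length(a)), score_threshold = 0, inclusive = TRUE)
}

# Shared assembly: threshold filter, self-loop drop, max-score dedupe.
build_network <- function(a, b, w, score_threshold, inclusive) {
  keep <- if (inclusive) w >= score_threshold else w > score_threshold
  keep <- keep & (a != b)
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  if (length(a) == 0) return(empty_network())
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  wmax <- tapply(w, key, max)
  pairs <- do.call(rbind, strsplit(names(wmax), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2], weight = as.numeric(wmax),
               stringsAsFactors = FALSE),
    directed = FALSE
  )
  g
}

empty_network <- function() {
  igraph::make_empty_graph(0, directed = FALSE)
}

#' Write a network as a TSV edge list
#'
#' Writes `node1<TAB>node2<TAB>score` rows (endpoints sorted within each row,
#' rows sorted lexicographically) so that write-then-read round trips are
#' byte-stable and edge-set preserving.
#'
#' @param net An undirected `igraph` network.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(igraph::is_igraph(net))
  el <- igraph::as_edgelist(net)
  w <- if ("weight" %in% igraph::edge_attr_names(net)) {
    igraph::E(net)$weight
  } else {
    rep(1.0, nrow(el))
  }
  if (nrow(el) > 0) {
    lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
    ord <- order(lo, hi)
    lines <- sprintf("%s\t%s\t%s", lo[ord], hi[ord],
                     formatC(w[ord], format = "g", digits = 15))
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a normalized gene set
#'
#' Gene symbols are trimmed, uppercased, and deduplicated, so that set
#' operations across databases with inconsistent casing behave correctly.
#'
#' @param x Character vector of gene symbols.
#' @param label Optional set label (e.g. the source database).
#' @return Sorted character vector of unique uppercase symbols, with a
#'   `label` attribute when one is supplied.
#' @export
gene_set <- function(x, label = NULL) {
  stopifnot(is.character(x))
  x <- toupper(trimws(x))
  x <- sort(unique(x[nzchar(x)]))
  if (!is.null(label)) attr(x, "label") <- label
  x
}

#' Read a gene set from a plain-text file
#'
#' One symbol per line; blank lines and `#` comments are ignored; symbols
#' are case-normalized and deduplicated via [gene_set()].
#'
#' @param path Path to the file.
#' @param label Optional set label; defaults to the file name.
#' @return A normalized gene-set character vector.
#' @export
read_gene_set <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  out <- gene_set(lines, label = label)
  if (length(out) == 0) stop("empty gene set: ", path)
  out
}

#' Read a component-to-target map
#'
#' Reads a two-column TSV (`component_id<TAB>target_symbol`, one row per
#' pair) describing which protein targets each drug component acts on.
#'
#' @param path Path to the TSV file.
#' @return A named list of gene sets, one per component id.
#' @export
read_component_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop("empty component map: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop(sprintf("malformed component-map line %d: expected 2 tab-separated fields", bad[1]))
  }
  comp <- trimws(vapply(parts, `[[`, "", 1))
  tgt <- vapply(parts, `[[`, "", 2)
  sets <- lapply(split(tgt, comp), gene_set)
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    stop("component with no valid targets: ", empty[1])
  }
  sets[order(names(sets))]
}

#' Write a component-to-target map
#'
#' @param map Named list of gene sets (component id -> targets).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_component_map <- function(map, path) {
  stopifnot(is.list(map), !is.null(names(map)))
  rows <- unlist(lapply(names(map), function(id) {
    sprintf("%s\t%s", id, map[[id]])
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Extract the largest connected component
#'
#' Centrality indicators such as closeness and eccentricity are only finite
#' on connected graphs, so analyses run on the largest connected component.
#' Size ties are broken in favour of the component containing the
#' lexicographically smallest node label, for determinism.
#'
#' @param net A non-empty undirected `igraph` network.
#' @return The induced subgraph on the largest connected component.
#' @export
largest_component <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0) stop("empty network")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    nm <- igraph::V(net)$name
    mins <- vapply(best, function(k) min(nm[comp$membership == k]), "")
    best <- best[mins == min(mins)][1]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

# Internal: assert an igraph is an undirected simple network.
check_network <- function(net, connected = FALSE) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::is_directed(net)) stop("network must be undirected")
  if (igraph::any_loop(net) || igraph::any_multiple(net)) {
    stop("network must be simple (no self-loops or duplicate edges)")
  }
  if (connected && igraph::vcount(net) > 0 && !igraph::is_connected(net)) {
    stop("network is disconnected; apply largest_component() first")
  }
  invisible(net)
}

# Internal: node names, or positional labels for unnamed graphs.
node_names <- function(net) {
  nm <- igraph::V(net)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(net))) else nm
}
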