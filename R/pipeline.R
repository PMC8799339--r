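#' Pipeline configuration
#'
#' Collects every tunable parameter of the key-target discovery and
#' proximity pipeline with its default:
#' edge-confidence cutoff 0.7 (STRING "high confidence"), importance
#' threshold `Z >= 0.4`, MCC top-50 hub list, entropy smoothing
#' `epsilon = 1e-4`, PageRank damping 0.85 with L1 tolerance 1e-8 and at
#' most 200 iterations, and the all-pairs within-set distance convention.
#'
#' @param score_threshold Edge-confidence cutoff in \[0, 1\].
#' @param inclusive Keep edges whose score equals the cutoff.
#' @param z_threshold Importance-score selection cutoff.
#' @param mcc_top_k Size of the MCC hub list.
#' @param epsilon Entropy smoothing constant.
#' @param damping,pr_tol,pr_max_iter PageRank parameters.
#' @param within Within-set distance convention, `"allpairs"` or
#'   `"closest"`.
#' @param sqrt_form Use the square-root importance form.
#' @param invert Indicator columns standardized as cost-type.
#' @param seed Optional integer seed recorded for provenance.
#' @return A validated list of class `netkey_config`.
#' @export
netkey_config <- function(score_threshold = 0.7, inclusive = TRUE,
                          z_threshold = 0.4, mcc_top_k = 50,
                          epsilon = 1e-4, damping = 0.85, pr_tol = 1e-8,
                          pr_max_iter = 200,
                          within = c("allpairs", "closest"),
                          sqrt_form = TRUE, invert = character(0),
                          seed = NULL) {
  within <- match.arg(within)
  stopifnot(score_threshold >= 0, score_threshold <= 1,
            z_threshold >= 0, z_threshold <= 1,
            mcc_top_k >= 1, epsilon > 0,
            damping > 0, damping < 1, pr_tol > 0, pr_max_iter >= 1,
            is.logical(inclusive), is.logical(sqrt_form))
  structure(
    list(score_threshold = score_threshold, inclusive = inclusive,
         z_threshold = z_threshold, mcc_top_k = as.integer(mcc_top_k),
         epsilon = epsilon, damping = damping, pr_tol = pr_tol,
         pr_max_iter = as.integer(pr_max_iter), within = within,
         sqrt_form = sqrt_form, invert = invert, seed = seed),
    class = "netkey_config"
  )
}

#' Read / write a pipeline configuration
#'
#' Flat-key YAML serialization of [netkey_config()]; configurations
#' round-trip unchanged.
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `netkey_config`; `write_config()`
#'   invisibly returns `path`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[!vapply(vals, is.null, TRUE)]
  if (!is.null(vals$invert)) vals$invert <- as.character(vals$invert)
  do.call(netkey_config, vals)
}

#' @rdname read_config
#' @param config A `netkey_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "netkey_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Union of gene sets
#'
#' Deduplicated, case-normalized union of any number of gene sets (the
#' "merge and remove duplicates" step of disease gene-set assembly).
#'
#' @param sets List of character vectors of gene symbols.
#' @return A normalized gene-set character vector.
#' @export
merge_union <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  gene_set(unlist(sets, use.names = FALSE))
}

#' Assemble a disease gene set by database-overlap voting
#'
#' Keeps genes present in at least `min_databases` of the input sets -- the
#' "overlapping in two or more databases" rule used when merging
#' disease-gene databases of varying reliability. `min_databases = 1` is the
#' plain union.
#'
#' @param db_sets List of >= `min_databases` gene sets (one per database).
#' @param min_databases Minimum number of sets a gene must appear in.
#' @return A normalized gene-set character vector.
#' @export
assemble_disease_set <- function(db_sets, min_databases = 2) {
  stopifnot(is.list(db_sets), min_databases >= 1)
  if (length(db_sets) < min_databases) {
    stop("fewer input sets than min_databases")
  }
  norm <- lapply(db_sets, gene_set)
  counts <- table(unlist(norm, use.names = FALSE))
  gene_set(names(counts)[counts >= min_databases])
}

#' Discover key targets by intersecting two screens
#'
#' The full key-target discovery chain on a confidence-filtered PPI
#' network: restrict to the largest connected component, build the
#' five-indicator centrality matrix, score nodes with the entropy-weighted
#' importance chain and keep those with `Z >=` the threshold, independently
#' rank hubs by Maximal Clique Centrality and keep the top k, and intersect
#' the two screens into the key-target set.
#'
#' @param net Confidence-filtered undirected `igraph` network.
#' @param config A [netkey_config()]; defaults apply if omitted.
#' @return An object of class `key_target_report`: a list with `key_targets`
#'   (the intersection), `iiem_selected`, `mcc_selected`, `scores` (a
#'   per-node data.frame of Z and MCC), `iiem` (the full [iiem()] result),
#'   `coverage` (fraction of input nodes retained in the largest
#'   component), and `config`.
#' @export
discover_key_targets <- function(net, config = netkey_config()) {
  stopifnot(inherits(config, "netkey_config"))
  check_network(net)
  if (igraph::vcount(net) == 0) stop("empty network")
  lcc <- largest_component(net)
  coverage <- igraph::vcount(lcc) / igraph::vcount(net)
  x <- indicator_matrix(lcc, damping = config$damping, tol = config$pr_tol,
                        max_iter = config$pr_max_iter)
  # a fully symmetric (vertex-transitive) graph leaves every indicator
  # constant: no node is distinguishable, so all importances are 0
  fit <- tryCatch(
    iiem(x, epsilon = config$epsilon, sqrt_form = config$sqrt_form,
         invert = config$invert),
    error = function(e) {
      if (!grepl("uninformative", conditionMessage(e))) stop(e)
      warning("all indicators are constant across nodes; importance scores are all 0")
      n <- ncol(x)
      structure(
        list(y = x * 0, H = stats::setNames(rep(1, n), colnames(x)),
             omega = stats::setNames(rep(1 / n, n), colnames(x)),
             Z = stats::setNames(rep(0, nrow(x)), rownames(x)),
             epsilon = config$epsilon, f = rep(0, n),
             sqrt_form = config$sqrt_form),
        class = "iiem")
    })
  iiem_sel <- select_by_z(fit$Z, threshold = config$z_threshold)
  mcc <- mcc_score(lcc)
  mcc_sel <- top_k(mcc, config$mcc_top_k)
  key <- intersect(iiem_sel, mcc_sel)
  if (length(key) == 0) {
    warning("IIEM and MCC screens have an empty intersection")
  }
  ids <- rownames(x)
  scores <- data.frame(node = ids, Z = unname(fit$Z[ids]),
                       mcc = unname(mcc[ids]),
                       iiem_selected = ids %in% iiem_sel,
                       mcc_selected = ids %in% mcc_sel,
                       stringsAsFactors = FALSE)
  scores <- scores[order(-scores$Z, scores$node), ]
  rownames(scores) <- NULL
  structure(
    list(key_targets = gene_set(key),
         iiem_selected = iiem_sel, mcc_selected = mcc_sel,
         scores = scores, iiem = fit, coverage = coverage, config = config),
    class = "key_target_report"
  )
}

#' @export
print.key_target_report <- function(x, ...) {
  cat(sprintf("Key-target report: %d nodes analyzed (%.0f%% of input in largest component)\n",
              nrow(x$scores), 100 * x$coverage))
  cat(sprintf("  importance screen (Z >= %.2f): %d nodes\n",
              x$config$z_threshold, length(x$iiem_selected)))
  cat(sprintf("  MCC screen (top %d):           %d nodes\n",
              x$config$mcc_top_k, length(x$mcc_selected)))
  cat(sprintf("  key targets (intersection):   %d nodes\n", length(x$key_targets)))
  if (length(x$key_targets) > 0) {
    cat("  ", paste(x$key_targets, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify drug components against the key-target set
#'
#' For each component: does it hit any directly-acting target
#' (`direct_actor`), does it hit a key target outright (`direct_key_hit`),
#' and is its target set proximal to the key set (`S_AB < 0`)? The derived
#' `class` is `"direct"` when a key target is hit outright,
#' `"indirect_regulator"` when `S_AB < 0` without a direct key-target hit,
#' and `"separated"` otherwise.
#'
#' @param net Background `igraph` network.
#' @param map Named list of component target sets.
#' @param key Key gene set.
#' @param direct_targets Optional set of directly-acting targets (e.g. the
#'   experimentally supported target list); `NULL` disables the
#'   `direct_actor` column.
#' @param within Within-set distance convention passed to [s_ab()].
#' @return `data.frame` with one row per scored component, merging the
#'   [batch_proximity()] columns with the overlap flags and `class`.
#' @export
classify_components <- function(net, map, key, direct_targets = NULL,
                                within = c("allpairs", "closest")) {
  within <- match.arg(within)
  key <- gene_set(key)
  if (length(key) == 0) stop("key gene set is empty")
  prox <- batch_proximity(net, map, key, within = within)
  prox$direct_key_hit <- vapply(prox$component_id, function(id) {
    length(intersect(gene_set(map[[id]]), key)) > 0
  }, TRUE)
  prox$direct_actor <- if (is.null(direct_targets)) NA else {
    dt <- gene_set(direct_targets)
    vapply(prox$component_id, function(id) {
      length(intersect(gene_set(map[[id]]), dt)) > 0
    }, TRUE)
  }
  prox$class <- ifelse(prox$direct_key_hit, "direct",
                ifelse(prox$S_AB < 0, "indirect_regulator", "separated"))
  rownames(prox) <- NULL
  prox
}

#' Write a key-target report to disk
#'
#' Emits a TSV of per-node scores and a JSON report (key sets, entropy
#' weights, configuration echo, and md5 digests of any input files) into a
#' directory. The JSON is canonical -- reruns with identical inputs and
#' configuration are byte-identical.
#'
#' @param report A `key_target_report` from [discover_key_targets()].
#' @param dir Output directory (created if needed).
#' @param input_files Optional character vector of input paths to digest
#'   into the provenance block.
#' @return Invisibly, the path of the JSON report.
#' @export
write_report <- function(report, dir, input_files = character(0)) {
  stopifnot(inherits(report, "key_target_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  score_path <- file.path(dir, "node_scores.tsv")
  utils::write.table(report$scores, score_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  digests <- if (length(input_files) > 0) {
    as.list(tools::md5sum(input_files))
  } else {
    NULL
  }
  payload <- list(
    key_targets = report$key_targets,
    iiem_selected = report$iiem_selected,
    mcc_selected = report$mcc_selected,
    entropy = as.list(report$iiem$H),
    weights = as.list(report$iiem$omega),
    coverage = report$coverage,
    config = unclass(report$config),
    input_digests = digests
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(json_path)
}
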