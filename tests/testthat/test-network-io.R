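write_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("confidence threshold filtering keeps scores at or above the cutoff", {
  path <- write_tsv(c("A\tB\t0.65", "A\tC\t0.70", "B\tC\t0.95"))
  g <- read_edge_list(path, score_threshold = 0.7)
  expect_equal(igraph::ecount(g), 2)
  g_excl <- read_edge_list(path, score_threshold = 0.7, inclusive = FALSE)
  expect_equal(igraph::ecount(g_excl), 1)
  # boundary edge retained only in the inclusive reading
  el <- igraph::as_edgelist(g)
  expect_true(any(el[, 1] == "A" & el[, 2] == "C" | el[, 1] == "C" & el[, 2] == "A"))
})

test_that("self-loops are dropped and duplicate unordered pairs keep the max score", {
  g <- read_edge_list(write_tsv("A\tA\t0.9"), score_threshold = 0)
  expect_equal(igraph::ecount(g), 0)
  g2 <- read_edge_list(write_tsv(c("A\tB\t0.8", "B\tA\t0.9")), score_threshold = 0)
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::E(g2)$weight, 0.9)
})

test_that("edge-list parsing errors carry line numbers and range checks", {
  expect_error(read_edge_list(write_tsv(c("A\tB\t0.8", "oops")), 0), "line 2")
  expect_error(read_edge_list(write_tsv("A\tB\tnot_a_number"), 0), "line 1")
  expect_error(read_edge_list(write_tsv("A\tB\t1.5"), 0), "outside")
  empty <- read_edge_list(write_tsv(character(0)), 0.7)
  expect_equal(igraph::vcount(empty), 0)
})

test_that("two-column edge lists default scores to 1 and SIF is readable", {
  g <- read_edge_list(write_tsv(c("a\tb", "b\tc")), score_threshold = 0.7)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(sort(igraph::V(g)$name), c("A", "B", "C"))
  s <- read_sif(write_tsv(c("A pp B", "B pp C", "A pp A")))
  expect_equal(igraph::ecount(s), 2)
  expect_error(read_sif(write_tsv("A B")), "SIF line 1")
})

test_that("edge lists round-trip through write-then-read", {
  withr::local_seed(11)
  rg <- rand_graph(15, 0.3)
  g <- rg$g
  igraph::E(g)$weight <- round(runif(igraph::ecount(g), 0.4, 1), 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  g2 <- read_edge_list(path, score_threshold = 0)
  key <- function(x) {
    el <- igraph::as_edgelist(x)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_equal(key(g2), key(g))
  expect_equal(sum(igraph::E(g2)$weight), sum(igraph::E(g)$weight))
})

test_that("raising the score threshold never increases the edge count", {
  withr::local_seed(7)
  lines <- sprintf("N%02d\tN%02d\t%.3f", sample(30, 60, TRUE), sample(30, 60, TRUE),
                   runif(60))
  path <- write_tsv(lines)
  counts <- vapply(seq(0, 1, by = 0.1), function(th) {
    igraph::ecount(read_edge_list(path, score_threshold = th))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("gene sets are case-folded, deduplicated, and refuse to be empty", {
  path <- write_tsv(c("akt1", "AKT1", "App"))
  expect_equal(read_gene_set(path), gene_set(c("AKT1", "APP")), ignore_attr = TRUE)
  expect_error(read_gene_set(write_tsv(c("# only", "# comments"))), "empty gene set")
  expect_length(read_gene_set(write_tsv(c("AGT", "SAA1", "KNG1"))), 3)
})

test_that("component maps parse one pair per row and group by component", {
  path <- write_tsv(c("c1\tAKT1", "c1\takt1", "c1\tAPP", "c2\tTP53"))
  map <- read_component_map(path)
  expect_named(map, c("c1", "c2"))
  expect_equal(as.character(map$c1), c("AKT1", "APP"))
  expect_error(read_component_map(write_tsv("c1 only_one_field")), "line 1")
})

test_that("largest_component returns the biggest induced connected subgraph", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "C", "D", "X", "Y"),
               to   = c("B", "C", "D", "E", "Y", "Z")),
    directed = FALSE)
  lcc <- largest_component(g)
  expect_equal(sort(igraph::V(lcc)$name), c("A", "B", "C", "D", "E"))
  expect_true(igraph::is_connected(lcc))
  # connected graph comes back whole
  k <- igraph::make_full_graph(4)
  igraph::V(k)$name <- LETTERS[1:4]
  expect_equal(igraph::vcount(largest_component(k)), 4)
  # equal-size tie goes to the component holding the smallest label
  tie <- igraph::graph_from_data_frame(
    data.frame(from = c("AAA", "BBB", "CCC", "DDD"),
               to   = c("BBB", "AAB", "DDD", "CCD")),
    directed = FALSE)
  expect_true("AAA" %in% igraph::V(largest_component(tie))$name)
  expect_error(largest_component(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})
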