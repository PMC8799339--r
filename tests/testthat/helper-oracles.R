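# Brute-force reference implementations, independent of the package's code
# paths (and of igraph's algorithms): plain-R BFS, shortest-path counting,
# dense linear solves, and bitmask subset enumeration. Deliberately slow and
# obvious.

# Dense adjacency with node labels (representation shim only).
oracle_adj <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# All-pairs unweighted distances by queue BFS from every source.
oracle_dist <- function(adj) {
  n <- nrow(adj)
  nbr <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier) > 0) {
      lev <- lev + 1
      nxt <- unique(unlist(nbr[frontier]))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- lev
      frontier <- nxt
    }
  }
  d
}

oracle_closeness <- function(adj) {
  d <- oracle_dist(adj)
  (nrow(adj) - 1) / rowSums(d)
}

oracle_eccentricity <- function(adj) {
  apply(oracle_dist(adj), 1, max)
}

# Shortest-path counts sigma[s, u] via DP over BFS levels.
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (u in ord) {
      if (u == s) next
      preds <- which(adj[u, ] > 0 & d[s, ] == d[s, u] - 1)
      sigma[s, u] <- sum(sigma[s, preds])
    }
  }
  sigma
}

# Unnormalized betweenness: sum over unordered pairs (s, t) of the fraction
# of shortest s-t paths through v.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_dist(adj)
  sigma <- oracle_path_counts(adj, d)
  bc <- stats::setNames(numeric(n), rownames(adj))
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && d[s, v] + d[v, t] == d[s, t]) {
        bc[v] <- bc[v] + sigma[s, v] * sigma[t, v] / sigma[s, t]
      }
    }
  }
  bc
}

# PageRank by dense linear solve of (I - damping * P) x = (1 - damping)/n.
oracle_pagerank <- function(adj, damping = 0.85) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  P <- matrix(0, n, n)
  for (v in seq_len(n)) {
    if (deg[v] > 0) P[, v] <- adj[, v] / deg[v] else P[, v] <- 1 / n
  }
  x <- solve(diag(n) - damping * P, rep((1 - damping) / n, n))
  stats::setNames(as.numeric(x), rownames(adj))
}

# All maximal cliques (size >= 2) by vectorized bitmask enumeration over
# every one of the 2^n vertex subsets. n <= 16.
oracle_cliques <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 16)
  bit <- bitwShiftL(1L, 0:(n - 1))
  adjmask <- vapply(seq_len(n), function(v) {
    m <- 0L
    for (u in which(adj[v, ] > 0)) m <- bitwOr(m, bit[u])
    m
  }, 0L)
  masks <- 0:(2^n - 1)
  is_clique <- rep(TRUE, length(masks))
  for (v in seq_len(n)) {
    inv <- bitwAnd(masks, bit[v]) > 0
    covered <- bitwAnd(masks, bitwOr(adjmask[v], bit[v])) == masks
    is_clique <- is_clique & (!inv | covered)
  }
  extendable <- rep(FALSE, length(masks))
  for (w in seq_len(n)) {
    outw <- bitwAnd(masks, bit[w]) == 0
    covers <- bitwAnd(masks, adjmask[w]) == masks
    extendable <- extendable | (outw & covers)
  }
  nbits <- vapply(masks, function(m) sum(bitwAnd(m, bit) > 0), 0)
  maximal <- masks[is_clique & !extendable & nbits >= 2]
  lapply(maximal, function(m) sort(rownames(adj)[bitwAnd(m, bit) > 0]))
}

oracle_mcc <- function(adj) {
  scores <- stats::setNames(numeric(nrow(adj)), rownames(adj))
  for (cl in oracle_cliques(adj)) {
    scores[cl] <- scores[cl] + factorial(length(cl) - 1)
  }
  scores
}

# Straight-line transcription of the importance-scoring chain, written
# without reference to the package implementation.
oracle_iiem <- function(x, epsilon = 1e-4, sqrt_form = TRUE) {
  m <- nrow(x); n <- ncol(x)
  y <- x
  for (j in 1:n) {
    mn <- min(x[, j]); mx <- max(x[, j])
    y[, j] <- if (mx == mn) 0 else (x[, j] - mn) / (mx - mn)
  }
  H <- numeric(n)
  for (j in 1:n) {
    b <- (y[, j] + epsilon) / sum(y[, j] + epsilon)
    H[j] <- -sum(b * log(b)) / log(m)
  }
  S <- sum(1 - H)
  omega <- ((1 - H) + 0.1 * S) / (S + 0.1 * n * S)
  Z <- numeric(m)
  for (i in 1:m) {
    Z[i] <- sum(omega * (y[i, ] - 0)^2)
    if (sqrt_form) Z[i] <- sqrt(Z[i])
  }
  list(y = y, H = H, omega = omega, Z = Z)
}

# Separation score from a precomputed dense distance matrix (double loops).
# Same-node pairs are skipped in the cross term so that S_AA = 0.
oracle_sab <- function(d, A, B) {
  cross <- c()
  for (a in A) for (b in B) if (a != b) cross <- c(cross, d[a, b])
  cross <- cross[is.finite(cross)]
  if (length(cross) == 0) return(0)
  win <- function(S) {
    if (length(S) < 2) return(0)
    v <- c()
    for (i in 1:(length(S) - 1)) for (j in (i + 1):length(S)) {
      v <- c(v, d[S[i], S[j]])
    }
    mean(v[is.finite(v)])
  }
  mean(cross) - (win(A) + win(B)) / 2
}

# Random simple graph on n labelled nodes; optionally resample until
# connected.
rand_graph <- function(n, p = 0.3, connected = FALSE) {
  repeat {
    adj <- matrix(0, n, n)
    up <- which(upper.tri(adj))
    adj[up] <- rbinom(length(up), 1, p)
    adj <- adj + t(adj)
    dimnames(adj) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (!connected || igraph::is_connected(g)) {
      return(list(g = g, adj = adj))
    }
  }
}

rand_indicator_matrix <- function(m, n = 5) {
  matrix(runif(m * n, 0, 10), m, n,
         dimnames = list(sprintf("N%03d", 1:m),
                         paste0("ind", 1:n)))
}
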