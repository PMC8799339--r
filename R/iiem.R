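#' Min-max standardization of an indicator matrix
#'
#' Each column is rescaled to \[0, 1\] by
#' `y_ij = (x_ij - min_i x_ij) / (max_i x_ij - min_i x_ij)`.
#' A constant column (max = min) carries no discriminating information and is
#' mapped to all zeros, which downstream receives maximal entropy and hence
#' minimal weight -- graceful degradation rather than an error.
#'
#' @param x Numeric matrix (m nodes x n indicators), m >= 2, finite entries.
#' @param invert Character vector of column names (or logical/integer index)
#'   to treat as cost-type: those columns are standardized as
#'   `(max - x) / (max - min)` so that smaller raw values score higher.
#' @return Matrix of the same shape with all entries in \[0, 1\].
#' @export
iiem_standardize <- function(x, invert = character(0)) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("standardization needs at least 2 rows")
  if (!all(is.finite(x))) stop("indicator matrix must be finite")
  inv <- logical(ncol(x))
  if (length(invert) > 0) {
    idx <- if (is.character(invert)) match(invert, colnames(x)) else invert
    if (anyNA(idx)) stop("invert names not found in indicator columns")
    inv[idx] <- TRUE
  }
  y <- x
  for (j in seq_len(ncol(x))) {
    rng <- range(x[, j])
    span <- rng[2] - rng[1]
    if (span == 0) {
      y[, j] <- 0
    } else if (inv[j]) {
      y[, j] <- (rng[2] - x[, j]) / span
    } else {
      y[, j] <- (x[, j] - rng[1]) / span
    }
  }
  y
}

#' Information entropy of standardized indicator columns
#'
#' For each column j the entries are smoothed and normalized into a
#' probability vector `b_ij = (y_ij + epsilon) / sum_i (y_ij + epsilon)` and
#' its Shannon entropy is computed on the natural-log scale, normalized by
#' `ln m` so that `H_j` lies in (0, 1\]:
#' `H_j = -(1 / ln m) * sum_i b_ij ln b_ij`.
#' The smoothing constant keeps zero entries from producing `0 * log 0`
#' while leaving uniform columns at exactly `H_j = 1`.
#'
#' @param y Standardized matrix from [iiem_standardize()], entries in \[0, 1\].
#' @param epsilon Smoothing constant, default `1e-4`.
#' @return Numeric vector of n entropies.
#' @export
iiem_entropy <- function(y, epsilon = 1e-4) {
  y <- as.matrix(y)
  m <- nrow(y)
  if (m < 2) stop("entropy needs at least 2 rows (ln m = 0 at m = 1)")
  stopifnot(epsilon > 0)
  if (any(y < 0 | y > 1)) stop("standardized values must lie in [0, 1]")
  b <- sweep(y + epsilon, 2, colSums(y + epsilon), "/")
  H <- -colSums(b * log(b)) / log(m)
  # a constant column is exactly uniform after smoothing: H = 1 analytically,
  # short-circuited to avoid returning 1 +/- rounding noise
  constant <- apply(y, 2, function(col) max(col) == min(col))
  H[constant] <- 1
  names(H) <- colnames(y)
  H
}

#' Entropy-derived indicator weights
#'
#' Converts column entropies into weights
#' `omega_j = ((1 - H_j) + 0.1 * S) / ((1 + 0.1 * n) * S)` with
#' `S = sum_j (1 - H_j)`. The additive `0.1 * S` term is the scheme's
#' improvement over plain entropy weighting: even a fully uniform
#' (uninformative) indicator keeps a small positive weight instead of being
#' zeroed out. Weights sum to 1 by construction.
#'
#' @param H Numeric vector of entropies in \[0, 1\].
#' @return Numeric weight vector of the same length, strictly positive,
#'   summing to 1.
#' @export
iiem_weights <- function(H) {
  stopifnot(is.numeric(H), length(H) >= 1)
  if (any(H < 0 | H > 1)) stop("entropies must lie in [0, 1]")
  n <- length(H)
  S <- sum(1 - H)
  if (S <= 0) stop("all indicators uninformative (every H_j = 1)")
  omega <- ((1 - H) + 0.1 * S) / ((1 + 0.1 * n) * S)
  names(omega) <- names(H)
  omega
}

#' Weighted-distance importance score
#'
#' Per-node importance as the weighted Euclidean distance of the
#' standardized indicator row from an ideal point `f` (all zeros by
#' default): `Z_i = sqrt(sum_j omega_j * (y_ij - f_j)^2)`. With `f = 0` and
#' `y` in \[0, 1\], `Z_i` lies in \[0, 1\]. Set `sqrt_form = FALSE` for the
#' plain weighted sum of squared deviations.
#'
#' @param y Standardized matrix (m x n).
#' @param omega Weight vector of length n summing to 1.
#' @param f Ideal-point vector of length n (or a scalar, recycled);
#'   default 0.
#' @param sqrt_form Take the square root (default `TRUE`).
#' @return Numeric vector of m importance scores named by row.
#' @export
iiem_importance <- function(y, omega, f = 0, sqrt_form = TRUE) {
  y <- as.matrix(y)
  n <- ncol(y)
  if (length(omega) != n) stop("length(omega) must equal ncol(y)")
  if (length(f) == 1) f <- rep(f, n)
  if (length(f) != n) stop("length(f) must equal ncol(y)")
  dev2 <- sweep(y, 2, f)^2
  Z <- as.numeric(dev2 %*% omega)
  if (sqrt_form) Z <- sqrt(Z)
  names(Z) <- rownames(y)
  Z
}

#' Entropy-weighted node importance (full chain)
#'
#' Runs the complete importance-scoring chain on a raw indicator matrix:
#' min-max standardization, per-indicator information entropy, entropy
#' weights, and the weighted-distance importance score `Z`. The five
#' centrality indicators from [indicator_matrix()] are the intended input,
#' but any m x n matrix with n >= 2 works.
#'
#' @param x Raw indicator matrix (m x n) with node labels as row names.
#' @param epsilon Entropy smoothing constant; default `1e-4`.
#' @param f Ideal point passed to [iiem_importance()]; default 0.
#' @param sqrt_form Use the square-root importance form; default `TRUE`.
#' @param invert Columns to standardize as cost-type (see
#'   [iiem_standardize()]); default none -- all indicators are treated as
#'   benefit-type, eccentricity included, since the standardization is
#'   applied uniformly.
#' @return An object of class `iiem`: a list with `y` (standardized matrix),
#'   `H` (entropies), `omega` (weights), `Z` (importance scores), `epsilon`,
#'   `f`, and `sqrt_form`.
#' @examples
#' x <- matrix(c(2, 4, 6, 1, 1, 5), ncol = 2,
#'             dimnames = list(c("A", "B", "C"), c("deg", "btw")))
#' res <- iiem(x)
#' res$Z
#' @export
iiem <- function(x, epsilon = 1e-4, f = 0, sqrt_form = TRUE,
                 invert = character(0)) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 indicators")
  y <- iiem_standardize(x, invert = invert)
  H <- iiem_entropy(y, epsilon = epsilon)
  omega <- iiem_weights(H)
  Z <- iiem_importance(y, omega, f = f, sqrt_form = sqrt_form)
  structure(
    list(y = y, H = H, omega = omega, Z = Z,
         epsilon = epsilon, f = if (length(f) == 1) rep(f, ncol(x)) else f,
         sqrt_form = sqrt_form),
    class = "iiem"
  )
}

#' @export
print.iiem <- function(x, ...) {
  cat(sprintf("Entropy-weighted importance over %d nodes x %d indicators\n",
              nrow(x$y), ncol(x$y)))
  cat("weights:\n")
  print(round(x$omega, 4))
  top <- sort(x$Z, decreasing = TRUE)
  cat(sprintf("top scores (of %d):\n", length(top)))
  print(round(utils::head(top, 10), 4))
  invisible(x)
}

#' Select nodes by importance threshold
#'
#' Returns the labels of nodes whose importance score meets the threshold
#' (inclusive: `Z_i >= threshold`), ordered by descending score with ties
#' broken by label.
#'
#' @param Z Named numeric importance vector, or an [iiem()] result.
#' @param threshold Selection cutoff in \[0, 1\]; default 0.4.
#' @return Character vector of selected node labels (possibly empty).
#' @export
select_by_z <- function(Z, threshold = 0.4) {
  if (inherits(Z, "iiem")) Z <- Z$Z
  stopifnot(is.numeric(Z), !is.null(names(Z)))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  sel <- Z[Z >= threshold]
  names(sel)[order(-sel, names(sel))]
}
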