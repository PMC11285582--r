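#' Rank distance between embedded compounds
#'
#' Absolute difference of curve bin indices: the distance "along" the
#' unfolded pseudo-Hilbert curve.
#'
#' @param b1,b2 Integer vectors of bin indices.
#' @return Non-negative integer vector.
#' @export
rank_distance <- function(b1, b2) {
  abs(b1 - b2)
}

#' Chebyshev distance between grid points
#'
#' The maximum coordinate-wise absolute difference; the perceived distance of
#' two embedded compounds stretched over the latent grid.
#'
#' @param x1,y1,x2,y2 Coordinate vectors.
#' @return Non-negative numeric vector.
#' @export
chebyshev_distance <- function(x1, y1, x2, y2) {
  pmax(abs(x1 - x2), abs(y1 - y2))
}

#' Per-bin compound counts of an embedding
#'
#' Condenses an embedding into a `4^z`-length vector whose entry `i` counts
#' the compounds assigned to curve bin `i - 1`. The vector total equals the
#' number of embedded compounds.
#'
#' @param embedding A `hilbert_embedding` (or data frame with a `bin` column
#'   plus `z` given explicitly).
#' @param z Curve order; taken from the embedding attributes when absent.
#' @return An integer vector of class `embedding_vector` with attributes `z`
#'   and `space_checksum`.
#' @export
embedding_vector <- function(embedding, z = NULL) {
  z <- z %||% attr(embedding, "z")
  if (is.null(z)) abort("z not given and not carried by the embedding")
  check_order(z)
  ez <- attr(embedding, "z")
  if (!is.null(ez) && ez != z) {
    abort(sprintf("embedding was generated at z = %d, not z = %d", ez, z))
  }
  n_cells <- as.integer(4^z)
  counts <- tabulate(embedding$bin + 1L, nbins = n_cells)
  structure(as.integer(counts), class = "embedding_vector", z = as.integer(z),
            space_checksum = attr(embedding, "space_checksum"))
}

#' Space-overlap statistic of two embeddings
#'
#' A modified Tanimoto coefficient on per-bin count vectors:
#' `theta = sum(A*B) / (sum(A^2) + sum(B^2) - sum(A*B))`. It is symmetric,
#' bounded in `[0, 1]`, equals 1 exactly on identical nonzero vectors, and 0
#' when the occupied bins are disjoint. Vectors from different grids or
#' different reference spaces are refused.
#'
#' @param a,b `embedding_vector`s (or plain numeric vectors of equal length).
#' @return The overlap in `[0, 1]`.
#' @export
theta_overlap <- function(a, b) {
  if (length(a) != length(b)) {
    abort("embedding vectors have different lengths (different z?)")
  }
  za <- attr(a, "z"); zb <- attr(b, "z")
  if (!is.null(za) && !is.null(zb) && za != zb) {
    abort("embedding vectors come from curves of different order")
  }
  ca <- attr(a, "space_checksum"); cb <- attr(b, "space_checksum")
  if (!is.null(ca) && !is.null(cb) && !is.na(ca) && !is.na(cb) && ca != cb) {
    abort("embedding vectors come from different reference spaces")
  }
  a <- as.numeric(a); b <- as.numeric(b)
  ab <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - ab
  if (denom == 0) abort("overlap undefined: both embedding vectors are empty")
  ab / denom
}

#' Correlation of rank distance and Chebyshev distance
#'
#' Over all unordered pairs of the analyzed compounds, correlates the curve
#' rank distance `|b_i - b_j|` with the grid Chebyshev distance. A strong
#' positive correlation indicates that proximity on the unfolded curve is
#' perceived as proximity on the 2D map. Optionally the analysis is repeated
#' on non-overlapping random subsets (sampled without replacement), in which
#' case per-subset estimates plus their mean and standard deviation are
#' returned.
#'
#' @param embedding A `hilbert_embedding`, or any data frame with `bin`, `x`,
#'   `y` columns.
#' @param method `"pearson"` or `"kendall"`.
#' @param subset_size Optional subset size (e.g. 100); `NULL` analyses the
#'   whole set once.
#' @param n_subsets Number of non-overlapping subsets to draw.
#' @param seed Optional seed for subset sampling.
#' @return A `distance_correlation` object: tibble with columns `subset`,
#'   `n`, `n_pairs`, `estimate`, and attributes `method`, `mean`, `sd`.
#'   Degenerate subsets (either distance constant) yield `NA` with a warning.
#' @export
distance_correlation <- function(embedding, method = c("pearson", "kendall"),
                                 subset_size = NULL, n_subsets = 1,
                                 seed = NULL) {
  method <- match.arg(method)
  need <- c("bin", "x", "y")
  if (!all(need %in% names(embedding))) {
    abort("embedding must carry bin, x and y columns")
  }
  n <- nrow(embedding)
  if (n < 3) abort("need at least 3 compounds")
  if (is.null(subset_size)) {
    groups <- list(seq_len(n))
  } else {
    if (subset_size < 3) abort("subset_size must be >= 3")
    if (n_subsets * subset_size > n) {
      abort(sprintf("cannot draw %d non-overlapping subsets of %d from %d",
                    n_subsets, subset_size, n))
    }
    perm <- if (is.null(seed)) sample.int(n) else
      withr::with_seed(seed, sample.int(n))
    groups <- lapply(seq_len(n_subsets), function(i) {
      perm[((i - 1) * subset_size + 1):(i * subset_size)]
    })
  }
  est <- vapply(groups, function(ix) {
    pair_correlation(embedding$bin[ix], embedding$x[ix], embedding$y[ix],
                     method)
  }, numeric(1))
  out <- tibble(subset = seq_along(groups),
                n = vapply(groups, length, integer(1)),
                n_pairs = vapply(groups, function(ix) {
                  as.integer(length(ix) * (length(ix) - 1) / 2)
                }, integer(1)),
                estimate = est)
  structure(out, method = method,
            mean = mean(est, na.rm = TRUE),
            sd = if (length(est) > 1) sd(est, na.rm = TRUE) else NA_real_,
            class = c("distance_correlation", class(out)))
}

pair_correlation <- function(bin, x, y, method) {
  ut <- upper.tri(matrix(0, length(bin), length(bin)))
  d_r <- abs(outer(bin, bin, "-"))[ut]
  d_c <- pmax(abs(outer(x, x, "-")), abs(outer(y, y, "-")))[ut]
  if (sd(d_r) == 0 || sd(d_c) == 0) {
    warn("correlation undefined: a distance is constant over all pairs")
    return(NA_real_)
  }
  cor(d_r, d_c, method = method)
}

#' @export
print.distance_correlation <- function(x, ...) {
  cat(sprintf("<distance_correlation> method = %s | mean = %.4f | sd = %s\n",
              attr(x, "method"), attr(x, "mean"),
              if (is.na(attr(x, "sd"))) "-" else sprintf("%.4f",
                                                         attr(x, "sd"))))
  NextMethod()
}

#' Coverage matrix of an embedding
#'
#' Accumulates compound counts on the `2^z` by `2^z` grid (row `y + 1`,
#' column `x + 1`), optionally binarized to 0/1 occupancy. The count-matrix
#' total equals the number of embedded compounds.
#'
#' @param embedding A `hilbert_embedding` (or data frame with `x`, `y` and an
#'   attribute-free `z` supplied).
#' @param binarize If `TRUE`, return 0/1 occupancy instead of counts.
#' @param z Curve order; taken from the embedding when absent.
#' @return An integer matrix.
#' @export
coverage_matrix <- function(embedding, binarize = FALSE, z = NULL) {
  z <- z %||% attr(embedding, "z")
  if (is.null(z)) abort("z not given and not carried by the embedding")
  check_order(z)
  n <- as.integer(2^z)
  m <- matrix(0L, nrow = n, ncol = n)
  if (nrow(embedding) > 0) {
    idx <- cbind(embedding$y + 1L, embedding$x + 1L)
    for (i in seq_len(nrow(idx))) {
      m[idx[i, 1], idx[i, 2]] <- m[idx[i, 1], idx[i, 2]] + 1L
    }
  }
  if (binarize) m <- (m > 0L) * 1L
  m
}
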