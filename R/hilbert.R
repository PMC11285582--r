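#' Pseudo-Hilbert-curve grid dimensions
#'
#' A pseudo-Hilbert curve of order `z` visits every cell of a
#' `2^z` by `2^z` grid exactly once, so the curve has `4^z` addressable
#' positions.
#'
#' @param z Curve order, an integer `>= 1`.
#' @return A tibble with columns `z`, `n_side` (`2^z`) and `n_cells` (`4^z`).
#' @export
grid_dimensions <- function(z) {
  check_order(z)
  tibble(z = as.integer(z), n_side = as.integer(2^z),
         n_cells = as.integer(4^z))
}

check_order <- function(z) {
  if (any(!is.finite(z)) || any(z < 1) || any(z != as.integer(z))) {
    abort("curve order z must be an integer >= 1")
  }
  if (any(z > 15)) abort("curve order z > 15 is not supported")
  invisible(TRUE)
}

#' Map curve indices to grid coordinates
#'
#' Converts zero-based positions along the pseudo-Hilbert curve of order `z`
#' to `(x, y)` cells of the `2^z` by `2^z` grid, using the standard
#' bit-manipulation construction with entry at the origin. The map is a
#' bijection onto the grid, and consecutive indices always land in
#' edge-adjacent cells. This orientation is a frozen convention: all embedding
#' coordinates produced by the package depend on it.
#'
#' @param d Integer vector of curve indices in `[0, 4^z - 1]`.
#' @param z Curve order.
#' @return A tibble with columns `d`, `x`, `y` (coordinates in `[0, 2^z - 1]`).
#' @export
hilbert_coords <- function(d, z) {
  check_order(z)
  n <- as.integer(2^z)
  d <- as.integer(d)
  if (any(is.na(d)) || any(d < 0) || any(d > n * n - 1)) {
    abort(sprintf("curve index out of range [0, %d]", n * n - 1))
  }
  x <- integer(length(d))
  y <- integer(length(d))
  t <- d
  s <- 1L
  while (s < n) {
    rx <- bitwAnd(1L, t %/% 2L)
    ry <- bitwAnd(1L, bitwXor(t, rx))
    # rotate quadrant
    flip <- ry == 0L & rx == 1L
    x[flip] <- s - 1L - x[flip]
    y[flip] <- s - 1L - y[flip]
    swap <- ry == 0L
    tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
    x <- x + s * rx
    y <- y + s * ry
    t <- t %/% 4L
    s <- s * 2L
  }
  tibble(d = d, x = x, y = y)
}

#' Map grid coordinates to curve indices
#'
#' Inverse of [hilbert_coords()].
#'
#' @param x,y Integer coordinate vectors in `[0, 2^z - 1]`.
#' @param z Curve order.
#' @return Integer vector of curve indices.
#' @export
hilbert_index <- function(x, y, z) {
  check_order(z)
  n <- as.integer(2^z)
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (any(is.na(x)) || any(is.na(y)) || any(x < 0) || any(y < 0) ||
      any(x >= n) || any(y >= n)) {
    abort(sprintf("coordinates out of range [0, %d]", n - 1))
  }
  d <- integer(length(x))
  s <- n %/% 2L
  while (s > 0L) {
    rx <- as.integer(bitwAnd(x, s) > 0L)
    ry <- as.integer(bitwAnd(y, s) > 0L)
    d <- d + s * s * bitwXor(3L * rx, ry)
    flip <- ry == 0L & rx == 1L
    x[flip] <- n - 1L - x[flip]
    y[flip] <- n - 1L - y[flip]
    swap <- ry == 0L
    tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
    s <- s %/% 2L
  }
  d
}

#' Bin size linking scaffold ranks to curve indices
#'
#' The ordered reference scaffolds (ranks `1..|S|`) are spread over the
#' zero-indexed curve positions `0..|D|-1`, so the bin size is
#' `l = |S| / (|D| - 1)`; the top rank then lands exactly on the last curve
#' index.
#'
#' @param space_size Number of reference scaffolds, `|S| >= 1`.
#' @param z Curve order.
#' @return The bin size `l` (positive real).
#' @export
bin_size <- function(space_size, z) {
  check_order(z)
  if (space_size < 1) abort("space_size must be >= 1")
  n_cells <- 4^z
  if (n_cells < 2) abort("grid must have at least 2 cells")
  space_size / (n_cells - 1)
}

# round half away from zero for positive values ("round half up"); base
# round() would bankers-round .5 ties.
round_half_up <- function(x) floor(x + 0.5)

#' Bin index of a scaffold rank
#'
#' The curve position assigned to a 1-based scaffold rank: `rank / l` rounded
#' to the nearest integer, with `.5` ties rounded up (half away from zero).
#'
#' @param rank Integer vector of 1-based scaffold ranks.
#' @param l Bin size from [bin_size()].
#' @return Integer vector of zero-based curve indices.
#' @export
bin_index <- function(rank, l) {
  if (any(rank < 1)) abort("ranks are 1-based and must be >= 1")
  if (l <= 0) abort("bin size must be positive")
  as.integer(round_half_up(rank / l))
}
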