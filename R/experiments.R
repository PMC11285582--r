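#' Coordinate convergence of an embedding over increasing curve order
#'
#' Embeds a library once per curve order in `z_range` (the scaffold and
#' nearest-reference stages are shared) and reports, for each consecutive
#' pair of orders, the mean displacement of the normalized coordinates
#' `(x / 2^z, y / 2^z)`. As the order grows, positions stabilize: the
#' successive displacement shrinks.
#'
#' @param df A compound data frame with `id` and `smiles`.
#' @param space A `scaffold_space`.
#' @param z_range Increasing integer vector of curve orders.
#' @return A tibble with columns `z_from`, `z_to`, `mean_displacement`.
#' @export
convergence_profile <- function(df, space, z_range = 2:8) {
  assert_space(space)
  stopifnot(length(z_range) >= 2, all(diff(z_range) > 0))
  rec <- scaffold_records(df)
  nn <- nearest_reference(rec, space)
  norm_xy <- lapply(z_range, function(z) {
    l <- bin_size(nrow(space), z)
    co <- hilbert_coords(bin_index(nn$nearest_rank, l), z)
    cbind(co$x, co$y) / 2^z
  })
  purrr::map_dfr(seq_len(length(z_range) - 1L), function(i) {
    delta <- norm_xy[[i + 1L]] - norm_xy[[i]]
    tibble(z_from = z_range[i], z_to = z_range[i + 1L],
           mean_displacement = mean(sqrt(rowSums(delta^2))))
  })
}

#' Robustness of scaffold positions to a reduced reference set
#'
#' Rebuilds the reference space from a random subset containing `fraction`
#' of the scaffold records (the tracked scaffolds are always retained, as in
#' a reduced-set design) and measures how far each tracked scaffold moves on
#' the grid of order `z`, in normalized coordinates `(x / 2^z, y / 2^z)`.
#' A robust embedding moves tracked scaffolds very little even though 10% of
#' the reference set disappeared.
#'
#' @param records Scaffold records as returned by [scaffold_records()] (or a
#'   raw `id`/`smiles` data frame, which will be processed first).
#' @param tracked_ranks Ranks (in the full space) of the scaffolds to track.
#' @param fraction Fraction of records kept in the reduced space.
#' @param z Curve order at which positions are compared.
#' @param seed Seed for the random subset.
#' @return A tibble with one row per tracked scaffold: `rank_full`,
#'   `rank_reduced`, `displacement` (normalized Euclidean); the mean is in
#'   attribute `mean_displacement`.
#' @export
subset_robustness <- function(records, tracked_ranks, fraction = 0.9, z = 8,
                              seed = 1) {
  if (!all(c(sk_cols(), "inchikey", "smiles") %in% names(records))) {
    records <- scaffold_records(records)
  }
  full <- build_reference_space(records, source_label = "full")
  tracked_ranks <- as.integer(tracked_ranks)
  if (any(tracked_ranks < 1) || any(tracked_ranks > nrow(full))) {
    abort("tracked_ranks outside the full space")
  }
  tracked_keys <- full$inchikey[match(tracked_ranks, full$rank)]
  keep_n <- round(fraction * nrow(records))
  keep <- withr::with_seed(seed, sample.int(nrow(records), keep_n))
  reduced_rec <- records[sort(unique(keep)), , drop = FALSE]
  # tracked scaffolds are always part of the reduced set
  missing_tracked <- !(tracked_keys %in% reduced_rec$inchikey)
  if (any(missing_tracked)) {
    add <- records[records$inchikey %in% tracked_keys[missing_tracked], ,
                   drop = FALSE]
    reduced_rec <- bind_rows(reduced_rec, add)
  }
  reduced <- build_reference_space(reduced_rec, source_label = "reduced")
  co_full <- space_coordinates(full, z)
  co_red <- space_coordinates(reduced, z)
  n_side <- 2^z
  ix_red <- match(tracked_keys, reduced$inchikey)
  if (anyNA(ix_red)) abort("a tracked scaffold vanished from the reduced space")
  out <- tibble(
    rank_full = tracked_ranks,
    rank_reduced = reduced$rank[ix_red],
    displacement = sqrt(
      ((co_full$x[match(tracked_ranks, co_full$rank)] -
          co_red$x[ix_red]) / n_side)^2 +
        ((co_full$y[match(tracked_ranks, co_full$rank)] -
            co_red$y[ix_red]) / n_side)^2
    )
  )
  attr(out, "mean_displacement") <- mean(out$displacement)
  out
}
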