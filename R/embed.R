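#' Nearest reference scaffold under the scaffold-key distance
#'
#' For each query key vector, finds the reference scaffold minimizing the
#' scaffold-key distance. Ties are broken by the lowest rank (the "simpler
#' first" semantics of the reference ordering).
#'
#' @param keys A numeric matrix with 32 columns, or a data frame carrying
#'   `sk01..sk32` columns (one row per query scaffold).
#' @param space A `scaffold_space`.
#' @return A tibble with columns `nearest_rank` and `d_sk`.
#' @export
nearest_reference <- function(keys, space) {
  assert_space(space)
  if (is.data.frame(keys)) keys <- sk_matrix(keys)
  if (nrow(space) == 0) abort("reference space is empty")
  d <- sk_distance_matrix(keys, sk_matrix(space))
  idx <- apply(d, 1L, which.min)  # first minimum = lowest rank
  tibble(nearest_rank = space$rank[idx],
         d_sk = d[cbind(seq_len(nrow(d)), idx)])
}

#' Embed a compound library into a reference scaffold space
#'
#' The embedding of one compound is independent of every other compound in
#' the batch: its Bemis-Murcko scaffold is extracted, the scaffold's 32 keys
#' are computed, the nearest reference scaffold under the scaffold-key
#' distance is located, and the compound assumes that scaffold's grid cell —
#' the curve position `round(rank / l)` folded to 2D by the pseudo-Hilbert
#' curve of order `z`. Compounds without a scaffold (or failing any stage)
#' are skipped and reported, never aborting the batch.
#'
#' @param df A data frame with `id` and `smiles` columns.
#' @param space A `scaffold_space`.
#' @param z Curve order (resolution of the embedding). When the grid has more
#'   cells than `|S| + 1` the embedding is sparser than the reference set can
#'   resolve; this is allowed but noted with a message.
#' @param max_z Safety cap on `z` (memory of downstream `4^z`-length
#'   summaries).
#' @return A `hilbert_embedding`: a tibble with columns `id`, `smiles`
#'   (standardized), `scaffold_smiles`, `nearest_rank`, `d_sk`, `bin`, `x`,
#'   `y`; attributes `z`, `n_side`, `n_cells`, `bin_width`, `space_size`,
#'   `space_checksum`, and `skipped` (tibble of id/reason).
#' @export
embed_library <- function(df, space, z, max_z = 10) {
  assert_space(space)
  check_order(z)
  if (z > max_z) {
    abort(sprintf("z = %d exceeds max_z = %d; raise max_z deliberately",
                  z, max_z))
  }
  dims <- grid_dimensions(z)
  if (dims$n_cells > nrow(space) + 1) {
    message(sprintf(
      "grid of %d cells exceeds the %d reference scaffolds; resolution is limited by the reference set",
      dims$n_cells, nrow(space)))
  }
  rec <- scaffold_records(df)
  nn <- nearest_reference(rec, space)
  l <- bin_size(nrow(space), z)
  b <- bin_index(nn$nearest_rank, l)
  co <- hilbert_coords(b, z)
  std <- suppressWarnings(standardize_structures(df))
  out <- tibble(id = rec$id,
                smiles = std$smiles[match(rec$id, std$id)],
                scaffold_smiles = rec$smiles,
                nearest_rank = nn$nearest_rank,
                d_sk = nn$d_sk,
                bin = b, x = co$x, y = co$y)
  new_embedding(out, z = z, space = space, l = l,
                skipped = attr(rec, "dropped") %||%
                  tibble(id = character(), reason = character()))
}

new_embedding <- function(df, z, space, l, skipped) {
  dims <- grid_dimensions(z)
  attr(df, "z") <- as.integer(z)
  attr(df, "n_side") <- dims$n_side
  attr(df, "n_cells") <- dims$n_cells
  attr(df, "bin_width") <- l
  attr(df, "space_size") <- nrow(space)
  attr(df, "space_checksum") <- attr(space, "checksum")
  attr(df, "skipped") <- skipped
  class(df) <- c("hilbert_embedding", class(df))
  df
}

#' @export
print.hilbert_embedding <- function(x, ...) {
  cat(sprintf(
    "<hilbert_embedding> %d compounds | z = %d (%d x %d grid) | space |S| = %d\n",
    nrow(x), attr(x, "z"), attr(x, "n_side"), attr(x, "n_side"),
    attr(x, "space_size")))
  sk <- attr(x, "skipped")
  if (!is.null(sk) && nrow(sk) > 0) {
    cat(sprintf("  skipped %d compound(s) without a usable scaffold\n",
                nrow(sk)))
  }
  NextMethod()
}

#' Write an embedding to a delimited text file
#'
#' Tab-separated with a `#`-prefixed header block recording the grid
#' parameters (`z`, `n_side`, `n_cells`, `bin_width`, `space_size`) and the
#' reference-space checksum.
#'
#' @param embedding A `hilbert_embedding`.
#' @param path Output path.
#' @return `embedding` invisibly.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "hilbert_embedding"))
  hdr <- c("# scaffoldspace embedding",
           sprintf("# z: %d", attr(embedding, "z")),
           sprintf("# n_side: %d", attr(embedding, "n_side")),
           sprintf("# n_cells: %d", attr(embedding, "n_cells")),
           sprintf("# bin_width: %.17g", attr(embedding, "bin_width")),
           sprintf("# space_size: %d", attr(embedding, "space_size")),
           sprintf("# space_checksum: %s", attr(embedding, "space_checksum")))
  writeLines(hdr, path)
  readr::write_tsv(as_tibble(embedding), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(embedding)
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path Path to an embedding file.
#' @return A `hilbert_embedding`.
#' @export
read_embedding <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(name) {
    hit <- grep(sprintf("^# %s: ", name), hdr, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(sprintf("^# %s: ", name), "", hit[[1]])
  }
  df <- readr::read_tsv(I(paste(lines[!startsWith(lines, "#")],
                                collapse = "\n")),
                        show_col_types = FALSE, progress = FALSE)
  df <- as_tibble(df)
  attr(df, "z") <- as.integer(get_field("z"))
  attr(df, "n_side") <- as.integer(get_field("n_side"))
  attr(df, "n_cells") <- as.integer(get_field("n_cells"))
  attr(df, "bin_width") <- as.numeric(get_field("bin_width"))
  attr(df, "space_size") <- as.integer(get_field("space_size"))
  attr(df, "space_checksum") <- get_field("space_checksum")
  attr(df, "skipped") <- tibble(id = character(), reason = character())
  class(df) <- c("hilbert_embedding", class(df))
  df
}
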