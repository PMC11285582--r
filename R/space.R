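#' Full scaffold records for a set of structures
#'
#' Convenience pipeline stage: standardize, extract the Bemis-Murcko
#' scaffold, generate its InChI-Key and compute the 32 scaffold keys.
#' Structures without a scaffold (acyclic) or failing any stage are dropped
#' and counted.
#'
#' @param df A data frame with `id` and `smiles` columns.
#' @return A tibble with columns `id`, `smiles` (scaffold canonical SMILES),
#'   `inchikey` (scaffold InChI-Key) and `sk01..sk32`; attribute `n_dropped`
#'   counts eliminated records and attribute `dropped` lists them.
#' @export
scaffold_records <- function(df) {
  std <- suppressWarnings(standardize_structures(df))
  dropped <- attr(std, "dropped")
  scaf <- extract_scaffolds(std)
  no_bms <- is.na(scaf$scaffold_smiles)
  if (any(no_bms)) {
    dropped <- bind_rows(dropped,
                         tibble(id = scaf$id[no_bms], reason = "no scaffold"))
  }
  scaf <- scaf[!no_bms, , drop = FALSE]
  rec <- tibble(id = scaf$id, smiles = scaf$scaffold_smiles,
                inchikey = scaf$scaffold_inchikey)
  rec <- suppressWarnings(compute_scaffold_keys(rec, smiles_col = "smiles"))
  failed <- attr(rec, "sk_failed")
  if (!is.null(failed) && nrow(failed) > 0) {
    dropped <- bind_rows(dropped,
                         tibble(id = failed$id, reason = "key perception"))
  }
  attr(rec, "dropped") <- dropped
  attr(rec, "n_dropped") <- nrow(dropped)
  rec
}

#' Build a reference scaffold space
#'
#' Runs the full pipeline that defines a chemical space: standardize the
#' input structures, extract Bemis-Murcko scaffolds (structures without one
#' are eliminated and counted), compute scaffold keys, deduplicate by the
#' 32-key vector (representative: smallest InChI-Key), sort by the key tuple
#' with InChI-Key tie-break, and assign ranks `1..|S|`. The result is
#' deterministic and independent of input order.
#'
#' @param df A data frame with `id` and `smiles` columns, or a tibble already
#'   carrying `smiles`, `inchikey` and `sk01..sk32` columns (as produced by
#'   [scaffold_records()]), in which case the chemistry stages are skipped.
#' @param source_label Optional provenance string stored with the space.
#' @return A `scaffold_space`: a tibble with `rank`, `smiles`, `inchikey`,
#'   `sk01..sk32`, plus attributes `source`, `dedup` (`"sk"`), `n_dropped`,
#'   and `checksum`.
#' @export
build_reference_space <- function(df, source_label = "unspecified") {
  stopifnot(is.data.frame(df))
  if (all(c(sk_cols(), "inchikey", "smiles") %in% names(df))) {
    rec <- as_tibble(df)
    n_dropped <- attr(df, "n_dropped") %||% 0L
  } else {
    rec <- scaffold_records(df)
    n_dropped <- attr(rec, "n_dropped")
  }
  if (nrow(rec) == 0) abort("no scaffold survived the preparation pipeline")
  rec <- rec[!duplicated(rec$smiles), , drop = FALSE]  # identical frameworks
  rec <- dedup_scaffolds(rec)
  rec <- sort_scaffolds(rec)
  keep <- c("rank", "smiles", "inchikey", sk_cols())
  space <- rec[, keep]
  attr(space, "source") <- source_label
  attr(space, "dedup") <- "sk"
  attr(space, "n_dropped") <- n_dropped
  attr(space, "checksum") <- space_checksum(space)
  class(space) <- c("scaffold_space", class(space))
  space
}

# hashed over a canonical text rendering (representation-independent)
space_checksum <- function(space) {
  body <- do.call(paste, c(list(space$rank, space$smiles, space$inchikey),
                           lapply(sk_cols(), function(cn) space[[cn]]),
                           list(sep = "\t")))
  hash(paste(body, collapse = "\n"))
}

space_size <- function(space) nrow(space)

assert_space <- function(space) {
  if (!inherits(space, "scaffold_space")) {
    abort("expected a 'scaffold_space' (see build_reference_space())")
  }
  invisible(TRUE)
}

#' @export
print.scaffold_space <- function(x, ...) {
  cat(sprintf("<scaffold_space> %d reference scaffolds (source: %s)\n",
              nrow(x), attr(x, "source") %||% "unspecified"))
  cat(sprintf("  dedup: %s | dropped on build: %s | checksum: %s\n",
              attr(x, "dedup") %||% "?", attr(x, "n_dropped") %||% "?",
              substr(attr(x, "checksum") %||% "", 1, 12)))
  NextMethod()
}

#' Write a reference space to a delimited text file
#'
#' One row per scaffold (rank, canonical SMILES, InChI-Key, the 32 keys),
#' preceded by `#`-prefixed header lines (format version, source, dedup
#' policy, size, checksum) so an embedding is reproducible from the file
#' alone. Identical spaces serialize to byte-identical files.
#'
#' @param space A `scaffold_space`.
#' @param path Output path.
#' @return `space` invisibly.
#' @export
write_space <- function(space, path) {
  assert_space(space)
  hdr <- c(
    "# scaffoldspace reference space",
    "# format_version: 1",
    sprintf("# source: %s", attr(space, "source") %||% "unspecified"),
    sprintf("# dedup: %s", attr(space, "dedup") %||% "sk"),
    sprintf("# n_scaffolds: %d", nrow(space)),
    sprintf("# n_dropped: %d", attr(space, "n_dropped") %||% 0L),
    sprintf("# checksum: %s", attr(space, "checksum"))
  )
  body <- vapply(seq_len(nrow(space)), function(i) {
    paste(c(space$rank[i], space$smiles[i], space$inchikey[i],
            vapply(sk_cols(), function(cn) as.character(space[[cn]][i]),
                   character(1))),
          collapse = "\t")
  }, character(1))
  cols <- paste(c("rank", "smiles", "inchikey", sk_cols()), collapse = "\t")
  writeLines(c(hdr, cols, body), path)
  invisible(space)
}

#' Read a reference space written by [write_space()]
#'
#' @param path Path to a space file.
#' @return A `scaffold_space`; errors if the stored checksum does not match
#'   the recomputed one.
#' @export
read_space <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_field <- function(name) {
    hit <- grep(sprintf("^# %s: ", name), hdr, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(sprintf("^# %s: ", name), "", hit[[1]])
  }
  df <- readr::read_tsv(I(paste(body, collapse = "\n")),
                        show_col_types = FALSE, progress = FALSE)
  df <- as_tibble(df)
  df$smiles <- as.character(df$smiles)
  df$inchikey <- as.character(df$inchikey)
  for (cn in sk_cols()) df[[cn]] <- as.integer(df[[cn]])
  df$rank <- as.integer(df$rank)
  attr(df, "source") <- get_field("source")
  attr(df, "dedup") <- get_field("dedup")
  attr(df, "n_dropped") <- as.integer(get_field("n_dropped"))
  class(df) <- c("scaffold_space", class(df))
  chk <- space_checksum(df)
  stored <- get_field("checksum")
  if (!is.na(stored) && stored != chk) {
    abort("space file checksum mismatch; the file was modified or truncated")
  }
  attr(df, "checksum") <- chk
  df
}

#' Grid coordinates of the reference scaffolds themselves
#'
#' Maps every reference scaffold directly through the binning mechanism onto
#' the pseudo-Hilbert grid of order `z` (this is how the reference space is
#' visualized and how scaffold positions are tracked across space rebuilds).
#'
#' @param space A `scaffold_space`.
#' @param z Curve order.
#' @return A tibble with `rank`, `smiles`, `bin`, `x`, `y`.
#' @export
space_coordinates <- function(space, z) {
  assert_space(space)
  l <- bin_size(nrow(space), z)
  b <- bin_index(space$rank, l)
  co <- hilbert_coords(b, z)
  tibble(rank = space$rank, smiles = space$smiles, bin = b,
         x = co$x, y = co$y)
}
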