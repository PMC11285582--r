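#' Read a SMILES file
#'
#' Reads whitespace-delimited `.smi` files: one structure per line, SMILES in
#' the first field and an optional identifier in the second. Missing
#' identifiers are filled in as `MOL00001`, `MOL00002`, ...
#'
#' @param path Path to a `.smi` file.
#' @return A tibble with columns `id` and `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  id <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
               character(1))
  missing <- is.na(id)
  id[missing] <- sprintf("MOL%05d", which(missing))
  if (anyDuplicated(id)) {
    abort("duplicate compound ids in SMILES file")
  }
  tibble(id = id, smiles = smiles)
}

#' Write a SMILES file
#'
#' @param df A data frame with `smiles` and `id` columns.
#' @param path Output path.
#' @return `df` invisibly.
#' @export
write_smiles <- function(df, path) {
  writeLines(paste(df$smiles, df$id), path)
  invisible(df)
}

#' Read a delimited compound table
#'
#' @param path Path to a delimited text file with a header row.
#' @param smiles_col,id_col Column names holding the SMILES and identifier.
#' @param delim Field delimiter (default tab).
#' @return A tibble with columns `id` and `smiles`.
#' @export
read_compound_table <- function(path, smiles_col = "smiles", id_col = "id",
                                delim = "\t") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!all(c(smiles_col, id_col) %in% names(df))) {
    abort(sprintf("columns '%s' and '%s' not both present in %s",
                  smiles_col, id_col, path))
  }
  tibble(id = as.character(df[[id_col]]), smiles = as.character(df[[smiles_col]]))
}

#' Read structures from an SDF file
#'
#' Identifiers are taken from `id_prop` when given, else from the molecule
#' title line, else generated.
#'
#' @param path Path to an SDF file.
#' @param id_prop Optional SDF property name holding the identifier.
#' @return A tibble with columns `id` and `smiles` (RDKit canonical); records
#'   that fail to parse are dropped with a warning.
#' @export
read_sdf <- function(path, id_prop = NULL) {
  res <- call_bridge("read_sdf",
                     list(path = normalizePath(path), id_prop = id_prop),
                     "sdf.tsv")
  df <- res$sdf
  df$ok <- as.integer(df$ok)
  bad <- df$ok == 0
  if (any(bad)) {
    warn(sprintf("%d SDF record(s) could not be parsed and were dropped",
                 sum(bad)))
  }
  tibble(id = as.character(df$id[!bad]), smiles = as.character(df$smiles[!bad]))
}

#' Standardize structures to their largest fragment
#'
#' Standardization keeps, for each substance, only the fragment with the most
#' heavy atoms (ties broken by canonical-SMILES order) and emits RDKit
#' canonical SMILES. Unparseable records are dropped with a warning naming the
#' offending ids; they are also recorded in the `"dropped"` attribute of the
#' result.
#'
#' @param df A data frame with `id` and `smiles` columns.
#' @return A tibble with columns `id`, `smiles` (canonical largest fragment),
#'   `inchikey`, `n_frags`; attribute `dropped` holds a tibble of rejected
#'   records with reasons.
#' @export
standardize_structures <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "smiles") %in% names(df)))
  if (anyDuplicated(df$id)) abort("compound ids must be unique")
  res <- bridge_process(df$id, df$smiles)
  bad <- res$ok == 0
  if (any(bad)) {
    warn(c(sprintf("%d record(s) rejected during standardization", sum(bad)),
           i = paste("ids:", paste(utils::head(res$id[bad], 10),
                                   collapse = ", "))))
  }
  out <- tibble(id = res$id[!bad],
                smiles = res$smiles_std[!bad],
                inchikey = res$inchikey[!bad],
                n_frags = res$n_frags[!bad])
  attr(out, "dropped") <- tibble(id = res$id[bad], reason = res$error[bad])
  out
}

#' Extract Bemis-Murcko scaffolds
#'
#' Appends the Bemis-Murcko framework (ring systems plus linkers, side chains
#' removed; the toolkit's standard variant, which retains exocyclic
#' double-bonded atoms) and its standard InChI-Key. Acyclic molecules have no
#' scaffold and get `NA` in both columns.
#'
#' @param df A data frame with `id` and `smiles` columns (ideally already
#'   standardized).
#' @return `df` with columns `scaffold_smiles` and `scaffold_inchikey` added.
#' @export
extract_scaffolds <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "smiles") %in% names(df)))
  res <- bridge_process(df$id, df$smiles)
  res <- res[match(df$id, res$id), ]
  scaffold <- ifelse(res$ok == 1 & nzchar(res$bms), res$bms, NA_character_)
  key <- ifelse(is.na(scaffold), NA_character_, res$bms_inchikey)
  df$scaffold_smiles <- scaffold
  df$scaffold_inchikey <- key
  as_tibble(df)
}

#' Standard InChI-Keys for structures
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of 27-character standard InChI-Keys (`NA` where
#'   generation fails).
#' @export
compute_inchikey <- function(smiles) {
  res <- bridge_process(sprintf("K%05d", seq_along(smiles)), smiles)
  ifelse(res$ok == 1, res$inchikey, NA_character_)
}

# Morgan fingerprints as a list of sorted on-bit integer vectors.
morgan_bits <- function(ids, smiles, radius = 3, nbits = 2048) {
  stopifnot(radius >= 0, nbits >= 1)
  fps <- bridge_fp(ids, smiles, radius, nbits)
  if (any(fps$ok == 0)) {
    abort(c("fingerprint generation failed",
            i = paste("ids:", paste(fps$id[fps$ok == 0], collapse = ", "))))
  }
  bits <- lapply(strsplit(fps$bits, " ", fixed = TRUE),
                 function(b) sort(as.integer(b[nzchar(b)])))
  names(bits) <- fps$id
  bits
}

tanimoto_sets <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) {
    warn("both fingerprints are empty; returning similarity 0")
    return(0)
  }
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Morgan/Tanimoto similarity of two structures
#'
#' Tanimoto coefficient of binary Morgan (ECFP-style circular) fingerprints.
#' Defaults follow common nearest-neighbor practice: radius 3, 2048 bits.
#'
#' @param smiles_a,smiles_b SMILES of the two structures.
#' @param radius Morgan radius.
#' @param nbits Fingerprint length in bits.
#' @return Similarity in `[0, 1]`.
#' @export
morgan_tanimoto <- function(smiles_a, smiles_b, radius = 3, nbits = 2048) {
  bits <- morgan_bits(c("a", "b"), c(smiles_a, smiles_b), radius, nbits)
  tanimoto_sets(bits[["a"]], bits[["b"]])
}

#' k nearest neighbors by Morgan/Tanimoto similarity
#'
#' Ranks every library member against each query by Tanimoto similarity of
#' Morgan fingerprints. A query present in the library is never returned as
#' its own neighbor. Ties are broken by ascending compound id so rankings are
#' reproducible.
#'
#' @param library A data frame with `id` and `smiles` columns.
#' @param query Optional data frame of queries (defaults to every library
#'   member queried against the rest).
#' @param k Number of neighbors per query.
#' @param radius,nbits Morgan fingerprint parameters.
#' @return A tibble with columns `query_id`, `neighbor_id`, `rank`,
#'   `similarity`.
#' @export
knn_compounds <- function(library, query = NULL, k = 5, radius = 3,
                          nbits = 2048) {
  stopifnot(is.data.frame(library), nrow(library) >= 1)
  if (is.null(query)) query <- library
  lib_bits <- morgan_bits(library$id, library$smiles, radius, nbits)
  qry_bits <- morgan_bits(query$id, query$smiles, radius, nbits)
  out <- purrr::map_dfr(query$id, function(qid) {
    cand <- setdiff(library$id, qid)
    if (k > length(cand)) {
      abort(sprintf("k = %d exceeds library size available for query '%s'",
                    k, qid))
    }
    sims <- vapply(cand, function(cid) {
      tanimoto_sets(qry_bits[[qid]], lib_bits[[cid]])
    }, numeric(1))
    ord <- order(-sims, cand, method = "radix")[seq_len(k)]
    tibble(query_id = qid, neighbor_id = cand[ord], rank = seq_len(k),
           similarity = unname(sims[ord]))
  })
  out
}
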