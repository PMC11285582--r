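#' The 32-key scaffold descriptor registry
#'
#' Each Bemis-Murcko scaffold is described by 32 non-negative integer keys
#' that capture its size, complexity and chemical composition, ordered so
#' that key 1 is the most significant under lexicographic ("alphanumeric")
#' comparison. Sorting scaffolds by the key tuple therefore yields a
#' size-first, complexity-second progression that mirrors how a medicinal
#' chemist would order frameworks. The registry below is this package's
#' documented interpretation of the scaffold-key ruleset; rings are the
#' toolkit's smallest set of smallest rings (SSSR), "heteroatom" means any
#' heavy atom other than carbon, and every key is computed from the scaffold
#' graph alone (no hydrogens, no stereochemistry).
#'
#' | key | definition |
#' |----:|:-----------|
#' | 1 | heavy atoms |
#' | 2 | ring atoms |
#' | 3 | acyclic (linker) atoms |
#' | 4 | rings (SSSR) |
#' | 5 | ring systems (rings connected through ring bonds or spiro atoms) |
#' | 6 | size of the largest ring |
#' | 7 | atoms in the largest ring system |
#' | 8 | fusion bonds (bonds shared by two or more rings) |
#' | 9 | spiro atoms (atoms in two or more rings with four or more ring bonds) |
#' | 10 | ring-junction atoms (three or more ring bonds) |
#' | 11 | aromatic rings |
#' | 12 | non-aromatic rings |
#' | 13 | heteroatoms |
#' | 14 | ring heteroatoms |
#' | 15 | nitrogen atoms |
#' | 16 | ring nitrogen atoms |
#' | 17 | oxygen atoms |
#' | 18 | ring oxygen atoms |
#' | 19 | sulfur atoms |
#' | 20 | ring sulfur atoms |
#' | 21 | heteroatoms other than N, O, S |
#' | 22 | non-aromatic double bonds |
#' | 23 | triple bonds |
#' | 24 | exocyclic multiple bonds attached to a ring atom |
#' | 25 | rings containing at least one heteroatom |
#' | 26 | five-membered rings |
#' | 27 | six-membered rings |
#' | 28 | rings of any other size |
#' | 29 | bonds between two heteroatoms |
#' | 30 | branching atoms (heavy-atom degree three or more) |
#' | 31 | acyclic bonds |
#' | 32 | atoms carrying a formal charge |
#'
#' @name scaffold_key_registry
#' @keywords internal
NULL

sk_cols <- function() sprintf("sk%02d", 1:32)

#' Compute scaffold-key vectors
#'
#' Appends the 32 integer scaffold keys (columns `sk01` ... `sk32`, see
#' [scaffold_key_registry]) for each scaffold SMILES. Scaffolds must contain
#' at least one ring; records whose keys cannot be computed are dropped with
#' a warning and recorded in the `"sk_failed"` attribute.
#'
#' @param df A data frame with a scaffold SMILES column.
#' @param smiles_col Name of that column (default `"scaffold_smiles"`, falling
#'   back to `"smiles"`).
#' @return `df` with 32 key columns appended.
#' @export
compute_scaffold_keys <- function(df, smiles_col = NULL) {
  stopifnot(is.data.frame(df))
  smiles_col <- smiles_col %||%
    (if ("scaffold_smiles" %in% names(df)) "scaffold_smiles" else "smiles")
  smiles <- df[[smiles_col]]
  if (is.null(smiles)) abort(sprintf("column '%s' not found", smiles_col))
  keep <- !is.na(smiles)
  uniq <- unique(smiles[keep])
  keys <- scaffold_keys_for(uniq)
  ok <- !is.na(keys[, 1L])
  if (any(!ok)) {
    warn(sprintf("%d scaffold(s) failed key perception and were dropped",
                 sum(!ok)))
  }
  idx <- match(smiles, uniq)
  km <- keys[idx, , drop = FALSE]
  out <- df[keep & !is.na(km[, 1L]), , drop = FALSE]
  attr_failed <- df[keep & is.na(km[, 1L]), , drop = FALSE]
  km <- km[keep & !is.na(km[, 1L]), , drop = FALSE]
  for (j in seq_len(32)) out[[sk_cols()[j]]] <- as.integer(km[, j])
  out <- as_tibble(out)
  attr(out, "sk_failed") <- as_tibble(attr_failed)
  out
}

# 32 keys for unique scaffold SMILES; returns a numeric matrix (NA row where
# the scaffold has no ring, which a valid Bemis-Murcko framework cannot have).
scaffold_keys_for <- function(smiles) {
  n_mol <- length(smiles)
  out <- matrix(NA_real_, nrow = n_mol, ncol = 32)
  if (n_mol == 0) return(out)
  g <- bridge_graphs(smiles)
  atoms <- g$atoms
  bonds <- g$bonds
  rings <- g$rings

  acc <- function(tab, expr_cols) {
    m <- matrix(0, nrow = n_mol, ncol = length(expr_cols))
    colnames(m) <- names(expr_cols)
    if (nrow(tab) > 0) {
      for (nm in names(expr_cols)) {
        v <- tapply(expr_cols[[nm]], factor(tab$mol, levels = 0:(n_mol - 1)),
                    sum)
        v[is.na(v)] <- 0
        m[, nm] <- v
      }
    }
    m
  }

  hetero <- function(anum) anum != 6
  a_cnt <- acc(atoms, list(
    k1 = rep(1, nrow(atoms)),
    k2 = atoms$in_ring,
    k3 = 1 - atoms$in_ring,
    k13 = as.numeric(hetero(atoms$anum)),
    k14 = as.numeric(hetero(atoms$anum) & atoms$in_ring == 1),
    k15 = as.numeric(atoms$anum == 7),
    k16 = as.numeric(atoms$anum == 7 & atoms$in_ring == 1),
    k17 = as.numeric(atoms$anum == 8),
    k18 = as.numeric(atoms$anum == 8 & atoms$in_ring == 1),
    k19 = as.numeric(atoms$anum == 16),
    k20 = as.numeric(atoms$anum == 16 & atoms$in_ring == 1),
    k21 = as.numeric(!atoms$anum %in% c(6, 7, 8, 16)),
    k30 = as.numeric(atoms$degree >= 3),
    k32 = as.numeric(atoms$charge != 0)
  ))

  aid <- function(mol, atom) paste(mol, atom, sep = ":")
  anum_of <- stats::setNames(atoms$anum, aid(atoms$mol, atoms$atom))
  inring_of <- stats::setNames(atoms$in_ring, aid(atoms$mol, atoms$atom))
  b_a <- aid(bonds$mol, bonds$a)
  b_b <- aid(bonds$mol, bonds$b)
  b_cnt <- acc(bonds, list(
    k22 = as.numeric(bonds$order == 2 & bonds$aromatic == 0),
    k23 = as.numeric(bonds$order == 3),
    k24 = as.numeric(bonds$in_ring == 0 & bonds$order >= 2 &
                       (inring_of[b_a] == 1 | inring_of[b_b] == 1)),
    k29 = as.numeric(hetero(anum_of[b_a]) & hetero(anum_of[b_b])),
    k31 = as.numeric(bonds$in_ring == 0)
  ))

  # per-ring summaries
  if (nrow(rings) > 0) {
    rkey <- paste(rings$mol, rings$ring, sep = ":")
    ring_mol <- as.integer(vapply(strsplit(unique(rkey), ":"), `[[`,
                                  character(1), 1L))
    names(ring_mol) <- unique(rkey)
    size <- tapply(rep(1, nrow(rings)), rkey, sum)
    r_atom <- aid(rings$mol, rings$atom)
    arom <- tapply(atoms$aromatic[match(r_atom, aid(atoms$mol, atoms$atom))],
                   rkey, function(x) all(x == 1))
    het <- tapply(hetero(anum_of[r_atom]), rkey, any)
    ring_ids <- names(size)
    ring_tab <- tibble(mol = unname(ring_mol[ring_ids]),
                       size = as.numeric(size),
                       arom = as.logical(arom[ring_ids]),
                       het = as.logical(het[ring_ids]))
    r_cnt <- acc(ring_tab, list(
      k4 = rep(1, nrow(ring_tab)),
      k11 = as.numeric(ring_tab$arom),
      k12 = as.numeric(!ring_tab$arom),
      k25 = as.numeric(ring_tab$het),
      k26 = as.numeric(ring_tab$size == 5),
      k27 = as.numeric(ring_tab$size == 6),
      k28 = as.numeric(!ring_tab$size %in% c(5, 6))
    ))
    k6 <- tapply(ring_tab$size, factor(ring_tab$mol, levels = 0:(n_mol - 1)),
                 max)
    k6[is.na(k6)] <- 0
  } else {
    r_cnt <- matrix(0, n_mol, 7,
                    dimnames = list(NULL, c("k4", "k11", "k12", "k25", "k26",
                                            "k27", "k28")))
    k6 <- rep(0, n_mol)
  }

  # fusion bonds: ring bonds whose endpoints co-occur in >= 2 SSSR rings
  ring_bonds <- bonds[bonds$in_ring == 1, , drop = FALSE]
  k8 <- rep(0, n_mol)
  atom_ringdeg <- stats::setNames(rep(0, nrow(atoms)),
                                  aid(atoms$mol, atoms$atom))
  if (nrow(ring_bonds) > 0) {
    rb_a <- aid(ring_bonds$mol, ring_bonds$a)
    rb_b <- aid(ring_bonds$mol, ring_bonds$b)
    deg_tab <- table(c(rb_a, rb_b))
    atom_ringdeg[names(deg_tab)] <- as.numeric(deg_tab)
    if (nrow(rings) > 0) {
      # rings containing both bond endpoints, via two membership joins
      rb <- tibble(bid = seq_len(nrow(ring_bonds)), mol = ring_bonds$mol,
                   a = ring_bonds$a, b = ring_bonds$b)
      rmem <- tibble(mol = rings$mol, ring = rings$ring, atom = rings$atom)
      ja <- dplyr::inner_join(rb, rmem, by = c("mol", "a" = "atom"),
                              relationship = "many-to-many")
      jb <- dplyr::inner_join(ja[, c("bid", "mol", "b", "ring")], rmem,
                              by = c("mol", "ring", "b" = "atom"))
      n_in <- tabulate(jb$bid, nbins = nrow(ring_bonds))
      fus <- tapply(as.numeric(n_in >= 2),
                    factor(ring_bonds$mol, levels = 0:(n_mol - 1)), sum)
      fus[is.na(fus)] <- 0
      k8 <- as.numeric(fus)
    }
  }

  ring_count_atom <- stats::setNames(rep(0, nrow(atoms)),
                                     aid(atoms$mol, atoms$atom))
  if (nrow(rings) > 0) {
    rc <- table(aid(rings$mol, rings$atom))
    ring_count_atom[names(rc)] <- as.numeric(rc)
  }
  a_key <- aid(atoms$mol, atoms$atom)
  spiro <- as.numeric(ring_count_atom[a_key] >= 2 & atom_ringdeg[a_key] >= 4)
  junction <- as.numeric(atom_ringdeg[a_key] >= 3)
  k9 <- acc(atoms, list(v = spiro))[, "v"]
  k10 <- acc(atoms, list(v = junction))[, "v"]

  # ring systems: connected components of the ring-bond subgraph
  k5 <- rep(0, n_mol)
  k7 <- rep(0, n_mol)
  if (nrow(ring_bonds) > 0) {
    gg <- igraph::graph_from_data_frame(
      data.frame(from = aid(ring_bonds$mol, ring_bonds$a),
                 to = aid(ring_bonds$mol, ring_bonds$b)),
      directed = FALSE
    )
    comp <- igraph::components(gg)
    vmol <- as.integer(sub(":.*$", "", igraph::V(gg)$name))
    sizes <- table(comp$membership)
    comp_mol <- tapply(vmol, comp$membership, `[`, 1L)
    sys_per_mol <- tapply(rep(1, length(sizes)),
                          factor(comp_mol, levels = 0:(n_mol - 1)), sum)
    max_per_mol <- tapply(as.numeric(sizes),
                          factor(comp_mol, levels = 0:(n_mol - 1)), max)
    sys_per_mol[is.na(sys_per_mol)] <- 0
    max_per_mol[is.na(max_per_mol)] <- 0
    k5 <- as.numeric(sys_per_mol)
    k7 <- as.numeric(max_per_mol)
  }

  out[, 1] <- a_cnt[, "k1"]; out[, 2] <- a_cnt[, "k2"]
  out[, 3] <- a_cnt[, "k3"]; out[, 4] <- r_cnt[, "k4"]
  out[, 5] <- k5; out[, 6] <- k6; out[, 7] <- k7; out[, 8] <- k8
  out[, 9] <- k9; out[, 10] <- k10
  out[, 11] <- r_cnt[, "k11"]; out[, 12] <- r_cnt[, "k12"]
  out[, 13] <- a_cnt[, "k13"]; out[, 14] <- a_cnt[, "k14"]
  out[, 15] <- a_cnt[, "k15"]; out[, 16] <- a_cnt[, "k16"]
  out[, 17] <- a_cnt[, "k17"]; out[, 18] <- a_cnt[, "k18"]
  out[, 19] <- a_cnt[, "k19"]; out[, 20] <- a_cnt[, "k20"]
  out[, 21] <- a_cnt[, "k21"]; out[, 22] <- b_cnt[, "k22"]
  out[, 23] <- b_cnt[, "k23"]; out[, 24] <- b_cnt[, "k24"]
  out[, 25] <- r_cnt[, "k25"]; out[, 26] <- r_cnt[, "k26"]
  out[, 27] <- r_cnt[, "k27"]; out[, 28] <- r_cnt[, "k28"]
  out[, 29] <- b_cnt[, "k29"]; out[, 30] <- a_cnt[, "k30"]
  out[, 31] <- b_cnt[, "k31"]; out[, 32] <- a_cnt[, "k32"]

  # a scaffold without any ring defeats key perception
  out[r_cnt[, "k4"] == 0, ] <- NA_real_
  out
}

#' Scaffold-key distance
#'
#' Distance between two 32-key vectors: the sum over keys of
#' `sqrt(|a_n - b_n|^3) / n`. A unit difference in key `n` therefore
#' contributes exactly `1/n`, so disagreement in the leading (size) keys
#' dominates. Symmetric, non-negative, and zero exactly on identical vectors.
#'
#' @param a,b Numeric vectors of length 32.
#' @return A non-negative scalar.
#' @export
sk_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 32 || length(b) != 32) {
    abort("scaffold-key vectors must have length 32")
  }
  sum(sqrt(abs(a - b)^3) / seq_len(32))
}

#' Pairwise scaffold-key distances between two key matrices
#'
#' @param a,b Numeric matrices with 32 columns (rows are scaffolds).
#' @return A `nrow(a)` by `nrow(b)` distance matrix.
#' @export
sk_distance_matrix <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != 32 || ncol(b) != 32) {
    abort("scaffold-key matrices must have 32 columns")
  }
  d <- matrix(0, nrow(a), nrow(b))
  for (n in seq_len(32)) {
    d <- d + abs(outer(a[, n], b[, n], "-"))^1.5 / n
  }
  d
}

sk_matrix <- function(df) {
  as.matrix(df[, sk_cols(), drop = FALSE])
}

#' Sort scaffolds into their reference ordering
#'
#' Orders scaffold records by lexicographic comparison of the 32-key tuple
#' (key 1 most significant) and breaks ties by the standard InChI-Key,
#' compared bytewise (C locale). Residual ties after the InChI-Key are
#' resolved by input order with a warning. Ranks `1..n` are assigned after
#' sorting.
#'
#' @param df A data frame carrying key columns `sk01..sk32` and an `inchikey`
#'   column.
#' @return `df` sorted, with a `rank` column prepended.
#' @export
sort_scaffolds <- function(df) {
  need <- c(sk_cols(), "inchikey")
  if (!all(need %in% names(df))) {
    abort("sort_scaffolds needs columns sk01..sk32 and inchikey")
  }
  keys <- unname(lapply(c(sk_cols(), "inchikey"), function(cn) df[[cn]]))
  ord <- do.call(order, c(keys, list(method = "radix")))
  out <- df[ord, , drop = FALSE]
  full_key <- do.call(paste, c(out[c(sk_cols(), "inchikey")], sep = "|"))
  if (anyDuplicated(full_key)) {
    warn("residual ordering ties beyond the InChI-Key; resolved by input order")
  }
  out$rank <- NULL
  out <- tibble::add_column(as_tibble(out), rank = seq_len(nrow(out)),
                            .before = 1)
  out
}

#' Deduplicate scaffolds by their key vectors
#'
#' Keeps one representative per distinct 32-key vector: the record with the
#' bytewise-smallest InChI-Key. Input order of the surviving records is
#' preserved.
#'
#' @param df A data frame with key columns `sk01..sk32` and `inchikey`.
#' @return The deduplicated tibble.
#' @export
dedup_scaffolds <- function(df) {
  need <- c(sk_cols(), "inchikey")
  if (!all(need %in% names(df))) {
    abort("dedup_scaffolds needs columns sk01..sk32 and inchikey")
  }
  key <- do.call(paste, c(df[sk_cols()], sep = "|"))
  ord <- order(key, df$inchikey, method = "radix")
  first <- ord[!duplicated(key[ord])]
  as_tibble(df[sort(first), , drop = FALSE])
}
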