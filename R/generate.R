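# Ring-unit grammar used by the synthetic scaffold generator. Internal units
# expose one attachment point written as {R}; terminal units close a chain.
# Two-ring (fused) units give the grammar a 1..5-ring size gradient, which is
# what makes the scaffold-key ordering of generated sets non-trivial.
grammar_units <- function() {
  list(
    benzene     = list(end = "c1ccccc1",        mid = "c1ccc({R})cc1",
                       rings = 1L),
    pyridine    = list(end = "c1ccncc1",        mid = "c1cnc({R})cc1",
                       rings = 1L),
    cyclohexane = list(end = "C1CCCCC1",        mid = "C1CCC({R})CC1",
                       rings = 1L),
    piperidine  = list(end = "C1CCNCC1",        mid = "C1CCC({R})NC1",
                       rings = 1L),
    oxane       = list(end = "C1CCOCC1",        mid = "C1CCC({R})OC1",
                       rings = 1L),
    naphthalene = list(end = "c1ccc2ccccc2c1",  mid = "c1ccc2cc({R})ccc2c1",
                       rings = 2L),
    quinoline   = list(end = "n1ccc2ccccc2c1",  mid = "c1cc2ccccc2nc1{R}",
                       rings = 2L),
    decalin     = list(end = "C1CCC2CCCCC2C1",  mid = "C1CCC2CC({R})CCC2C1",
                       rings = 2L)
  )
}

# assemble one random chain-linked scaffold SMILES (1..5 rings total)
sample_scaffold_smiles <- function(units, linker_lengths) {
  n_units <- sample.int(4L, 1L, prob = c(0.3, 0.3, 0.25, 0.15))
  picks <- sample(names(units), n_units, replace = TRUE)
  total_rings <- sum(vapply(picks, function(u) units[[u]]$rings, integer(1)))
  while (total_rings > 5L && length(picks) > 1L) {
    picks <- picks[-length(picks)]
    total_rings <- sum(vapply(picks, function(u) units[[u]]$rings, integer(1)))
  }
  smi <- units[[picks[length(picks)]]]$end
  if (length(picks) > 1L) {
    for (u in rev(picks[-length(picks)])) {
      linker <- strrep("C", sample(linker_lengths, 1L))
      smi <- sub("{R}", paste0(linker, smi), units[[u]]$mid, fixed = TRUE)
    }
  }
  smi
}

#' Generate a deterministic synthetic scaffold set
#'
#' Assembles valid, ring-bearing, constitutionally distinct scaffolds from a
#' small grammar: benzene / pyridine / cyclohexane / piperidine / oxane
#' single-ring units and naphthalene / quinoline / decalin fused units,
#' chain-linked through alkyl linkers of length 0-4, for a total of 1-5 rings
#' per scaffold. The size/complexity gradient makes the scaffold-key ordering
#' of the set non-degenerate. Output is byte-identical for a given seed.
#'
#' @param n Number of distinct scaffolds.
#' @param seed Integer seed (no global RNG state is touched).
#' @param linker_lengths Allowed alkyl linker lengths.
#' @return A tibble with columns `id` (`SC...`) and `smiles` (RDKit
#'   canonical, deduplicated).
#' @export
generate_scaffolds <- function(n, seed, linker_lengths = 0:4) {
  stopifnot(n >= 1)
  units <- grammar_units()
  seen <- character(0)
  tried <- character(0)
  withr::with_seed(seed, {
    for (round in 1:40) {
      cand <- vapply(seq_len(max(2L * n, 64L)), function(i) {
        sample_scaffold_smiles(units, linker_lengths)
      }, character(1))
      cand <- setdiff(unique(cand), tried)
      tried <- c(tried, cand)
      if (length(cand) > 0) {
        canon <- bridge_process(sprintf("G%06d", seq_along(cand)), cand)
        got <- canon$smiles_std[canon$ok == 1]
        seen <- unique(c(seen, got))
      }
      if (length(seen) >= n) break
    }
  })
  if (length(seen) < n) {
    abort(sprintf("grammar exhausted: only %d distinct scaffolds reachable",
                  length(seen)))
  }
  tibble(id = sprintf("SC%05d", seq_len(n)), smiles = seen[seq_len(n)])
}

#' Generate a decorated compound library over a scaffold set
#'
#' Each compound is a scaffold from `scaffolds` decorated with 0-3 small
#' substituents (methyl, ethyl, hydroxy, amino, halogen, methoxy, nitrile,
#' isopropyl, acetyl by default) at ring carbons. The true parent scaffold is
#' recorded for oracle tests. Deterministic for a given seed.
#'
#' @param scaffolds A data frame with `id` and `smiles` columns.
#' @param n Number of compounds.
#' @param seed Integer seed.
#' @param max_substituents Maximum substituents per compound.
#' @param pool Optional character vector of substituent SMILES.
#' @return A tibble with columns `id` (`CPD...`), `smiles`, `parent_id`,
#'   `n_substituents`.
#' @export
generate_compounds <- function(scaffolds, n, seed, max_substituents = 3,
                               pool = NULL) {
  stopifnot(is.data.frame(scaffolds), nrow(scaffolds) >= 1, n >= 1)
  payload <- list(scaffolds = I(as.character(scaffolds$smiles)),
                  n = as.integer(n), seed = as.integer(seed),
                  max_sub = as.integer(max_substituents))
  if (!is.null(pool)) payload$pool <- I(as.character(pool))
  res <- call_bridge("decorate", payload, "compounds.tsv")$compounds
  tibble(id = sprintf("CPD%05d", as.integer(res$i)),
         smiles = as.character(res$smiles),
         parent_id = scaffolds$id[as.integer(res$parent)],
         n_substituents = as.integer(res$n_sub))
}

#' Cherry-pick seed scaffolds with their rank-window neighborhoods
#'
#' Selects seed ranks together with their `window` nearest neighbors in the
#' reference ordering on both sides (so each seed contributes
#' `2 * window + 1` scaffolds). Windows must not overlap and must fit within
#' the space; with 9 seeds and window 50 the marked set has exactly 909
#' members.
#'
#' @param space A `scaffold_space`, or an integer giving the space size when
#'   only the rank arithmetic is needed.
#' @param seed_ranks Integer vector of seed ranks.
#' @param window Number of rank neighbors per side.
#' @return A tibble with columns `rank` and `seed_rank` (plus `smiles`,
#'   `inchikey` when a full space is given), one row per marked scaffold.
#' @export
cherry_pick_set <- function(space, seed_ranks, window = 50) {
  if (inherits(space, "scaffold_space")) {
    size <- nrow(space)
  } else if (is.numeric(space) && length(space) == 1) {
    size <- as.integer(space)
    space <- NULL
  } else {
    abort("space must be a scaffold_space or a single integer size")
  }
  seed_ranks <- sort(as.integer(seed_ranks))
  window <- as.integer(window)
  if (window < 0) abort("window must be >= 0")
  if (any(seed_ranks < 1 + window) || any(seed_ranks > size - window)) {
    abort("a seed window extends beyond the rank range of the space")
  }
  if (length(seed_ranks) > 1 && any(diff(seed_ranks) <= 2 * window)) {
    abort("seed windows overlap; seeds must be separated by more than 2*window")
  }
  out <- purrr::map_dfr(seed_ranks, function(r) {
    tibble(rank = (r - window):(r + window), seed_rank = r)
  })
  if (!is.null(space)) {
    out$smiles <- space$smiles[out$rank]
    out$inchikey <- space$inchikey[out$rank]
  }
  out
}
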