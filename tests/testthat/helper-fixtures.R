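# Shared synthetic world for the unit tests: a 60-scaffold reference space
# and an 80-compound decorated library. Built once per test run; the bridge
# memoises repeated chemistry calls within the session.
fx_scaffolds <- generate_scaffolds(60, seed = 101)
fx_space <- build_reference_space(fx_scaffolds, source_label = "fixture60")
fx_library <- generate_compounds(fx_scaffolds, 80, seed = 202)
fx_embedding <- suppressMessages(embed_library(fx_library, fx_space, z = 4))

# Purely synthetic scaffold records (no chemistry): 32-key rows with fake
# InChI-Keys, for ordering/dedup/nearest tests that need exact key control.
synthetic_records <- function(key_rows, inchikeys) {
  stopifnot(length(key_rows) == length(inchikeys))
  df <- tibble::tibble(
    id = sprintf("SYN%03d", seq_along(key_rows)),
    smiles = sprintf("synthetic-%03d", seq_along(key_rows)),
    inchikey = inchikeys
  )
  km <- do.call(rbind, key_rows)
  stopifnot(ncol(km) == 32)
  for (j in 1:32) df[[sprintf("sk%02d", j)]] <- as.integer(km[, j])
  df
}

base_key <- function(...) {
  v <- rep(0L, 32)
  mods <- list(...)
  for (nm in names(mods)) v[as.integer(nm)] <- as.integer(mods[[nm]])
  v
}

fake_ik <- function(ch) {
  vapply(ch, function(c1) paste0(strrep(c1, 14), "-", strrep(c1, 10), "-N"),
         character(1), USE.NAMES = FALSE)
}

sk_matrix_public <- function(df) as.matrix(df[, sprintf("sk%02d", 1:32)])
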