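test_that("standardization keeps the largest fragment and is idempotent", {
  df <- tibble::tibble(
    id = c("a", "b", "c"),
    smiles = c("CCO", "CCO.[Na+].[Cl-]", "c1ccccc1.O")
  )
  std <- standardize_structures(df)
  expect_equal(std$smiles, c("CCO", "CCO", "c1ccccc1"))
  expect_equal(std$n_frags, c(1L, 3L, 2L))
  # idempotence: standardizing the standardized output changes nothing
  again <- standardize_structures(std[, c("id", "smiles")])
  expect_equal(again$smiles, std$smiles)
  # fixture-wide idempotence
  std_fx <- standardize_structures(fx_library[1:20, ])
  again_fx <- standardize_structures(std_fx[, c("id", "smiles")])
  expect_equal(again_fx$smiles, std_fx$smiles)
})

test_that("unparseable structures are rejected with their ids", {
  df <- tibble::tibble(id = c("ok", "bad"), smiles = c("CCO", "not_a_smiles"))
  expect_warning(std <- standardize_structures(df), "rejected")
  expect_equal(std$id, "ok")
  expect_equal(attr(std, "dropped")$id, "bad")
})

test_that("scaffold extraction implements the Bemis-Murcko rule", {
  df <- tibble::tibble(
    id = c("ethylbenzene", "benzene", "hexane"),
    smiles = c("CCc1ccccc1", "c1ccccc1", "CCCCCC")
  )
  scaf <- extract_scaffolds(df)
  expect_equal(scaf$scaffold_smiles[1], "c1ccccc1")  # side chain removed
  expect_equal(scaf$scaffold_smiles[2], "c1ccccc1")  # bare ring is itself
  expect_true(is.na(scaf$scaffold_smiles[3]))        # acyclic: no scaffold
  # scaffold of a scaffold is itself, across the fixture scaffolds
  own <- extract_scaffolds(tibble::tibble(id = fx_scaffolds$id[1:15],
                                          smiles = fx_scaffolds$smiles[1:15]))
  twice <- extract_scaffolds(tibble::tibble(id = own$id,
                                            smiles = own$scaffold_smiles))
  expect_equal(twice$scaffold_smiles, own$scaffold_smiles)
})

test_that("InChI-Keys are standard, deterministic and discriminating", {
  keys <- compute_inchikey(c("c1ccccc1", "c1ccccc1", "c1ccncc1"))
  expect_equal(keys[1], "UHOVQNZJYSORNB-UHFFFAOYSA-N")
  expect_equal(keys[1], keys[2])
  expect_false(keys[1] == keys[3])
  expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", keys)))
  # constitutionally distinct fixture scaffolds get distinct keys
  fk <- compute_inchikey(fx_scaffolds$smiles[1:20])
  expect_equal(anyDuplicated(fk), 0L)
})

test_that("Morgan/Tanimoto similarity is a bounded symmetric self-identity", {
  expect_equal(morgan_tanimoto("CCc1ccccc1", "CCc1ccccc1"), 1.0)
  ab <- morgan_tanimoto("CCc1ccccc1", "c1ccncc1")
  ba <- morgan_tanimoto("c1ccncc1", "CCc1ccccc1")
  expect_equal(ab, ba)
  pairs <- utils::combn(fx_library$smiles[1:8], 2)
  sims <- apply(pairs, 2, function(p) morgan_tanimoto(p[1], p[2]))
  expect_true(all(sims >= 0 & sims <= 1))
})

test_that("knn agrees with a brute-force similarity sort", {
  toy <- tibble::tibble(
    id = c("m1", "m2", "m3", "m4", "m5", "m6"),
    smiles = c("CCc1ccccc1", "Cc1ccccc1", "c1ccccc1", "C1CCCCC1",
               "c1ccncc1", "CCCCO")
  )
  got <- knn_compounds(toy, query = toy[1, ], k = 5)
  # brute-force oracle: all pairwise similarities, sorted
  sims <- vapply(toy$id[-1], function(cid) {
    morgan_tanimoto(toy$smiles[1], toy$smiles[toy$id == cid])
  }, numeric(1))
  ord <- order(-sims, names(sims), method = "radix")
  expect_equal(got$neighbor_id, names(sims)[ord])
  expect_equal(got$similarity, unname(sims[ord]))
  expect_equal(got$rank, 1:5)
  # an exact duplicate ranks first with similarity 1
  dup <- dplyr::bind_rows(toy, tibble::tibble(id = "m1copy",
                                              smiles = toy$smiles[1]))
  got2 <- knn_compounds(dup, query = dup[1, ], k = 3)
  expect_equal(got2$neighbor_id[1], "m1copy")
  expect_equal(got2$similarity[1], 1.0)
  # k = |library| - 1 returns a permutation of the remaining ids
  full <- knn_compounds(toy, query = toy[1, ], k = 5)
  expect_setequal(full$neighbor_id, toy$id[-1])
  # k too large errors
  expect_error(knn_compounds(toy, query = toy[1, ], k = 6), "exceeds")
})

test_that("smiles and delimited readers roundtrip", {
  path <- withr::local_tempfile(fileext = ".smi")
  write_smiles(fx_scaffolds[1:5, ], path)
  back <- read_smiles(path)
  expect_equal(back$smiles, fx_scaffolds$smiles[1:5])
  expect_equal(back$id, fx_scaffolds$id[1:5])
  # ids are generated when missing
  writeLines(c("CCO", "c1ccccc1 benz"), path)
  got <- read_smiles(path)
  expect_equal(got$id, c("MOL00001", "benz"))
  # delimited reader with named columns
  tpath <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(name = c("x1"), structure = c("CCO")), tpath)
  tab <- read_compound_table(tpath, smiles_col = "structure", id_col = "name")
  expect_equal(tab$smiles, "CCO")
})
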