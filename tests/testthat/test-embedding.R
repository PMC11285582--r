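test_that("reference space construction ranks, drops and deduplicates", {
  ten <- fx_scaffolds[1:10, ]
  space <- build_reference_space(ten, source_label = "ten")
  expect_s3_class(space, "scaffold_space")
  expect_equal(space$rank, 1:10)
  # acyclic input is eliminated and counted
  with_hexane <- dplyr::bind_rows(ten,
                                  tibble::tibble(id = "hex", smiles = "CCCCCC"))
  space2 <- build_reference_space(with_hexane)
  expect_equal(nrow(space2), 10)
  expect_equal(attr(space2, "n_dropped"), 1L)
  expect_error(build_reference_space(tibble::tibble(id = "h",
                                                    smiles = "CCCCCC")),
               "no scaffold")
})

test_that("space construction is deterministic and order-independent", {
  shuffled <- fx_scaffolds[withr::with_seed(5, sample.int(nrow(fx_scaffolds))), ]
  space_a <- build_reference_space(fx_scaffolds, source_label = "det")
  space_b <- build_reference_space(shuffled, source_label = "det")
  expect_equal(space_a$smiles, space_b$smiles)
  expect_equal(attr(space_a, "checksum"), attr(space_b, "checksum"))
  # byte-identical space files
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_space(space_a, fa)
  write_space(space_b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("space files roundtrip and detect tampering", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_space(fx_space, path)
  back <- read_space(path)
  expect_equal(back$smiles, fx_space$smiles)
  expect_equal(sk_matrix_public(back), sk_matrix_public(fx_space))
  expect_equal(attr(back, "checksum"), attr(fx_space, "checksum"))
  # flip one key value: checksum must catch it
  lines <- readLines(path)
  body_at <- length(lines)
  fields <- strsplit(lines[body_at], "\t")[[1]]
  fields[4] <- as.character(as.integer(fields[4]) + 1L)
  lines[body_at] <- paste(fields, collapse = "\t")
  writeLines(lines, path)
  expect_error(read_space(path), "checksum mismatch")
})

test_that("nearest reference matches a brute-force scan and breaks ties low", {
  space20 <- build_reference_space(fx_scaffolds[1:20, ], source_label = "s20")
  rec <- scaffold_records(fx_library[1:25, ])
  nn <- nearest_reference(rec, space20)
  ref_keys <- sk_matrix_public(space20)
  for (i in seq_len(nrow(rec))) {
    d <- apply(ref_keys, 1, sk_distance, b = sk_matrix_public(rec)[i, ])
    expect_equal(nn$d_sk[i], min(d))
    expect_equal(nn$nearest_rank[i], which.min(d))  # first = lowest rank
  }
  # a reference scaffold queried against its own space is its own neighbor
  self <- nearest_reference(space20, space20)
  expect_equal(self$nearest_rank, space20$rank)
  expect_equal(self$d_sk, rep(0, nrow(space20)))
  # equidistant references: the lower rank wins
  refs <- synthetic_records(list(base_key(`1` = 4), base_key(`1` = 8)),
                            fake_ik(c("A", "B")))
  syn_space <- build_reference_space(refs, source_label = "tie")
  q <- synthetic_records(list(base_key(`1` = 6)), fake_ik("Q"))
  tie <- nearest_reference(q, syn_space)
  expect_equal(tie$nearest_rank, 1L)
})

test_that("embedding composes the defined maps and skips scaffold-less input", {
  emb <- fx_embedding
  l <- attr(emb, "bin_width")
  # every row is the composition bin_index -> hilbert_coords
  expect_equal(emb$bin, bin_index(emb$nearest_rank, l))
  co <- hilbert_coords(emb$bin, attr(emb, "z"))
  expect_equal(emb$x, co$x)
  expect_equal(emb$y, co$y)
  # compounds sharing a scaffold share a coordinate
  sib <- dplyr::add_count(tibble::as_tibble(emb), scaffold_smiles)
  sib <- dplyr::filter(sib, n > 1)
  if (nrow(sib) > 0) {
    per <- dplyr::summarise(dplyr::group_by(sib, scaffold_smiles),
                            nx = dplyr::n_distinct(x),
                            ny = dplyr::n_distinct(y))
    expect_true(all(per$nx == 1 & per$ny == 1))
  }
  # an undecorated reference scaffold lands exactly at its own rank's cell
  r <- 7L
  probe <- tibble::tibble(id = "probe", smiles = fx_space$smiles[r])
  got <- suppressMessages(embed_library(probe, fx_space, z = 4))
  expect_equal(got$nearest_rank, r)
  expect_equal(got$d_sk, 0)
  want <- hilbert_coords(bin_index(r, bin_size(nrow(fx_space), 4)), 4)
  expect_equal(got$x, want$x)
  expect_equal(got$y, want$y)
  # acyclic compounds are skipped and reported, not fatal
  with_bad <- dplyr::bind_rows(fx_library[1:3, ],
                               tibble::tibble(id = "hex", smiles = "CCCCCC"))
  got2 <- suppressMessages(embed_library(with_bad, fx_space, z = 4))
  expect_equal(nrow(got2), 3)
  expect_true("hex" %in% attr(got2, "skipped")$id)
})

test_that("a compound's position is independent of its batch", {
  sub <- suppressMessages(embed_library(fx_library[1:10, ], fx_space, z = 4))
  full <- tibble::as_tibble(fx_embedding)
  merged <- dplyr::left_join(tibble::as_tibble(sub), full, by = "id",
                             suffix = c("_sub", "_full"))
  expect_equal(merged$x_sub, merged$x_full)
  expect_equal(merged$y_sub, merged$y_full)
  expect_equal(merged$bin_sub, merged$bin_full)
  # and identical reruns are identical
  again <- suppressMessages(embed_library(fx_library, fx_space, z = 4))
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(fx_embedding))
})

test_that("embedding files roundtrip with their grid header", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(fx_embedding, path)
  back <- read_embedding(path)
  expect_equal(tibble::as_tibble(back)[, c("id", "bin", "x", "y")],
               tibble::as_tibble(fx_embedding)[, c("id", "bin", "x", "y")])
  expect_equal(attr(back, "z"), attr(fx_embedding, "z"))
  expect_equal(attr(back, "bin_width"), attr(fx_embedding, "bin_width"))
  expect_equal(attr(back, "space_checksum"),
               attr(fx_embedding, "space_checksum"))
})

test_that("normalized coordinates stabilize as the order grows", {
  prof <- convergence_profile(fx_library, fx_space, z_range = 2:6)
  expect_equal(nrow(prof), 4)
  expect_true(all(diff(prof$mean_displacement) < 0))
})
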