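test_that("rank distance is the absolute bin difference", {
  expect_equal(rank_distance(5L, 2L), 3L)
  expect_equal(rank_distance(4L, 4L), 0L)
  expect_equal(rank_distance(c(1L, 9L), c(9L, 1L)), c(8L, 8L))  # symmetric
})

test_that("Chebyshev distance is a metric on the grid", {
  expect_equal(chebyshev_distance(0, 0, 3, 1), 3)
  expect_equal(chebyshev_distance(2, 5, 2, 5), 0)
  # triangle inequality, exhaustively on the 8x8 grid
  pts <- expand.grid(x = 0:7, y = 0:7)
  n <- nrow(pts)
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    chebyshev_distance(pts$x[i], pts$y[i], pts$x[j], pts$y[j])
  })
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0))
  for (k in seq_len(n)) {
    expect_true(all(d <= outer(d[, k], d[k, ], "+")))
  }
})

test_that("embedding vectors conserve compound counts", {
  ev <- embedding_vector(fx_embedding)
  expect_length(ev, 4^attr(fx_embedding, "z"))
  expect_equal(sum(ev), nrow(fx_embedding))
  expect_true(all(ev >= 0))
  # empty embedding: all-zero vector
  empty <- tibble::tibble(bin = integer(0))
  expect_equal(sum(embedding_vector(empty, z = 3)), 0)
  expect_length(embedding_vector(empty, z = 3), 64)
  # three compounds in one bin
  three <- tibble::tibble(bin = c(5L, 5L, 5L))
  ev3 <- embedding_vector(three, z = 2)
  expect_equal(ev3[6], 3L)
  expect_equal(sum(ev3), 3L)
  # declared z must match the embedding's z
  expect_error(embedding_vector(fx_embedding, z = 5), "generated at")
})

test_that("the overlap statistic behaves like a count-vector Tanimoto", {
  a <- embedding_vector(fx_embedding)
  expect_equal(theta_overlap(a, a), 1)
  # worked example: A = (1,1,0), B = (1,0,1) -> 1 / (2 + 2 - 1) = 1/3
  expect_equal(theta_overlap(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  # disjoint supports
  expect_equal(theta_overlap(c(2, 0, 0, 1), c(0, 3, 1, 0)), 0)
  # symmetry and bounds on random integer vectors
  withr::with_seed(11, {
    for (i in 1:20) {
      u <- rpois(32, 1); v <- rpois(32, 1)
      if (sum(u) + sum(v) == 0) next
      th <- theta_overlap(u, v)
      expect_equal(th, theta_overlap(v, u))
      expect_gte(th, 0); expect_lte(th, 1)
    }
  })
  expect_error(theta_overlap(c(0, 0), c(0, 0)), "undefined")
  expect_error(theta_overlap(c(1, 0), c(1, 0, 0)), "length")
  # different spaces are refused
  b <- a
  attr(b, "space_checksum") <- "different"
  expect_error(theta_overlap(a, b), "different reference spaces")
})

test_that("distance correlation matches a brute-force oracle", {
  emb <- tibble::as_tibble(fx_embedding)[1:30, ]
  got <- distance_correlation(emb)
  # brute force over all unordered pairs
  dr <- c(); dc <- c()
  for (i in 1:29) for (j in (i + 1):30) {
    dr <- c(dr, abs(emb$bin[i] - emb$bin[j]))
    dc <- c(dc, max(abs(emb$x[i] - emb$x[j]), abs(emb$y[i] - emb$y[j])))
  }
  expect_equal(got$estimate, cor(dr, dc))
  expect_equal(got$n_pairs, 435L)
  # kendall agrees with the oracle too
  got_k <- distance_correlation(emb, method = "kendall")
  expect_equal(got_k$estimate, cor(dr, dc, method = "kendall"))
  # row order of the input is irrelevant
  perm <- withr::with_seed(3, sample.int(nrow(emb)))
  expect_equal(distance_correlation(emb[perm, ])$estimate, got$estimate)
})

test_that("a monotone layout correlates perfectly and degeneracy warns", {
  diag_emb <- tibble::tibble(bin = 0:9, x = 0:9, y = 0:9)
  expect_equal(distance_correlation(diag_emb)$estimate, 1)
  const <- tibble::tibble(bin = rep(3L, 5), x = rep(1L, 5), y = rep(1L, 5))
  expect_warning(got <- distance_correlation(const), "undefined")
  expect_true(is.na(got$estimate))
})

test_that("subset protocol draws seeded non-overlapping subsets", {
  emb <- tibble::as_tibble(fx_embedding)
  got <- distance_correlation(emb, subset_size = 20, n_subsets = 3, seed = 42)
  expect_equal(nrow(got), 3)
  expect_equal(got$n, rep(20L, 3))
  g <- glance(got)
  expect_equal(g$mean, mean(got$estimate))
  expect_equal(g$sd, sd(got$estimate))
  # reproducible under the same seed
  again <- distance_correlation(emb, subset_size = 20, n_subsets = 3,
                                seed = 42)
  expect_equal(got$estimate, again$estimate)
  expect_error(
    distance_correlation(emb, subset_size = 50, n_subsets = 2, seed = 1),
    "non-overlapping")
})

test_that("coverage matrices count and binarize occupancy", {
  m <- coverage_matrix(fx_embedding)
  expect_equal(sum(m), nrow(fx_embedding))
  mb <- coverage_matrix(fx_embedding, binarize = TRUE)
  expect_true(all(mb %in% c(0L, 1L)))
  occupied <- nrow(dplyr::distinct(tibble::as_tibble(fx_embedding), x, y))
  expect_equal(sum(mb), occupied)
  # occupied cells equal the support of the embedding vector
  expect_equal(sum(mb), sum(embedding_vector(fx_embedding) > 0))
  # cells hold exact per-coordinate counts
  one <- tibble::as_tibble(fx_embedding)[1, ]
  expect_gte(m[one$y + 1, one$x + 1], 1L)
})

test_that("result objects tidy, glance and plot", {
  expect_s3_class(tidy(fx_space), "tbl_df")
  expect_equal(glance(fx_space)$n_scaffolds, nrow(fx_space))
  g <- glance(fx_embedding)
  expect_equal(g$z, 4L)
  expect_equal(g$n_embedded, nrow(fx_embedding))
  p <- autoplot(fx_embedding)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_coverage(coverage_matrix(fx_embedding)), "ggplot")
  expect_s3_class(plot_space_curve(fx_space, 4), "ggplot")
})
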