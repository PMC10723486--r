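toy_traj <- function(vals, genes = "g1") {
  k <- if (is.matrix(vals)) nrow(vals) else length(vals)
  v <- if (is.matrix(vals)) vals else matrix(vals, k, 1)
  colnames(v) <- genes
  spots <- sprintf("s%d", seq_len(k))
  rownames(v) <- spots
  structure(list(values = v,
                 path = structure(list(spots = spots, cost = 1, k = k),
                                  class = "traversal_path"),
                 gene_ids = genes, set_sizes = rep(1L, k)),
            class = "trajectory_matrix")
}

test_that("length normalization yields 101 rows, exact endpoints, bounded values", {
  nt <- length_normalize(toy_traj(c(0, 1, 0)))
  expect_equal(nrow(nt$values), 101)
  expect_equal(nt$positions, seq(0, 1, by = 0.01))
  expect_equal(unname(nt$values["0.25", 1]), 0.5)  # piecewise-linear by hand
  expect_identical(nt$values[1, 1], 0)             # endpoints exact
  expect_identical(nt$values[101, 1], 0)
  expect_true(all(nt$values >= 0 & nt$values <= 1))

  const <- length_normalize(toy_traj(rep(3.5, 4)))
  expect_true(all(const$values == 3.5))

  expect_error(length_normalize(toy_traj(5)), class = "st_degenerate_input")

  # interpolation bounds on a fitted trajectory, and endpoint identity
  sf <- study_fit()
  nt2 <- sf$fit$normalized
  traj <- sf$fit$trajectory
  expect_equal(unname(nt2$values[1, ]), unname(traj$values[1, ]))
  expect_equal(unname(nt2$values[101, ]), unname(traj$values[nrow(traj$values), ]))
  for (j in c(1, 10, 20)) {
    expect_gte(min(nt2$values[, j]), min(traj$values[, j]) - 1e-12)
    expect_lte(max(nt2$values[, j]), max(traj$values[, j]) + 1e-12)
  }
})

test_that("cost spacing stretches the axis by cumulative edge weight", {
  sf <- study_fit()
  nt_u <- length_normalize(sf$fit$trajectory)
  nt_c <- length_normalize(sf$fit$trajectory, spacing = "cost",
                           graph = sf$fit$graph)
  expect_equal(dim(nt_c$values), dim(nt_u$values))
  expect_equal(unname(nt_c$values[1, ]), unname(nt_u$values[1, ]))
  expect_equal(unname(nt_c$values[101, ]), unname(nt_u$values[101, ]))
})

test_that("trajectory averaging produces the stated mean, sd and CI band", {
  t1 <- length_normalize(toy_traj(c(1, 1)))
  t2 <- length_normalize(toy_traj(c(2, 2)))
  t3 <- length_normalize(toy_traj(c(3, 3)))
  avg <- average_trajectories(list(t1, t2, t3))
  expect_true(all(avg$mean == 2))
  expect_true(all(abs(avg$sd - 1) < 1e-12))
  expect_equal(unname(avg$upper[1, 1]), 2 + 1.96 / sqrt(3))

  # two trajectories that are negatives of each other average to zero
  tm <- length_normalize(toy_traj(c(-1, -2)))
  tp <- length_normalize(toy_traj(c(1, 2)))
  expect_true(all(abs(average_trajectories(list(tm, tp))$mean) < 1e-12))

  # single trajectory: mean equals it, band omitted
  a1 <- average_trajectories(list(t1))
  expect_equal(a1$mean, t1$values)
  expect_true(all(is.na(a1$sd)))

  t_other <- length_normalize(toy_traj(c(1, 2), genes = "other"))
  expect_error(average_trajectories(list(t1, t_other)),
               class = "st_contract_error")
})

test_that("pair pools enumerate windowed start/end pairs", {
  g <- make_visium_grid(5, 2, 8)
  A <- g$barcode[g$array_col <= 1]          # left edge, one per row
  B <- g$barcode[g$array_col >= 2]          # right edge
  pool <- build_pair_pool(g, A, B, r = 1)
  expect_equal(nrow(pool$pairs), 13)        # windows of size 2,3,3,3,2
  # each start has at most 2r + 1 partners
  expect_lte(max(table(pool$pairs$start)), 3)
  # starts and ends are sorted ascending by the y pixel coordinate
  y <- g$pxl_row[match(pool$starts, g$barcode)]
  expect_false(is.unsorted(y))

  pool_sat <- build_pair_pool(g, A, B, r = 10)
  expect_equal(nrow(pool_sat$pairs), 25)    # r >= n saturates to n^2

  p1 <- build_pair_pool(g, A[1], B[1], r = 4)
  expect_equal(nrow(p1$pairs), 1)

  expect_error(build_pair_pool(g, character(0), B), class = "st_invalid_argument")
})

test_that("pair sampling is uniform without replacement and seeded", {
  g <- make_visium_grid(5, 2, 8)
  pool <- build_pair_pool(g, g$barcode[g$array_col <= 1],
                          g$barcode[g$array_col >= 2], r = 10)
  z <- sample_pairs(pool, 10, seed = 3)
  expect_equal(nrow(z), 10)
  expect_equal(anyDuplicated(paste(z$start, z$end)), 0)
  expect_identical(sample_pairs(pool, 10, seed = 3), z)
  # exhaustive sample is a permutation of the pool
  zall <- sample_pairs(pool, nrow(pool$pairs), seed = 1)
  expect_setequal(paste(zall$start, zall$end),
                  paste(pool$pairs$start, pool$pairs$end))
  err <- expect_error(sample_pairs(pool, 26, seed = 1),
                      class = "st_invalid_argument")
  expect_match(conditionMessage(err), "25")
})

test_that("spearman concordance matches the rank-difference formula", {
  # oracle: 1 - 6*sum(d^2)/(n*(n^2-1)) on untied data
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  d <- rank(x) - rank(y)
  expect_equal(spearman_concordance(x, y), 1 - 6 * sum(d^2) / (4 * 15))
  expect_equal(spearman_concordance(x, y), 0.8)
  expect_equal(spearman_concordance(x, x), 1)
  expect_equal(spearman_concordance(x, rev(x)), -1)
  expect_error(spearman_concordance(c(1, 1, 1), c(1, 2, 3)),
               class = "st_degenerate_input")
  expect_error(spearman_concordance(1:2, 1:2), class = "st_invalid_argument")
})
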