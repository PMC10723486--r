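test_that("visium grids have the stated shape and hex structure", {
  g <- make_visium_grid(78, 64, 55)
  expect_equal(length(unique(g$array_row)), 78)
  # 64 columns of spots in every row (doubled array_col convention)
  expect_true(all(table(g$array_row) == 64))
  expect_equal(nrow(g), 78 * 64)
  # odd/even rows offset: row parity matches column parity
  expect_true(all(g$array_col %% 2 == g$array_row %% 2))

  g1 <- make_visium_grid(1, 1, 10)
  expect_equal(nrow(g1), 1)
  expect_length(lattice_neighbors(g1, g1$barcode[1]), 0)

  g3 <- make_visium_grid(3, 3, 10)
  center <- g3$barcode[g3$array_row == 1 & g3$array_col == 3]
  expect_length(lattice_neighbors(g3, center), 6)

  expect_error(make_visium_grid(0, 5, 10), class = "st_invalid_argument")
  expect_error(lattice_neighbors(g3, "nope"), class = "st_invalid_argument")
})

test_that("tile centers are spaced so tile footprints never overlap", {
  for (d in c(9, 10, 55)) {
    g <- make_visium_grid(4, 4, d)
    dr <- outer(g$pxl_row, g$pxl_row, "-")
    dc <- outer(g$pxl_col, g$pxl_col, "-")
    ut <- upper.tri(dr)
    overlap <- abs(dr[ut]) < d & abs(dc[ut]) < d
    expect_false(any(overlap))
  }
})

test_that("layered slides are deterministic with contiguous equal-width bands", {
  g <- make_visium_grid(12, 12, 10)
  sl1 <- make_layered_slide(g, two_layer_specs(), layer_axis = "x", seed = 5)
  sl2 <- make_layered_slide(g, two_layer_specs(), layer_axis = "x", seed = 5)
  expect_identical(sl1$image, sl2$image)
  expect_identical(sl1$counts, sl2$counts)

  three <- c(two_layer_specs(3),
             list(layer_spec(3, c(95, 115, 205), 120, 6, c(5, 100, 5))))
  sl3 <- make_layered_slide(g, three, layer_axis = "x", seed = 5)
  expect_setequal(unique(sl3$truth_labels), 1:3)
  # contiguity: per-label pixel-column ranges do not interleave
  x <- sl3$grid$pxl_col
  r1 <- range(x[sl3$truth_labels == 1]); r2 <- range(x[sl3$truth_labels == 2])
  r3 <- range(x[sl3$truth_labels == 3])
  expect_true(r1[2] < r2[1] && r2[2] < r3[1])
  # every in-tissue spot carries exactly one label
  expect_setequal(names(sl3$truth_labels), sl3$grid$barcode)

  expect_error(make_layered_slide(g, two_layer_specs()[1], seed = 1),
               class = "st_invalid_argument")
  expect_error(make_layered_slide(make_visium_grid(1, 2, 8),
                                  c(two_layer_specs(), two_layer_specs()),
                                  layer_axis = "y", seed = 1),
               class = "st_invalid_argument")
})

test_that("identical layer specs produce bands with matching image statistics", {
  g <- make_visium_grid(10, 10, 10)
  same <- list(layer_spec(1, c(150, 150, 150), 0, 5, c(10, 10)),
               layer_spec(2, c(150, 150, 150), 0, 5, c(10, 10)))
  sl <- make_layered_slide(g, same, layer_axis = "x", seed = 2)
  tiles <- extract_tiles(sl$image, sl$grid)
  m <- apply(tiles$tiles, 1, mean)
  m1 <- mean(m[sl$truth_labels == 1]); m2 <- mean(m[sl$truth_labels == 2])
  expect_lt(abs(m1 - m2), 2)  # within pixel noise
})

test_that("counts follow the layer's Poisson means", {
  g <- make_visium_grid(14, 14, 8)
  lay <- list(layer_spec(1, c(200, 100, 100), 0, 3, c(100, 0)),
              layer_spec(2, c(100, 200, 100), 0, 3, c(0, 100)))
  sl <- make_layered_slide(g, lay, layer_axis = "x", seed = 9)
  in1 <- names(sl$truth_labels)[sl$truth_labels == 1]
  m <- mean(sl$counts[in1, 1])
  se <- sqrt(100 / length(in1))   # Poisson: var = mean
  expect_lt(abs(m - 100), 3 * se)
  expect_true(all(sl$counts[in1, 2] == 0))
})

test_that("boundary annotations are one per layer pair, disjoint, and adjacency-exact", {
  sl3 <- study_slide()
  b <- make_boundary_annotations(sl3)
  expect_length(b, 2)
  expect_length(intersect(b[[1]], b[[2]]), 0)

  sl2 <- small_two_layer_slide()
  b2 <- make_boundary_annotations(sl2)
  expect_length(b2, 1)
  # oracle: direct adjacency scan
  g <- sl2$grid
  lab <- sl2$truth_labels
  expected <- g$barcode[vapply(g$barcode, function(bc)
    lab[bc] == 1 && any(lab[lattice_neighbors(g, bc)] == 2), TRUE)]
  expect_setequal(b2[[1]], expected)

  one <- sl2; one$truth_labels[] <- 1L
  expect_error(make_boundary_annotations(one), class = "st_invalid_argument")
})
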