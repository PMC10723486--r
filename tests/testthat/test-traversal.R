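test_that("lattice neighbors follow the hex rule at interior, edge and corner", {
  g <- make_visium_grid(5, 5, 8)
  interior <- g$barcode[g$array_row == 2 & g$array_col == 4]
  nbrs <- lattice_neighbors(g, interior)
  expect_length(nbrs, 6)
  # neighbors sit exactly at the offsets (0,+/-2), (+/-1,+/-1)
  i <- match(interior, g$barcode)
  j <- match(nbrs, g$barcode)
  off <- cbind(g$array_row[j] - g$array_row[i], g$array_col[j] - g$array_col[i])
  expect_setequal(paste(off[, 1], off[, 2]),
                  c("0 2", "0 -2", "1 1", "1 -1", "-1 1", "-1 -1"))
  corner <- g$barcode[g$array_row == 0 & g$array_col == 0]
  expect_lt(length(lattice_neighbors(g, corner)), 6)
})

test_that("graph weights are Euclidean embedding distances, symmetric, lattice-only", {
  g <- make_visium_grid(1, 2, 8)   # two adjacent spots
  emb <- structure(rbind(c(0, 0), c(3, 4)),
                   dimnames = list(g$barcode, NULL),
                   class = c("embedding_set", "matrix", "array"))
  gr <- build_graph(g, emb)
  expect_equal(nrow(gr$edges), 1)
  expect_equal(gr$edges$weight, 5)

  g3 <- make_visium_grid(3, 3, 8)
  same <- structure(matrix(1, 9, 4, dimnames = list(g3$barcode, NULL)),
                    class = c("embedding_set", "matrix", "array"))
  gr3 <- build_graph(g3, same)
  expect_true(all(gr3$edges$weight == 0))   # identical embeddings -> 0, no floor
  # every edge joins lattice-adjacent spots
  for (k in seq_len(nrow(gr3$edges)))
    expect_true(gr3$edges$to[k] %in% lattice_neighbors(g3, gr3$edges$from[k]))
  expect_error(build_graph(g3, same[-1, , drop = FALSE]),
               class = "st_contract_error")
})

test_that("dijkstra equals the brute-force enumeration oracle on small grids", {
  for (nr in 2:4) for (nc in 2:4) {
    g <- make_visium_grid(nr, nc, 8)
    gr <- random_weight_graph(g, seed = nr * 10 + nc)
    a <- gr$vertices[1]; b <- gr$vertices[length(gr$vertices)]
    p <- shortest_path(gr, a, b)
    expect_equal(p$cost, brute_force_cost(gr, a, b), tolerance = 1e-12)
    # validity: starts/ends at anchors, no repeats, consecutive adjacency
    expect_identical(p$spots[1], a)
    expect_identical(p$spots[p$k], b)
    expect_false(anyDuplicated(p$spots) > 0)
    for (i in seq_len(p$k - 1))
      expect_true(p$spots[i + 1] %in% lattice_neighbors(g, p$spots[i]))
  }
})

test_that("dijkstra agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  g <- make_visium_grid(6, 6, 8)
  gr <- random_weight_graph(g, seed = 99)
  ig <- igraph::graph_from_data_frame(gr$edges, directed = FALSE,
                                      vertices = gr$vertices)
  for (pair in list(c(1, 36), c(3, 30), c(10, 25))) {
    a <- gr$vertices[pair[1]]; b <- gr$vertices[pair[2]]
    expect_equal(shortest_path(gr, a, b)$cost,
                 as.numeric(igraph::distances(ig, a, b,
                                              weights = igraph::E(ig)$weight)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate and uniform-weight cases behave as contracted", {
  g <- make_visium_grid(4, 4, 8)
  gr <- random_weight_graph(g, seed = 1)
  a <- gr$vertices[1]
  p <- shortest_path(gr, a, a)
  expect_equal(p$k, 1)
  expect_equal(p$cost, 0)

  # uniform weights: cost = w * minimal hop count
  gu <- gr; gu$edges$weight <- rep(0.5, nrow(gu$edges))
  b <- gr$vertices[16]
  pu <- shortest_path(gu, a, b)
  # minimal-hop path on the hex lattice from (0,0) to (3,7): 3 diagonal
  # moves (+1,+1) plus 2 horizontal moves (0,+2) = 5 hops
  expect_equal(pu$cost, 0.5 * 5)

  # disconnected components raise a no-path error naming members
  g2 <- make_visium_grid(1, 3, 8)   # row 0: cols 0,2,4 - chain
  gr2 <- random_weight_graph(g2, seed = 2)
  gr2$edges <- gr2$edges[0, ]       # cut all edges
  err <- expect_error(shortest_path(gr2, gr2$vertices[1], gr2$vertices[3]),
                      class = "st_no_path_error")
  expect_match(conditionMessage(err), gr2$vertices[1], fixed = TRUE)
})

test_that("triangle inequality holds across anchor choices", {
  g <- make_visium_grid(4, 4, 8)
  gr <- random_weight_graph(g, seed = 7)
  v <- gr$vertices
  cost <- function(a, b) shortest_path(gr, a, b)$cost
  for (trip in list(c(1, 16, 6), c(2, 15, 9), c(4, 13, 8)))
    expect_lte(cost(v[trip[1]], v[trip[2]]),
               cost(v[trip[1]], v[trip[3]]) + cost(v[trip[3]], v[trip[2]]) + 1e-12)
})

test_that("tie-breaking picks fewest spots then lexicographic order", {
  # triangle of equal-cost routes: direct edge vs two-hop detour, same cost
  g <- make_visium_grid(2, 2, 8)
  emb <- structure(matrix(0, 4, 2, dimnames = list(g$barcode, NULL)),
                   class = c("embedding_set", "matrix", "array"))
  gr <- build_graph(g, emb)   # all weights 0: every route ties on cost
  a <- g$barcode[1]; b <- g$barcode[4]   # (0,0) -> (1,3): two 2-hop routes
  p <- shortest_path(gr, a, b)
  expect_equal(p$cost, 0)
  # fewest-spots tie-break: a minimal 2-hop route, not longer 0-cost walks
  expect_equal(p$k, 3)
  # lexicographic tie-break: middle spot is the smaller barcode (0,2)
  expect_identical(p$spots[2], g$barcode[g$array_row == 0 & g$array_col == 2])
  expect_identical(shortest_path(gr, a, b)$spots, p$spots)  # reproducible
})
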