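test_that("triplet loss matches its closed form, including the margin boundary", {
  expect_equal(triplet_loss(0.5, 0.2, 0.001), 0.301)
  expect_equal(triplet_loss(0.3, 0.3, 0.01), 0.01)    # d_ap = d_an -> alpha
  expect_equal(triplet_loss(0, 0.5, 0.001), 0)        # satisfied margin
  # grid including the boundary d_an - d_ap = alpha
  for (dap in c(0, 0.1, 1)) for (alpha in c(1e-3, 0.05)) {
    expect_equal(triplet_loss(dap, dap + alpha, alpha), 0)
    expect_equal(triplet_loss(dap, dap + alpha / 2, alpha), alpha / 2)
  }
  expect_gte(min(triplet_loss(runif(20), runif(20), 0.01)), 0)
  expect_error(triplet_loss(-0.1, 0.5, 0.001), class = "st_invalid_argument")
})

test_that("triplet sampling respects adjacency and exclusion contracts", {
  g <- make_visium_grid(3, 3, 8)
  tb <- sample_triplets(g, 100, seed = 4)
  expect_equal(nrow(tb), 100)
  for (i in seq_len(nrow(tb))) {
    nbrs <- lattice_neighbors(g, tb$anchor[i])
    expect_true(tb$positive[i] %in% nbrs)
    expect_false(tb$negative[i] %in% c(tb$anchor[i], nbrs))
  }
  expect_identical(sample_triplets(g, 50, seed = 9),
                   sample_triplets(g, 50, seed = 9))
  # two adjacent spots only: no legal negative exists
  g2 <- make_visium_grid(1, 2, 8)
  expect_error(sample_triplets(g2, 10, seed = 1),
               class = "st_degenerate_input")
})

test_that("pooled multi-slide sampling draws negatives across slides", {
  g1 <- make_visium_grid(3, 3, 8)
  g2 <- make_visium_grid(3, 3, 8)
  g2$barcode <- sub("SPOT", "S2", g2$barcode)
  tb <- sample_triplets(list(g1, g2), 400, seed = 2)
  anchor_slide <- ifelse(startsWith(tb$anchor, "S2"), 2L, 1L)
  neg_slide <- ifelse(startsWith(tb$negative, "S2"), 2L, 1L)
  expect_true(any(anchor_slide != neg_slide))
  # positives always share the anchor's slide (adjacency is within-slide)
  pos_slide <- ifelse(startsWith(tb$positive, "S2"), 2L, 1L)
  expect_true(all(pos_slide == anchor_slide))
})

test_that("full-scale config carries the reference optimizer settings", {
  cfg <- train_config("paper")
  expect_equal(cfg$margin, 0.001)
  expect_equal(cfg$epochs, 1000L)
  expect_equal(cfg$batch_size, 768L)
  expect_equal(cfg$learning_rate, 0.05)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$weight_decay, 1e-4)
  expect_error(train_config("small", margin = 0), class = "st_invalid_argument")
  expect_error(train_config("small", epochs = 0), class = "st_invalid_argument")
})

test_that("training reduces the triplet loss and is seed-deterministic", {
  sl <- small_two_layer_slide()
  tn <- normalize_tiles(extract_tiles(sl$image, sl$grid))
  cfg <- train_config("small", epochs = 12, seed = 21)
  enc <- train_encoder(tn, sl$grid, cfg)
  expect_lt(tail(enc$loss_history, 1), enc$loss_history[1])
  enc2 <- train_encoder(tn, sl$grid, cfg)
  emb <- embed_tiles(enc, tn)
  expect_identical(unclass(emb), unclass(embed_tiles(enc2, tn)))
  # inference is deterministic: same tile twice -> identical vectors
  expect_identical(unclass(embed_tiles(enc, tn)), unclass(emb))
  expect_true(all(is.finite(emb)))
  expect_equal(ncol(emb), 32)

  expect_error(train_encoder(tn, sl$grid,
                             train_config("small", epochs = 2,
                                          batch_size = 4096, n_triplets = 64)),
               class = "st_invalid_argument")
  expect_error(train_encoder(extract_tiles(sl$image, sl$grid), sl$grid, cfg),
               class = "st_invalid_argument")  # raw tiles rejected
})

test_that("mismatched tile statistics are rejected at inference", {
  sl <- small_two_layer_slide()
  tiles <- extract_tiles(sl$image, sl$grid)
  tn <- normalize_tiles(tiles)
  enc <- train_encoder(tn, sl$grid, train_config("small", epochs = 3, seed = 1))
  other <- normalize_tiles(tiles, stats = list(mean = c(0, 0, 0), sd = c(1, 1, 1)))
  expect_error(embed_tiles(enc, other), class = "st_contract_error")
})

test_that("trained embeddings separate layers: within-layer distance < between", {
  sf <- study_fit()
  emb <- sf$fit$embeddings
  lab <- sf$slide$truth_labels[rownames(emb)]
  D <- as.matrix(dist(unclass(emb)))
  ut <- upper.tri(D)
  within <- mean(D[outer(lab, lab, "==") & ut])
  between <- mean(D[outer(lab, lab, "!=") & ut])
  expect_lt(within, between)
})
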