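#' Training configuration for the tile encoder
#'
#' Holds the triplet-loss margin and the optimizer settings. Two encoder
#' sizes are provided. `"paper"` carries the full-scale reference
#' configuration — margin 0.001, 1000 epochs, batch size 768, learning rate
#' 0.05, SGD with momentum 0.9 and weight decay 1e-4, a 3-layer projection
#' head of width 2048 — intended for real slide datasets. `"small"` is a
#' compact encoder (3 conv blocks, a 2-layer head, 32-dimensional output)
#' whose defaults train in minutes on a CPU and suffice for synthetic
#' layered slides.
#'
#' @param encoder_size `"small"` or `"paper"`.
#' @param margin triplet-loss margin `alpha` (> 0).
#' @param epochs,batch_size,learning_rate,momentum,weight_decay SGD settings.
#' @param embed_dim output embedding dimension.
#' @param hidden integer vector of hidden widths of the projection head
#'   (its length sets the head depth: `length(hidden) + 1` linear layers).
#' @param channels integer vector of conv-bank channel widths (3 blocks).
#' @param n_triplets triplets sampled per epoch.
#' @param seed integer seed for sampling and initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(encoder_size = c("small", "paper"),
                         margin = 0.001, epochs = NULL, batch_size = NULL,
                         learning_rate = NULL, momentum = 0.9,
                         weight_decay = 1e-4, embed_dim = NULL,
                         hidden = NULL, channels = NULL,
                         n_triplets = NULL, seed = 1L) {
  encoder_size <- match.arg(encoder_size)
  def <- if (encoder_size == "paper") {
    list(epochs = 1000L, batch_size = 768L, learning_rate = 0.05,
         embed_dim = 2048L, hidden = c(2048L, 2048L),
         channels = c(32L, 64L, 128L), n_triplets = 8192L)
  } else {
    list(epochs = 40L, batch_size = 128L, learning_rate = 0.05,
         embed_dim = 32L, hidden = 64L,
         channels = c(8L, 16L, 32L), n_triplets = 1024L)
  }
  cfg <- list(encoder_size = encoder_size,
              margin = margin,
              epochs = as.integer(epochs %||% def$epochs),
              batch_size = as.integer(batch_size %||% def$batch_size),
              learning_rate = as.numeric(learning_rate %||% def$learning_rate),
              momentum = momentum, weight_decay = weight_decay,
              embed_dim = as.integer(embed_dim %||% def$embed_dim),
              hidden = as.integer(hidden %||% def$hidden),
              channels = as.integer(channels %||% def$channels),
              n_triplets = as.integer(n_triplets %||% def$n_triplets),
              seed = as.integer(seed))
  if (!is.numeric(cfg$margin) || cfg$margin <= 0)
    stop_invalid("margin must be > 0")
  if (cfg$epochs < 1L) stop_invalid("epochs must be >= 1")
  structure(cfg, class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf(paste0("train_config (%s): margin %g, %d epochs, batch %d, ",
                     "lr %g, momentum %g, wd %g, dim %d\n"),
              x$encoder_size, x$margin, x$epochs, x$batch_size,
              x$learning_rate, x$momentum, x$weight_decay, x$embed_dim))
  invisible(x)
}

# ---- triplet sampling --------------------------------------------------

# Pool one or more grids into a single spot table with per-slide neighbor
# structure. Negatives are drawn from the whole pool ("all other tiles in
# the dataset"), so with several slides a negative may come from a
# different slide than its anchor.
.pool_grids <- function(grid) {
  grids <- if (inherits(grid, "spot_grid")) list(grid) else grid
  if (!all(vapply(grids, inherits, TRUE, "spot_grid")))
    stop_invalid("grid must be a spot_grid or a list of spot_grids")
  tabs <- lapply(seq_along(grids), function(s) {
    g <- in_tissue_grid(grids[[s]])
    nb <- neighbor_index(g)
    list(barcode = g$barcode, nb = nb, slide = rep(s, nrow(g)))
  })
  barcode <- unlist(lapply(tabs, `[[`, "barcode"))
  if (anyDuplicated(barcode))
    stop_invalid("barcodes must be unique across the pooled slides")
  offset <- cumsum(c(0L, utils::head(vapply(tabs, function(t) length(t$barcode), 1L), -1L)))
  nb <- do.call(c, lapply(seq_along(tabs), function(s)
    lapply(tabs[[s]]$nb, function(j) j + offset[s])))
  list(barcode = barcode, nb = nb,
       slide = unlist(lapply(tabs, `[[`, "slide")))
}

.sample_triplets <- function(pool, n) {
  n_spots <- length(pool$barcode)
  n_nb <- lengths(pool$nb)
  valid <- which(n_nb >= 1L & (n_spots - 1L - n_nb) >= 1L)
  if (n_spots < 3L || length(valid) == 0L)
    stop_degenerate("grid admits no valid triplet (need an adjacent pair plus a non-adjacent spot)")
  a <- valid[sample.int(length(valid), n, replace = TRUE)]
  p <- vapply(a, function(i) {
    nbs <- pool$nb[[i]]
    nbs[sample.int(length(nbs), 1L)]
  }, 1L)
  ng <- vapply(a, function(i) {
    excl <- c(i, pool$nb[[i]])
    allowed <- setdiff(seq_len(n_spots), excl)
    allowed[sample.int(length(allowed), 1L)]
  }, 1L)
  structure(data.frame(anchor = pool$barcode[a],
                       positive = pool$barcode[p],
                       negative = pool$barcode[ng],
                       stringsAsFactors = FALSE),
            slide = list(anchor = pool$slide[a], negative = pool$slide[ng]),
            class = c("triplet_batch", "data.frame"))
}

#' Sample training triplets from the lattice
#'
#' Anchors are drawn uniformly from spots that have at least one lattice
#' neighbor (and at least one non-adjacent spot to serve as a negative);
#' each positive is drawn uniformly from the anchor's lattice neighbors and
#' each negative uniformly from all other spots in the dataset, excluding
#' the anchor and its neighbors so a sampled negative can never be a legal
#' positive. With a list of grids the negatives are drawn across the pooled
#' dataset.
#'
#' @param grid a `spot_grid` or a list of them (a pooled dataset).
#' @param n number of triplets.
#' @param seed integer seed.
#' @return A `triplet_batch` data.frame with columns `anchor`, `positive`,
#'   `negative` (barcodes).
#' @export
sample_triplets <- function(grid, n, seed = 1L) {
  if (!is.numeric(n) || n < 1L) stop_invalid("n must be >= 1")
  pool <- .pool_grids(grid)
  with_seed(seed, .sample_triplets(pool, as.integer(n)))
}

#' Triplet margin loss
#'
#' `max(0, d_ap - d_an + alpha)`: zero once the anchor-negative distance
#' exceeds the anchor-positive distance by at least the margin `alpha`.
#' Distances are mean squared error between embeddings during training.
#'
#' @param d_ap,d_an nonnegative anchor-positive and anchor-negative
#'   distances (vectorized).
#' @param alpha positive margin.
#' @return Nonnegative loss value(s).
#' @examples
#' triplet_loss(0.5, 0.2, 0.001)  # 0.301
#' @export
triplet_loss <- function(d_ap, d_an, alpha) {
  if (any(!is.finite(d_ap)) || any(!is.finite(d_an)) || !is.finite(alpha))
    stop_invalid("inputs must be finite")
  if (any(d_ap < 0) || any(d_an < 0))
    stop_invalid("distances must be nonnegative")
  if (alpha <= 0) stop_invalid("alpha must be > 0")
  pmax(0, d_ap - d_an + alpha)
}

# ---- convolutional feature bank ---------------------------------------

# Seeded random filter bank: 3 conv blocks (3x3 kernels, zero padding,
# ReLU, 2x2 mean pooling). The filters are fixed at initialization; the
# trainable part of the encoder is the MLP projection head on top. He-scaled
# Gaussian filters preserve color and oriented-texture statistics well
# enough for the head to separate histological layers.
.init_bank <- function(channels) {
  cin <- 3L
  bank <- vector("list", length(channels))
  for (b in seq_along(channels)) {
    cout <- channels[b]
    bank[[b]] <- matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                        9L * cin, cout)
    cin <- cout
  }
  bank
}

# 3x3 'same' convolution via im2col on a zero-padded array.
.conv_same <- function(x, w) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cin <- dim(x)[3]
  xp <- array(0, c(h + 2L, wd + 2L, cin))
  xp[2:(h + 1L), 2:(wd + 1L), ] <- x
  cols <- matrix(0, h * wd, 9L * cin)
  k <- 1L
  for (c0 in 1:cin) for (dj in 0:2) for (di in 0:2) {
    cols[, k] <- as.vector(xp[di + seq_len(h), dj + seq_len(wd), c0])
    k <- k + 1L
  }
  out <- cols %*% w
  array(out, c(h, wd, ncol(w)))
}

.pool2 <- function(x) {
  h2 <- dim(x)[1] %/% 2L; w2 <- dim(x)[2] %/% 2L
  if (h2 < 1L || w2 < 1L) return(x)
  x <- x[seq_len(2L * h2), seq_len(2L * w2), , drop = FALSE]
  (x[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE] +
   x[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE] +
   x[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE] +
   x[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE]) / 4
}

# Per-tile feature vector: global channel means after the conv bank, plus
# the raw per-channel mean and sd of the tile (direct color statistics).
.tile_features <- function(tile, bank) {
  x <- tile
  for (w in bank) {
    x <- .conv_same(x, w)
    x[x < 0] <- 0
    x <- .pool2(x)
  }
  conv_feat <- apply(x, 3, mean)
  raw_mean <- apply(tile, 3, mean)
  raw_sd <- apply(tile, 3, stats::sd)
  c(conv_feat, raw_mean, raw_sd)
}

.stack_features <- function(tiles, bank) {
  n <- length(tiles$spot_ids)
  f1 <- .tile_features(tiles$tiles[1, , , ], bank)
  out <- matrix(0, n, length(f1))
  out[1, ] <- f1
  if (n > 1L) for (i in 2:n) out[i, ] <- .tile_features(tiles$tiles[i, , , ], bank)
  rownames(out) <- tiles$spot_ids
  out
}

# ---- MLP projection head ----------------------------------------------

.init_head <- function(n_in, hidden, n_out) {
  dims <- c(n_in, hidden, n_out)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    layers[[l]] <- list(
      W = matrix(stats::rnorm(dims[l] * dims[l + 1L], 0, sqrt(2 / dims[l])),
                 dims[l], dims[l + 1L]),
      b = rep(0, dims[l + 1L]))
  }
  layers
}

# Forward pass; returns the output and the per-layer inputs for backprop.
.head_forward <- function(head, x) {
  acts <- vector("list", length(head))
  for (l in seq_along(head)) {
    acts[[l]] <- x
    x <- sweep(x %*% head[[l]]$W, 2L, head[[l]]$b, `+`)
    if (l < length(head)) x[x < 0] <- 0
  }
  list(out = x, acts = acts)
}

# Backprop of dL/dout through the head; returns per-layer W/b gradients.
.head_backward <- function(head, fwd, grad_out) {
  grads <- vector("list", length(head))
  g <- grad_out
  for (l in rev(seq_along(head))) {
    x <- fwd$acts[[l]]
    if (l < length(head)) {
      # recompute the ReLU mask from the pre-activation output
      pre <- sweep(x %*% head[[l]]$W, 2L, head[[l]]$b, `+`)
      g <- g * (pre > 0)
    }
    grads[[l]] <- list(W = crossprod(x, g), b = colSums(g))
    g <- g %*% t(head[[l]]$W)
  }
  grads
}

encoder_fingerprint <- function(bank, head, tile_stats) {
  nums <- c(unlist(lapply(bank, as.vector)),
            unlist(lapply(head, function(l) c(as.vector(l$W), l$b))),
            tile_stats$mean, tile_stats$sd)
  sprintf("enc-%0.10e-%0.10e-%d", sum(nums), sum(nums^2), length(nums))
}

#' Train the tile encoder with triplet loss
#'
#' Learns the embedding function `f` mapping each standardized tile to a
#' vector, by pulling lattice-adjacent tiles together and pushing
#' non-adjacent tiles apart: for each sampled triplet (anchor, positive,
#' negative) the loss is `max(0, d(f(a), f(p)) - d(f(a), f(n)) + alpha)`
#' with mean-squared-error distances. The encoder is a fixed, seeded random
#' convolutional feature bank (3 blocks of 3x3 convolution, ReLU and mean
#' pooling, plus raw per-channel color statistics) followed by a trainable
#' MLP projection head optimized with SGD (momentum, weight decay). The
#' projection-head output is the representation used downstream — the loss
#' acts on it directly. Training is end-to-end deterministic given
#' `cfg$seed`.
#'
#' @param tiles a normalized [tile_stack()].
#' @param grid the `spot_grid` the tiles came from (or a list of grids for
#'   a pooled multi-slide dataset).
#' @param cfg a [train_config()].
#' @return An object of class `st_encoder` with the feature bank, head
#'   weights, feature standardization, tile statistics fingerprint, and the
#'   per-epoch mean training loss in `$loss_history`.
#' @export
train_encoder <- function(tiles, grid, cfg = train_config("small")) {
  if (!inherits(tiles, "tile_stack")) stop_invalid("tiles must be a tile_stack")
  if (!tiles$normalized) stop_invalid("tiles must be normalized first")
  if (!inherits(cfg, "train_config")) stop_invalid("cfg must be a train_config")
  if (cfg$batch_size > cfg$n_triplets)
    stop_invalid("batch_size (%d) exceeds the triplet pool per epoch (%d)",
                 cfg$batch_size, cfg$n_triplets)
  pool <- .pool_grids(grid)
  if (!identical(sort(pool$barcode), sort(tiles$spot_ids)))
    stop_contract("tile spot_ids do not match the grid's in-tissue spots")

  with_seed(cfg$seed, {
    bank <- .init_bank(cfg$channels)
    feats <- .stack_features(tiles, bank)
    fmean <- colMeans(feats)
    fsd <- apply(feats, 2, stats::sd)
    fsd[!is.finite(fsd) | fsd < 1e-12] <- 1
    feats <- sweep(sweep(feats, 2L, fmean), 2L, fsd, `/`)

    head <- .init_head(ncol(feats), cfg$hidden, cfg$embed_dim)
    vel <- lapply(head, function(l) list(W = l$W * 0, b = l$b * 0))
    d <- cfg$embed_dim
    loss_history <- numeric(cfg$epochs)

    for (ep in seq_len(cfg$epochs)) {
      tb <- .sample_triplets(pool, cfg$n_triplets)
      ia <- match(tb$anchor, rownames(feats))
      ip <- match(tb$positive, rownames(feats))
      ig <- match(tb$negative, rownames(feats))
      ord <- sample.int(cfg$n_triplets)
      ep_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, cfg$n_triplets, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, cfg$n_triplets)]
        B <- length(idx)
        fa <- .head_forward(head, feats[ia[idx], , drop = FALSE])
        fp <- .head_forward(head, feats[ip[idx], , drop = FALSE])
        fn <- .head_forward(head, feats[ig[idx], , drop = FALSE])
        dap <- rowMeans((fa$out - fp$out)^2)
        dan <- rowMeans((fa$out - fn$out)^2)
        li <- pmax(0, dap - dan + cfg$margin)
        ep_loss <- ep_loss + mean(li)
        n_batches <- n_batches + 1L
        act <- (li > 0) / B
        ga <- (2 / d) * (fn$out - fp$out) * act
        gp <- (2 / d) * (fp$out - fa$out) * act
        gn <- (2 / d) * (fa$out - fn$out) * act
        gr_a <- .head_backward(head, fa, ga)
        gr_p <- .head_backward(head, fp, gp)
        gr_n <- .head_backward(head, fn, gn)
        for (l in seq_along(head)) {
          gW <- gr_a[[l]]$W + gr_p[[l]]$W + gr_n[[l]]$W +
            cfg$weight_decay * head[[l]]$W
          gb <- gr_a[[l]]$b + gr_p[[l]]$b + gr_n[[l]]$b
          vel[[l]]$W <- cfg$momentum * vel[[l]]$W - cfg$learning_rate * gW
          vel[[l]]$b <- cfg$momentum * vel[[l]]$b - cfg$learning_rate * gb
          head[[l]]$W <- head[[l]]$W + vel[[l]]$W
          head[[l]]$b <- head[[l]]$b + vel[[l]]$b
        }
      }
      loss_history[ep] <- ep_loss / n_batches
    }

    ts <- list(mean = tiles$channel_mean, sd = tiles$channel_sd)
    structure(list(bank = bank, head = head,
                   feat_mean = fmean, feat_sd = fsd,
                   tile_stats = ts, cfg = cfg, dim = d,
                   loss_history = loss_history,
                   fingerprint = encoder_fingerprint(bank, head, ts)),
              class = "st_encoder")
  })
}

#' @export
print.st_encoder <- function(x, ...) {
  cat(sprintf("st_encoder (%s): dim %d, %d epochs trained, final loss %.4g\n",
              x$cfg$encoder_size, x$dim, length(x$loss_history),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Embed tiles with a trained encoder
#'
#' Applies the learned embedding function in inference mode (no
#' randomness): every call on the same tiles yields identical vectors. The
#' tiles must have been standardized with the same per-channel statistics
#' the encoder was trained with; a mismatch raises a contract error.
#'
#' @param encoder an `st_encoder` from [train_encoder()].
#' @param tiles a normalized [tile_stack()].
#' @return An `embedding_set`: an n x d matrix with barcode rownames and an
#'   `encoder_fingerprint` attribute.
#' @export
embed_tiles <- function(encoder, tiles) {
  if (!inherits(encoder, "st_encoder")) stop_invalid("encoder must be an st_encoder")
  if (!inherits(tiles, "tile_stack") || !tiles$normalized)
    stop_invalid("tiles must be a normalized tile_stack")
  if (!isTRUE(all.equal(encoder$tile_stats$mean, tiles$channel_mean,
                        tolerance = 1e-8)) ||
      !isTRUE(all.equal(encoder$tile_stats$sd, tiles$channel_sd,
                        tolerance = 1e-8)))
    stop_contract("tile statistics differ from those the encoder was trained with")
  feats <- .stack_features(tiles, encoder$bank)
  feats <- sweep(sweep(feats, 2L, encoder$feat_mean), 2L, encoder$feat_sd, `/`)
  out <- .head_forward(encoder$head, feats)$out
  rownames(out) <- tiles$spot_ids
  if (any(!is.finite(out))) stop_contract("non-finite embedding produced")
  structure(out, encoder_fingerprint = encoder$fingerprint,
            class = c("embedding_set", "matrix", "array"))
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("embedding_set: %d spots x %d dims\n", nrow(x), ncol(x)))
  invisible(x)
}
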