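#' Fit a histology-anchored traversal of a spatial slide
#'
#' The main fitting function. Given a slide image, the spot grid, the raw
#' counts, and two user-chosen anchor spots, it runs the full procedure:
#' extract and standardize spot-centered tiles, learn a spatially aware
#' tile embedding with triplet loss, build the embedding-weighted hexagonal
#' lattice graph, find the shortest path between the anchors, assign every
#' spot to its nearest path tile, average the normalized expression within
#' each assignment set, and length-normalize the resulting trajectories
#' onto the unit axis. The result is a classed object carrying every
#' intermediate product, with `print`, `summary`, `plot`, `predict` and
#' `fitted` methods.
#'
#' @param image H x W x 3 slide raster (0–255), e.g. from
#'   [read_slide_bundle()] or a `synthetic_slide`.
#' @param grid a `spot_grid`.
#' @param counts a raw [count_matrix()] or a bare integer matrix with
#'   barcode rownames and gene colnames.
#' @param start,end anchor spot barcodes.
#' @param config a [train_config()]; its seed drives all randomness.
#' @param target_count target average count per spot for normalization
#'   (default `1e4`).
#' @param tile_statistics optional per-channel statistics to reuse (pooled
#'   multi-slide datasets); default: computed from this slide's tiles.
#' @param verbose log stage progress.
#' @return An object of class `sttraverse`.
#' @examples
#' \donttest{
#' g <- make_visium_grid(10, 10, 10)
#' lay <- list(layer_spec(1, c(200, 120, 160), 0, 4, c(60, 4)),
#'             layer_spec(2, c(110, 170, 120), 60, 4, c(4, 60)))
#' sl <- make_layered_slide(g, lay, seed = 7)
#' fit <- sttraverse(sl$image, sl$grid, sl$counts,
#'                   start = sl$grid$barcode[1],
#'                   end = sl$grid$barcode[nrow(sl$grid)],
#'                   config = train_config("small", epochs = 5))
#' print(fit)
#' }
#' @export
sttraverse <- function(image, grid, counts, start, end,
                       config = train_config("small"),
                       target_count = 1e4, tile_statistics = NULL,
                       verbose = FALSE) {
  cl <- match.call()
  if (is.matrix(counts)) counts <- count_matrix(counts)
  st_log("tiles", "extracting spot tiles", verbose)
  tiles <- extract_tiles(image, grid)
  tiles_n <- normalize_tiles(tiles, stats = tile_statistics)
  st_log("train", sprintf("training %s encoder (%d epochs)",
                          config$encoder_size, config$epochs), verbose)
  encoder <- train_encoder(tiles_n, grid, config)
  emb <- embed_tiles(encoder, tiles_n)
  st_log("traverse", sprintf("shortest path %s -> %s", start, end), verbose)
  graph <- build_graph(grid, emb)
  path <- shortest_path(graph, start, end)
  st_log("align", sprintf("aligning %d spots to %d path tiles",
                          nrow(emb), path$k), verbose)
  assignment <- assign_spots(emb, path)
  counts_norm <- normalize_counts(counts, t = target_count)
  trajectory <- average_along_path(counts_norm, assignment)
  normalized <- if (path$k >= 2L) length_normalize(trajectory) else NULL
  structure(list(encoder = encoder, embeddings = emb, graph = graph,
                 path = path, assignment = assignment,
                 trajectory = trajectory, normalized = normalized,
                 counts_norm = counts_norm, grid = in_tissue_grid(grid),
                 config = config, call = cl),
            class = "sttraverse")
}

#' @export
print.sttraverse <- function(x, ...) {
  cat("Histology-anchored traversal fit\n")
  cat(sprintf("  spots: %d   genes: %d   embedding dim: %d\n",
              nrow(x$embeddings), length(x$trajectory$gene_ids),
              ncol(x$embeddings)))
  cat(sprintf("  path: %d spots, %s -> %s, cost %.6g\n",
              x$path$k, x$path$spots[1], x$path$spots[x$path$k], x$path$cost))
  invisible(x)
}

#' @export
summary.sttraverse <- function(object, ...) {
  s <- list(
    n_spots = nrow(object$embeddings),
    n_genes = length(object$trajectory$gene_ids),
    k = object$path$k,
    cost = object$path$cost,
    set_sizes = summary(object$trajectory$set_sizes),
    loss_first = object$encoder$loss_history[1],
    loss_final = utils::tail(object$encoder$loss_history, 1),
    config = object$config
  )
  class(s) <- "summary.sttraverse"
  s
}

#' @export
print.summary.sttraverse <- function(x, ...) {
  cat("Histology-anchored traversal fit\n")
  cat(sprintf("  %d spots, %d genes; path of %d tiles, cost %.6g\n",
              x$n_spots, x$n_genes, x$k, x$cost))
  cat(sprintf("  training loss: %.4g -> %.4g over %d epochs\n",
              x$loss_first, x$loss_final, x$config$epochs))
  cat("  assignment set sizes:\n")
  print(x$set_sizes)
  invisible(x)
}

#' @export
fitted.sttraverse <- function(object, ...) object$trajectory$values

#' Plot gene expression trajectories of a fit
#'
#' Draws the length-normalized trajectory of the selected genes against the
#' relative path position (0 = start anchor, 1 = end anchor).
#'
#' @param x an `sttraverse` fit.
#' @param genes gene ids to draw (default: up to 5 most variable).
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the plotted matrix.
#' @export
plot.sttraverse <- function(x, genes = NULL, ...) {
  if (is.null(x$normalized))
    stop_degenerate("single-spot path has no trajectory to plot")
  v <- x$normalized$values
  if (is.null(genes)) {
    vr <- apply(v, 2, stats::var)
    genes <- colnames(v)[order(vr, decreasing = TRUE)][seq_len(min(5, ncol(v)))]
  }
  graphics::matplot(x$normalized$positions, v[, genes, drop = FALSE],
                    type = "l", lty = 1, xlab = "relative path position",
                    ylab = "normalized expression", ...)
  graphics::legend("topright", legend = genes, lty = 1,
                   col = seq_along(genes), bty = "n", cex = 0.8)
  invisible(v[, genes, drop = FALSE])
}

#' Predict embeddings or path assignments for new tiles
#'
#' Embeds new tiles with the fitted encoder (standardizing them with the
#' training statistics) and optionally assigns them to the fitted path.
#'
#' @param object an `sttraverse` fit.
#' @param tiles a raw or normalized [tile_stack()].
#' @param type `"embedding"` or `"assignment"`.
#' @param ... unused.
#' @return An `embedding_set`, or a named integer vector of path indices.
#' @export
predict.sttraverse <- function(object, tiles,
                               type = c("embedding", "assignment"), ...) {
  type <- match.arg(type)
  if (!tiles$normalized)
    tiles <- normalize_tiles(tiles, stats = object$encoder$tile_stats)
  emb <- embed_tiles(object$encoder, tiles)
  if (type == "embedding") return(emb)
  all_emb <- rbind(object$embeddings[object$path$spots, , drop = FALSE],
                   emb[setdiff(rownames(emb), object$path$spots), ,
                       drop = FALSE])
  structure(assign_spots(
    structure(all_emb, class = c("embedding_set", "matrix", "array")),
    object$path)$assignment[rownames(emb)], names = rownames(emb))
}
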