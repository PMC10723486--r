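#' Run the full pipeline from a slide bundle on disk
#'
#' End-to-end execution with file IO: read (or simulate) a slide bundle,
#' fit the traversal with [sttraverse()], and write every artifact — the
#' encoder checkpoint, tile statistics, the path, the per-spot assignment,
#' the trajectory and its length-normalized form — plus a JSON manifest
#' listing each artifact with its MD5 hash. Two runs with the same
#' configuration and seed produce hash-identical artifacts.
#'
#' @param config either the path of a JSON configuration file or a list
#'   with elements: `bundle_dir` (a bundle written by
#'   [write_slide_bundle()] or equivalent), `out_dir`, `start`, `end`
#'   (anchor barcodes), `spot_diameter_px`, optional `train` (arguments to
#'   [train_config()]), `target_count`, `seed`, `verbose`, and optional
#'   `simulate` (arguments `n_rows`, `n_cols`, `spot_diameter_px`,
#'   `n_layers`, `n_genes` to generate the bundle first).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  verbose <- isTRUE(config$verbose %||% TRUE)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop_invalid("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    st_log("simulate", "generating synthetic layered bundle", verbose)
    sim <- config$simulate
    slide <- simulate_study_slide(
      n_rows = sim$n_rows %||% 20L, n_cols = sim$n_cols %||% 20L,
      spot_diameter_px = sim$spot_diameter_px %||% 12L,
      n_layers = sim$n_layers %||% 3L, n_genes = sim$n_genes %||% 20L,
      seed = seed)
    config$bundle_dir <- config$bundle_dir %||% file.path(out_dir, "bundle")
    write_slide_bundle(slide, config$bundle_dir)
    config$spot_diameter_px <- spot_diameter(slide$grid)
  }

  bdir <- config$bundle_dir %||% stop_invalid("config$bundle_dir is required")
  st_log("read", sprintf("reading bundle %s", bdir), verbose)
  bundle <- read_slide_bundle(file.path(bdir, "image.png"),
                              file.path(bdir, "tissue_positions.csv"),
                              file.path(bdir, "counts"),
                              config$spot_diameter_px)
  start <- config$start %||% bundle$grid$barcode[1]
  end <- config$end %||% bundle$grid$barcode[nrow(bundle$grid)]
  tc <- do.call(train_config, c(config$train %||% list(), list(seed = seed)))
  fit <- sttraverse(bundle$image, bundle$grid, bundle$counts, start, end,
                    config = tc, target_count = config$target_count %||% 1e4,
                    verbose = verbose)

  st_log("write", sprintf("writing artifacts to %s", out_dir), verbose)
  paths <- list(
    checkpoint = file.path(out_dir, "encoder.rds"),
    tile_stats = file.path(out_dir, "tile_stats.json"),
    path = file.path(out_dir, "path.json"),
    assignment = file.path(out_dir, "assignment.csv"),
    trajectory = file.path(out_dir, "trajectory.csv"),
    normalized = file.path(out_dir, "trajectory_normalized.csv")
  )
  saveRDS(fit$encoder, paths$checkpoint, version = 2)
  write_tile_stats(fit$encoder$tile_stats, paths$tile_stats)
  jsonlite::write_json(list(spots = fit$path$spots, cost = fit$path$cost,
                            k = fit$path$k),
                       paths$path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(barcode = names(fit$assignment$assignment),
                              path_index = as.integer(fit$assignment$assignment)),
                   paths$assignment, row.names = FALSE, quote = FALSE)
  utils::write.csv(fit$trajectory$values, paths$trajectory, quote = FALSE)
  if (!is.null(fit$normalized))
    utils::write.csv(fit$normalized$values, paths$normalized, quote = FALSE)
  else paths$normalized <- NULL

  manifest <- list(seed = seed, start = start, end = end,
                   artifacts = lapply(paths, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  st_log("done", "pipeline complete", verbose)
  invisible(manifest)
}

#' Simulate the package's reference study slide
#'
#' A convenience generator for the layered study conditions used throughout
#' the documentation and tests: `n_layers` contiguous vertical bands on an
#' `n_rows` x `n_cols` Visium-style grid, each layer with a distinct H&E-like
#' base color and stripe orientation, and a gene panel in which gene 1 marks
#' the first layer (expected counts declining across layers), the last gene
#' marks the last layer (rising), and the remaining genes have moderate
#' layer-shuffled means.
#'
#' @param n_rows,n_cols grid size (default 20 x 20, about 400 spots).
#' @param spot_diameter_px tile side in pixels (default 12).
#' @param n_layers number of layers (default 3).
#' @param n_genes gene panel size (default 20).
#' @param seed integer seed.
#' @return A `synthetic_slide`.
#' @export
simulate_study_slide <- function(n_rows = 20L, n_cols = 20L,
                                 spot_diameter_px = 12L, n_layers = 3L,
                                 n_genes = 20L, seed = 1L) {
  grid <- make_visium_grid(n_rows, n_cols, spot_diameter_px)
  colors <- list(c(205, 120, 165), c(120, 175, 125), c(95, 115, 205),
                 c(215, 200, 110), c(150, 150, 150))
  angles <- c(0, 60, 120, 30, 90)
  gm <- with_seed(seed + 1L, {
    base <- matrix(stats::runif(n_layers * n_genes, 5, 30), n_layers, n_genes)
    # gene 1: marker of layer 1, declining 10-fold per layer
    base[, 1] <- 100 / 10^(seq_len(n_layers) - 1)
    # last gene: marker of the last layer, rising
    base[, n_genes] <- 100 / 10^(n_layers - seq_len(n_layers))
    base
  })
  layers <- lapply(seq_len(n_layers), function(l)
    layer_spec(l, colors[[(l - 1L) %% length(colors) + 1L]],
               texture_angle = angles[(l - 1L) %% length(angles) + 1L],
               noise_sd = 8, gene_means = gm[l, ]))
  make_layered_slide(grid, layers, layer_axis = "x", seed = seed)
}
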