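#' Synthetic layered slides
#'
#' The simulator emulates the situation the method is designed for: a tissue
#' section whose histological layers are stacked as parallel bands (as in a
#' gut wall cut perpendicular to the mucosal surface), imaged as an H&E-like
#' raster and profiled on a Visium-style hexagonal grid. Each layer has its
#' own tile appearance — a base color, an oriented striped texture standing
#' in for cell orientation, and Gaussian pixel noise — and its own per-gene
#' expected counts; spot counts are drawn from a Poisson law at the layer
#' means. Truth labels are returned so downstream alignment and segmentation
#' can be scored against known ground truth.
#'
#' @name fixtures
NULL

#' Describe one synthetic tissue layer
#'
#' @param layer_id integer >= 1 identifying the layer.
#' @param color_mean length-3 numeric in `[0, 255]`: mean RGB of the layer.
#' @param texture_angle orientation of the striped texture, degrees.
#' @param noise_sd per-channel Gaussian pixel noise SD (>= 0).
#' @param gene_means nonnegative numeric vector of expected counts per gene;
#'   must have the same length for every layer of a slide.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(layer_id, color_mean, texture_angle = 0,
                       noise_sd = 5, gene_means) {
  if (length(color_mean) != 3L || any(color_mean < 0) || any(color_mean > 255))
    stop_invalid("color_mean must be 3 values in [0, 255]")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (any(gene_means < 0)) stop_invalid("gene_means must be nonnegative")
  structure(list(layer_id = as.integer(layer_id),
                 color_mean = as.numeric(color_mean),
                 texture_angle = as.numeric(texture_angle),
                 noise_sd = as.numeric(noise_sd),
                 gene_means = as.numeric(gene_means)),
            class = "layer_spec")
}

#' Render a synthetic layered slide
#'
#' Partitions the in-tissue spots into contiguous bands of approximately
#' equal width along `layer_axis` ("x": bands vary with the pixel column, so
#' layers are vertical stripes traversed left to right; "y": bands vary with
#' the pixel row). Each spot's square tile footprint is rendered with its
#' layer's striped texture, and counts are drawn spot-by-spot from a Poisson
#' law at the layer's `gene_means`. The result is bit-identical for identical
#' `(grid, layers, seed)`.
#'
#' @param grid a `spot_grid`.
#' @param layers list of >= 2 [layer_spec()] objects with equal-length
#'   `gene_means`.
#' @param layer_axis `"x"` or `"y"`; the axis along which layers stack.
#' @param seed integer; the single source of randomness.
#' @param stripe_amplitude,stripe_period texture contrast (intensity units)
#'   and wavelength (px) of the oriented stripes.
#' @return An object of class `synthetic_slide`: a list with `grid`, `image`
#'   (H x W x 3 array, 0–255), `counts` (in-tissue spot x gene integer
#'   matrix), `truth_labels` (named integer, 1-based layer per in-tissue
#'   spot), and `layers`.
#' @examples
#' g <- make_visium_grid(8, 8, 10)
#' ls2 <- list(layer_spec(1, c(200, 120, 160), 0, 4, c(50, 5)),
#'             layer_spec(2, c(110, 170, 120), 60, 4, c(5, 50)))
#' sl <- make_layered_slide(g, ls2, seed = 1)
#' table(sl$truth_labels)
#' @export
make_layered_slide <- function(grid, layers, layer_axis = c("x", "y"),
                               seed = 1L, stripe_amplitude = 25,
                               stripe_period = 6) {
  layer_axis <- match.arg(layer_axis)
  if (!inherits(grid, "spot_grid") || nrow(grid) == 0L)
    stop_invalid("grid must be a non-empty spot_grid")
  if (!is.list(layers) || length(layers) < 2L)
    stop_invalid("need at least 2 layers")
  if (!all(vapply(layers, inherits, TRUE, "layer_spec")))
    stop_invalid("layers must be layer_spec objects")
  ng <- unique(vapply(layers, function(l) length(l$gene_means), 1L))
  if (length(ng) != 1L)
    stop_invalid("all layers must have gene_means of the same length")
  g <- in_tissue_grid(grid)
  L <- length(layers)

  coord <- if (layer_axis == "x") g$pxl_col else g$pxl_row
  # contiguous, approximately equal-width bands over the span of spot centers
  br <- seq(min(coord), max(coord), length.out = L + 1L)
  band <- findInterval(coord, br, rightmost.closed = TRUE, all.inside = TRUE)
  if (length(unique(band)) != L)
    stop_invalid("grid too small to hold %d contiguous layer bands along %s",
                 L, layer_axis)
  truth <- as.integer(band)
  names(truth) <- g$barcode

  d <- as.integer(round(spot_diameter(grid)))
  H <- max(g$pxl_row) + d + 1L
  W <- max(g$pxl_col) + d + 1L

  slide <- with_seed(seed, {
    img <- array(255, dim = c(H, W, 3L))
    off <- floor(d / 2L)
    # render spots in grid order so output is order-independent of the caller
    for (i in seq_len(nrow(g))) {
      ls <- layers[[truth[i]]]
      r0 <- g$pxl_row[i] - off  # 0-based top-left of the tile footprint
      c0 <- g$pxl_col[i] - off
      rows <- r0 + seq_len(d)   # 1-based image rows
      cols <- c0 + seq_len(d)
      th <- ls$texture_angle * pi / 180
      # stripes in absolute slide coordinates so texture is continuous
      phase <- outer(rows - 1L, cols - 1L,
                     function(y, x) sin(2 * pi * (x * cos(th) + y * sin(th)) /
                                          stripe_period))
      for (ch in 1:3) {
        tilev <- ls$color_mean[ch] + stripe_amplitude * phase +
          matrix(stats::rnorm(d * d, 0, ls$noise_sd), d, d)
        img[rows, cols, ch] <- pmin(255, pmax(0, tilev))
      }
    }
    counts <- matrix(0L, nrow(g), ng,
                     dimnames = list(g$barcode, sprintf("gene%03d", seq_len(ng))))
    for (i in seq_len(nrow(g)))
      counts[i, ] <- stats::rpois(ng, layers[[truth[i]]]$gene_means)
    list(image = img, counts = counts)
  })

  structure(list(grid = g, image = slide$image, counts = slide$counts,
                 truth_labels = truth, layers = layers,
                 layer_axis = layer_axis),
            class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("synthetic_slide: %d spots, %d genes, %d layers, image %d x %d px\n",
              nrow(x$grid), ncol(x$counts), length(x$layers),
              dim(x$image)[1], dim(x$image)[2]))
  invisible(x)
}

#' Boundary annotations from a synthetic slide's ground truth
#'
#' Emulates the manual layer-boundary annotation used when scoring
#' segmentations: for each adjacent layer pair `(l, l+1)` the boundary set is
#' every layer-`l` spot with a lattice neighbor in layer `l+1` — a
#' one-spot-thick band on the lower-layer side of each transition, ordered
#' from the first layer to the last.
#'
#' @param slide a `synthetic_slide` with >= 2 layers.
#' @return A list of `L - 1` character vectors of barcodes, one per boundary.
#' @export
make_boundary_annotations <- function(slide) {
  if (!inherits(slide, "synthetic_slide"))
    stop_invalid("slide must be a synthetic_slide")
  L <- length(unique(slide$truth_labels))
  if (L < 2L) stop_invalid("slide has a single layer; no boundaries exist")
  g <- slide$grid
  nb <- neighbor_index(g)
  lab <- slide$truth_labels[g$barcode]
  out <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    sel <- which(lab == l &
                   vapply(nb, function(j) any(lab[j] == l + 1L), TRUE))
    out[[l]] <- g$barcode[sel]
  }
  names(out) <- sprintf("boundary_%d_%d", seq_len(L - 1L), 2:L)
  out
}

#' Write a synthetic slide as a standard spatial bundle
#'
#' Writes the on-disk layout consumed by [read_slide_bundle()]: `image.png`,
#' `tissue_positions.csv` (Space Ranger column order), a `counts/` directory
#' with `matrix.mtx` (features x barcodes), `barcodes.tsv` and
#' `features.tsv`, `truth_labels.csv`, and `scalefactors.json` carrying the
#' spot diameter.
#'
#' @param slide a `synthetic_slide`.
#' @param dir output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
write_slide_bundle <- function(slide, dir) {
  if (!inherits(slide, "synthetic_slide"))
    stop_invalid("slide must be a synthetic_slide")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- slide$grid
  image_path <- file.path(dir, "image.png")
  png::writePNG(slide$image / 255, image_path)

  positions_path <- file.path(dir, "tissue_positions.csv")
  utils::write.csv(
    data.frame(barcode = g$barcode,
               in_tissue = as.integer(g$in_tissue),
               array_row = g$array_row, array_col = g$array_col,
               pxl_row_in_fullres = g$pxl_row, pxl_col_in_fullres = g$pxl_col),
    positions_path, row.names = FALSE, quote = FALSE)

  counts_dir <- file.path(dir, "counts")
  dir.create(counts_dir, showWarnings = FALSE)
  m <- Matrix::Matrix(t(slide$counts), sparse = TRUE)  # features x barcodes
  Matrix::writeMM(m, file.path(counts_dir, "matrix.mtx"))
  writeLines(colnames(slide$counts), file.path(counts_dir, "features.tsv"))
  writeLines(rownames(slide$counts), file.path(counts_dir, "barcodes.tsv"))

  truth_path <- file.path(dir, "truth_labels.csv")
  utils::write.csv(data.frame(barcode = names(slide$truth_labels),
                              layer = as.integer(slide$truth_labels)),
                   truth_path, row.names = FALSE, quote = FALSE)

  sf_path <- file.path(dir, "scalefactors.json")
  jsonlite::write_json(list(spot_diameter_fullres = spot_diameter(g)),
                       sf_path, auto_unbox = TRUE)

  invisible(list(image = image_path, positions = positions_path,
                 counts = counts_dir, truth = truth_path,
                 scalefactors = sf_path))
}
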