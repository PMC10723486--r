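#' Count matrices
#'
#' A `count_matrix` pairs a spot x gene matrix with its spot and gene
#' identifiers and a flag saying whether it holds raw integer counts or
#' normalized expression. Row order always matches the in-tissue spot order
#' of the accompanying grid (ascending array row, then array column).
#'
#' @param values spot x gene matrix with barcode rownames and gene colnames.
#' @param normalized logical; `TRUE` once counts have been normalized.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop_invalid("values must be a matrix with barcode rownames and gene colnames")
  if (anyDuplicated(colnames(values)))
    stop_format("gene_ids must be unique")
  if (any(values < 0)) stop_invalid("counts must be nonnegative")
  if (!normalized && any(values != round(values)))
    stop_invalid("raw counts must be integers")
  structure(list(values = values,
                 spot_ids = rownames(values),
                 gene_ids = colnames(values),
                 normalized = isTRUE(normalized)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d spots x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Tile stacks
#'
#' A `tile_stack` holds one square 3-channel image tile per in-tissue spot
#' (a 4-d array: spot, row, col, channel) along with dataset-level
#' per-channel statistics once standardized.
#'
#' @param tiles n x side x side x 3 numeric array.
#' @param spot_ids character vector of length n.
#' @param normalized logical.
#' @param channel_mean,channel_sd per-channel statistics used for
#'   standardization (required when `normalized = TRUE`).
#' @return An object of class `tile_stack`.
#' @export
tile_stack <- function(tiles, spot_ids, normalized = FALSE,
                       channel_mean = NULL, channel_sd = NULL) {
  if (length(dim(tiles)) != 4L || dim(tiles)[4] != 3L)
    stop_invalid("tiles must be an n x side x side x 3 array")
  if (dim(tiles)[2] != dim(tiles)[3])
    stop_invalid("tiles must be square")
  if (dim(tiles)[1] != length(spot_ids))
    stop_invalid("one tile per spot id required")
  if (isTRUE(normalized)) {
    if (is.null(channel_mean) || is.null(channel_sd))
      stop_invalid("normalized tile stacks must carry channel statistics")
    if (any(channel_sd <= 0))
      stop_invalid("channel_sd must be > 0 when normalized")
  }
  structure(list(tiles = tiles, spot_ids = spot_ids,
                 side = dim(tiles)[2], normalized = isTRUE(normalized),
                 channel_mean = channel_mean, channel_sd = channel_sd),
            class = "tile_stack")
}

#' @export
print.tile_stack <- function(x, ...) {
  cat(sprintf("tile_stack: %d tiles of %d x %d px (%s)\n",
              length(x$spot_ids), x$side, x$side,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_format("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop_format("unsupported image format '.%s' (PNG or TIFF expected)", ext)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

read_positions <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 6L)
    stop_format("positions file must have 6 columns (Space Ranger dialect)")
  df <- df[, 1:6]
  names(df) <- c("barcode", "in_tissue", "array_row", "array_col",
                 "pxl_row", "pxl_col")
  df$in_tissue <- as.logical(as.integer(df$in_tissue))
  df
}

read_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    bc  <- file.path(path, "barcodes.tsv")
    ft  <- file.path(path, "features.tsv")
    if (!file.exists(mtx)) stop_format("no matrix.mtx in %s", path)
    m <- as.matrix(Matrix::readMM(mtx))   # features x barcodes
    genes <- readLines(ft)
    barcodes <- readLines(bc)
    # features.tsv may carry extra columns (id, name, type)
    genes <- vapply(strsplit(genes, "\t"), `[[`, "", 1L)
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
      stop_format("matrix.mtx dimensions do not match barcodes/features")
    out <- t(m)
    dimnames(out) <- list(barcodes, genes)
    out
  } else if (tolower(tools::file_ext(path)) == "csv") {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    as.matrix(df)
  } else {
    stop_format("counts must be an MTX bundle directory or a dense CSV, got %s",
                path)
  }
}

#' Read a spatial slide bundle
#'
#' Loads the image, the tissue-positions table, and the count matrix; keeps
#' only in-tissue spots; orders spots ascending by array row then array
#' column; and reorders the count rows to match. Spots not covered by tissue
#' are dropped here so every downstream stage sees in-tissue spots only.
#'
#' @param image_path PNG or TIFF slide image.
#' @param positions_path tissue-positions CSV (Space Ranger column order,
#'   header auto-detected).
#' @param counts_path either a directory holding `matrix.mtx` +
#'   `barcodes.tsv` + `features.tsv` (features x barcodes) or a dense CSV
#'   with barcodes as the first column and genes as the header.
#' @param spot_diameter_px the spot diameter in full-resolution pixels.
#' @return A list with `image` (H x W x 3, 0–255), `grid` (a [spot_grid()]
#'   of in-tissue spots) and `counts` (a raw [count_matrix()]).
#' @export
read_slide_bundle <- function(image_path, positions_path, counts_path,
                              spot_diameter_px) {
  for (p in c(image_path, positions_path))
    if (!file.exists(p)) stop_format("file not found: %s", p)
  if (!file.exists(counts_path) && !dir.exists(counts_path))
    stop_format("file not found: %s", counts_path)
  image <- read_image(image_path)
  pos <- read_positions(positions_path)
  counts <- read_counts(counts_path)

  pos <- pos[pos$in_tissue, , drop = FALSE]
  missing <- setdiff(pos$barcode, rownames(counts))
  if (length(missing))
    stop_format("in-tissue barcodes absent from counts: %s",
                paste(utils::head(missing, 5L), collapse = ", "))
  grid <- spot_grid(pos, spot_diameter_px)
  counts <- counts[grid$barcode, , drop = FALSE]
  storage.mode(counts) <- "double"

  d <- round(spot_diameter_px)
  off <- floor(d / 2)
  if (any(grid$pxl_row - off < 0) || any(grid$pxl_col - off < 0) ||
      any(grid$pxl_row - off + d > dim(image)[1]) ||
      any(grid$pxl_col - off + d > dim(image)[2]))
    stop_bounds("image (%d x %d px) too small for the tile footprints",
                dim(image)[1], dim(image)[2])

  list(image = image, grid = grid, counts = count_matrix(counts))
}

#' Extract per-spot image tiles
#'
#' Cuts one square tile per in-tissue spot, of side `round(spot_diameter_px)`
#' and centered on the spot's pixel coordinates. Centering uses a
#' `floor(side/2)` top-left offset from the (0-based) center so extraction is
#' reproducible bit-exactly for odd and even sides alike.
#'
#' @param image H x W x 3 numeric array (0–255).
#' @param grid a `spot_grid`.
#' @return A raw [tile_stack()], one tile per in-tissue spot in grid order.
#' @export
extract_tiles <- function(image, grid) {
  if (length(dim(image)) != 3L) stop_invalid("image must be H x W x 3")
  g <- in_tissue_grid(grid)
  d <- as.integer(round(spot_diameter(grid)))
  off <- floor(d / 2L)
  r0 <- g$pxl_row - off
  c0 <- g$pxl_col - off
  bad <- r0 < 0 | c0 < 0 | r0 + d > dim(image)[1] | c0 + d > dim(image)[2]
  if (any(bad))
    stop_bounds("tile footprint outside image for spots: %s",
                paste(utils::head(g$barcode[bad], 5L), collapse = ", "))
  tiles <- array(0, dim = c(nrow(g), d, d, 3L))
  for (i in seq_len(nrow(g)))
    tiles[i, , , ] <- image[r0[i] + seq_len(d), c0[i] + seq_len(d), ]
  tile_stack(tiles, g$barcode)
}
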