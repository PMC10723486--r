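#' Hexagonal spot grids
#'
#' A `spot_grid` stores the spot layout of a Visium-style capture area: one
#' row per spot with its barcode, array coordinates (the hexagonal lattice
#' convention in which row `r` holds array columns of parity `r %% 2`),
#' full-resolution pixel coordinates of the spot center (0-based, row/col
#' order matching image indexing), and an in-tissue flag. The spot diameter
#' in pixels is carried as an attribute; it is the side length of the square
#' image tile extracted around each spot.
#'
#' @param positions data.frame with columns `barcode`, `in_tissue`,
#'   `array_row`, `array_col`, `pxl_row`, `pxl_col`.
#' @param spot_diameter_px positive number, spot diameter in pixels.
#' @return An object of class `spot_grid` (a data.frame subclass).
#' @export
spot_grid <- function(positions, spot_diameter_px) {
  req <- c("barcode", "in_tissue", "array_row", "array_col", "pxl_row", "pxl_col")
  if (!all(req %in% names(positions)))
    stop_format("positions must have columns: %s", paste(req, collapse = ", "))
  if (!is.numeric(spot_diameter_px) || length(spot_diameter_px) != 1L ||
      spot_diameter_px < 1)
    stop_invalid("spot_diameter_px must be a single number >= 1")
  if (anyDuplicated(positions$barcode))
    stop_format("duplicate barcodes: %s",
                paste(unique(positions$barcode[duplicated(positions$barcode)]),
                      collapse = ", "))
  key <- paste(positions$array_row, positions$array_col)
  if (anyDuplicated(key))
    stop_format("duplicate array coordinates: %s",
                paste(unique(key[duplicated(key)]), collapse = "; "))
  positions <- positions[order(positions$array_row, positions$array_col), ,
                         drop = FALSE]
  rownames(positions) <- NULL
  structure(positions,
            spot_diameter_px = as.numeric(spot_diameter_px),
            class = c("spot_grid", "data.frame"))
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf("spot_grid: %d spots (%d in tissue), %d array rows x %d array cols, spot diameter %g px\n",
              nrow(x), sum(x$in_tissue),
              length(unique(x$array_row)), length(unique(x$array_col)),
              attr(x, "spot_diameter_px")))
  invisible(x)
}

#' Spot diameter of a grid, in pixels
#' @param grid a `spot_grid`.
#' @return A single number.
#' @export
spot_diameter <- function(grid) attr(grid, "spot_diameter_px")

#' Construct a full Visium-style hexagonal grid
#'
#' Builds a rectangular capture-area grid in the Visium array-coordinate
#' convention: `n_rows` array rows; within row `r` the `n_cols` spots sit at
#' array columns `2*j + (r %% 2)` so that odd and even rows are offset by one
#' half step. Pixel centers are spaced so that square tiles with side
#' `spot_diameter_px` centered on the spots never overlap: the array-column
#' pixel unit is `ceiling(d/sqrt(3))` and the row unit `ceiling(unit*sqrt(3))`,
#' which makes the six lattice neighbors approximately equidistant. All spots
#' are flagged in-tissue. The full 6.5 mm Visium capture area corresponds to
#' `make_visium_grid(78, 64, d)`.
#'
#' @param n_rows,n_cols positive integers, array rows and spots per row.
#' @param spot_diameter_px positive integer, spot (and tile) diameter in px.
#' @return A `spot_grid` with `n_rows * n_cols` spots.
#' @examples
#' g <- make_visium_grid(6, 4, 12)
#' length(unique(g$array_row))
#' @export
make_visium_grid <- function(n_rows, n_cols, spot_diameter_px) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 1 || n_cols < 1)
    stop_invalid("n_rows and n_cols must be positive integers")
  if (!is.numeric(spot_diameter_px) || spot_diameter_px < 1)
    stop_invalid("spot_diameter_px must be >= 1")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  d <- as.integer(round(spot_diameter_px))
  r <- rep(seq_len(n_rows) - 1L, each = n_cols)
  j <- rep(seq_len(n_cols) - 1L, times = n_rows)
  array_col <- 2L * j + r %% 2L
  ux <- as.integer(ceiling(d / sqrt(3)))     # px per array-column unit
  uy <- as.integer(ceiling(ux * sqrt(3)))    # px per array-row unit (>= d)
  margin <- d                                 # border so corner tiles fit
  positions <- data.frame(
    barcode   = sprintf("SPOT-%04d-%04d", r, array_col),
    in_tissue = TRUE,
    array_row = r,
    array_col = array_col,
    pxl_row   = margin + r * uy,
    pxl_col   = margin + array_col * ux,
    stringsAsFactors = FALSE
  )
  spot_grid(positions, d)
}

# The six hexagonal lattice neighbor offsets in (array_row, array_col).
.hex_offsets <- cbind(
  dr = c(0L, 0L, 1L, 1L, -1L, -1L),
  dc = c(2L, -2L, 1L, -1L, 1L, -1L)
)

#' Hexagonal lattice neighbors of a spot
#'
#' The Visium array stores a hexagonal packing in doubled column coordinates:
#' the (up to six) lattice neighbors of a spot sit at array offsets
#' (0, +/-2) and (+/-1, +/-1). Only in-tissue spots are returned.
#'
#' @param grid a `spot_grid`.
#' @param spot a barcode present in `grid`.
#' @return Character vector of neighbor barcodes (possibly empty).
#' @export
lattice_neighbors <- function(grid, spot) {
  i <- match(spot, grid$barcode)
  if (is.na(i)) stop_invalid("unknown spot '%s'", spot)
  key <- paste(grid$array_row, grid$array_col)
  cand <- paste(grid$array_row[i] + .hex_offsets[, "dr"],
                grid$array_col[i] + .hex_offsets[, "dc"])
  idx <- match(cand, key)
  idx <- idx[!is.na(idx)]
  idx <- idx[grid$in_tissue[idx]]
  grid$barcode[idx]
}

# Neighbor index list for every in-tissue spot; used throughout the package.
# Returns a list parallel to the rows of `grid` with integer row indices.
neighbor_index <- function(grid) {
  key <- paste(grid$array_row, grid$array_col)
  lookup <- seq_len(nrow(grid))
  names(lookup) <- key
  out <- vector("list", nrow(grid))
  for (k in seq_len(6L)) {
    cand <- paste(grid$array_row + .hex_offsets[k, "dr"],
                  grid$array_col + .hex_offsets[k, "dc"])
    hit <- lookup[cand]
    for (i in which(!is.na(hit))) {
      j <- hit[[i]]
      if (grid$in_tissue[j]) out[[i]] <- c(out[[i]], j)
    }
  }
  lapply(out, function(v) sort(v %||% integer(0)))
}

# Subset a grid to its in-tissue spots, preserving attributes.
in_tissue_grid <- function(grid) {
  g <- grid[grid$in_tissue, , drop = FALSE]
  rownames(g) <- NULL
  structure(g, spot_diameter_px = attr(grid, "spot_diameter_px"),
            class = c("spot_grid", "data.frame"))
}
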