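#' Normalize spot counts
#'
#' Per-slide count normalization in the style standard for single-cell RNA
#' data: each entry is scaled by the slide's average total count per spot,
#' multiplied by a target count `t`, and log-transformed,
#' \deqn{\tilde X_{s,g} = \ln\!\big(1 + t\, X_{s,g} \,/\, (\Sigma X / |S|)\big),}
#' where \eqn{\Sigma X / |S|} is the average total count per spot over the
#' slide. The default target is `t = 1e4` average counts per spot. The
#' transform is monotone per entry, order-preserving within a spot, and
#' invariant to a global rescaling of the raw counts.
#'
#' @param counts a raw [count_matrix()].
#' @param t positive target average count per spot (default `1e4`).
#' @return A normalized [count_matrix()].
#' @examples
#' x <- count_matrix(matrix(c(1, 2, 1, 0), 2, 2,
#'                          dimnames = list(c("s1", "s2"), c("g1", "g2"))))
#' normalize_counts(x)$values["s1", "g1"]  # log(1 + 1e4 * 1/2)
#' @export
normalize_counts <- function(counts, t = 1e4) {
  if (!inherits(counts, "count_matrix")) stop_invalid("counts must be a count_matrix")
  if (counts$normalized) stop_invalid("counts are already normalized")
  if (!is.numeric(t) || t <= 0) stop_invalid("t must be positive")
  avg <- sum(counts$values) / nrow(counts$values)
  if (avg == 0) stop_degenerate("all-zero count matrix cannot be normalized")
  v <- log1p(t * counts$values / avg)
  count_matrix(v, normalized = TRUE)
}

#' Per-channel statistics of a tile stack
#'
#' Mean and (sample) standard deviation of each color channel over all
#' pixels of all tiles. With multiple slides in a dataset, pool the stacks
#' first so one set of statistics covers the whole dataset
#' (`tile_stats(list_of_stacks)` accepts a list), or pass a single stack for
#' per-slide statistics.
#'
#' @param tiles a raw [tile_stack()] or a list of them.
#' @return A list with `mean` and `sd`, each length 3.
#' @export
tile_stats <- function(tiles) {
  stacks <- if (inherits(tiles, "tile_stack")) list(tiles) else tiles
  if (!all(vapply(stacks, inherits, TRUE, "tile_stack")))
    stop_invalid("tiles must be a tile_stack or list of tile_stacks")
  if (any(vapply(stacks, function(s) s$normalized, TRUE)))
    stop_invalid("tile statistics are computed on raw tiles")
  ch <- function(k) unlist(lapply(stacks, function(s) as.vector(s$tiles[, , , k])))
  m <- vapply(1:3, function(k) mean(ch(k)), 0)
  s <- vapply(1:3, function(k) stats::sd(ch(k)), 0)
  list(mean = m, sd = s)
}

#' Standardize tiles per channel
#'
#' Subtracts the per-channel mean and divides by the per-channel standard
#' deviation, both computed over all pixels of all tiles in the dataset
#' (pass `stats` to reuse statistics computed elsewhere — e.g. the training
#' dataset's statistics at inference time, or pooled multi-slide
#' statistics). The statistics used are stored on the returned stack for
#' reuse and for the encoder's fingerprint check.
#'
#' @param tiles a raw [tile_stack()].
#' @param stats optional list with `mean` and `sd` (length 3 each) to reuse;
#'   when `NULL`, statistics are computed from `tiles` itself.
#' @return A normalized [tile_stack()].
#' @export
normalize_tiles <- function(tiles, stats = NULL) {
  if (!inherits(tiles, "tile_stack")) stop_invalid("tiles must be a tile_stack")
  if (tiles$normalized) stop_invalid("tiles are already normalized")
  st <- stats %||% tile_stats(tiles)
  if (any(!is.finite(st$sd)) || any(st$sd <= 0))
    stop_degenerate("zero variance in a color channel; tiles cannot be standardized")
  out <- tiles$tiles
  for (k in 1:3) out[, , , k] <- (out[, , , k] - st$mean[k]) / st$sd[k]
  tile_stack(out, tiles$spot_ids, normalized = TRUE,
             channel_mean = st$mean, channel_sd = st$sd)
}

#' Persist or restore tile statistics
#'
#' Tile statistics are written as a small JSON sidecar so the exact training
#' standardization can be reapplied at inference time.
#'
#' @param stats list with `mean` and `sd`.
#' @param path JSON file path.
#' @return `write_tile_stats` returns `path` invisibly; `read_tile_stats`
#'   returns the statistics list.
#' @export
write_tile_stats <- function(stats, path) {
  jsonlite::write_json(lapply(stats, as.numeric), path, digits = NA)
  invisible(path)
}

#' @rdname write_tile_stats
#' @export
read_tile_stats <- function(path) {
  st <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(mean = as.numeric(st$mean), sd = as.numeric(st$sd))
}
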