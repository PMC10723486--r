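#' Length-normalize a trajectory onto the unit axis
#'
#' Paths through different samples have different lengths `k`, so
#' trajectories are resampled onto a common relative axis: the start of the
#' path sits at 0, the end at 1, path index `i` at `(i-1)/(k-1)`, and each
#' gene is linearly interpolated at every 0.01 step, giving exactly 101
#' position rows. The endpoints are preserved exactly, and every
#' interpolated value lies within the range of its source column. With
#' `spacing = "cost"` the path indices are instead placed at the normalized
#' cumulative edge weight (an option for traversals whose embedding
#' distances should stretch the axis).
#'
#' @param traj a `trajectory_matrix` with `k >= 2`.
#' @param spacing `"uniform"` (default) or `"cost"`.
#' @param graph a `lattice_graph`, required for `spacing = "cost"`.
#' @return An object of class `normalized_trajectory`: `values`
#'   (101 x genes), `positions` (0, 0.01, ..., 1), `gene_ids`, `source`.
#' @export
length_normalize <- function(traj, spacing = c("uniform", "cost"),
                             graph = NULL) {
  spacing <- match.arg(spacing)
  if (!inherits(traj, "trajectory_matrix"))
    stop_invalid("traj must be a trajectory_matrix")
  k <- nrow(traj$values)
  if (k < 2L)
    stop_degenerate("a path of %d spot(s) cannot be length-normalized", k)
  if (spacing == "uniform") {
    x <- (seq_len(k) - 1) / (k - 1)
  } else {
    if (is.null(graph)) stop_invalid("spacing = 'cost' requires the graph")
    key <- paste(pmin(graph$edges$from, graph$edges$to),
                 pmax(graph$edges$from, graph$edges$to))
    w <- graph$edges$weight[match(paste(pmin(utils::head(traj$path$spots, -1),
                                             traj$path$spots[-1]),
                                        pmax(utils::head(traj$path$spots, -1),
                                             traj$path$spots[-1])), key)]
    if (any(is.na(w))) stop_contract("path edges missing from the graph")
    cw <- c(0, cumsum(w))
    if (max(cw) == 0) x <- (seq_len(k) - 1) / (k - 1)   # all-zero cost: fall back
    else x <- cw / max(cw)
  }
  pos <- seq(0, 1, by = 0.01)
  vals <- apply(traj$values, 2L, function(y)
    stats::approx(x, y, xout = pos, ties = "ordered")$y)
  # exact endpoint preservation (approx can wobble in the last ulp)
  vals[1, ] <- traj$values[1, ]
  vals[length(pos), ] <- traj$values[k, ]
  rownames(vals) <- sprintf("%.2f", pos)
  structure(list(values = vals, positions = pos,
                 gene_ids = traj$gene_ids,
                 source = sprintf("%s->%s", traj$path$spots[1],
                                  traj$path$spots[k])),
            class = "normalized_trajectory")
}

#' @export
print.normalized_trajectory <- function(x, ...) {
  cat(sprintf("normalized_trajectory: 101 positions x %d genes (%s)\n",
              ncol(x$values), x$source))
  invisible(x)
}

#' Average length-normalized trajectories
#'
#' Per gene and per relative position: the mean, the sample standard
#' deviation, and a normal-approximation 95% confidence band
#' `mean +/- 1.96 * sd / sqrt(n)`. With a single trajectory the mean equals
#' it and the band is omitted (`NA`), since the sample sd is undefined at
#' `n = 1`.
#'
#' @param trajs list of `normalized_trajectory` objects over a common gene
#'   set (same genes, same order).
#' @return An object of class `trajectory_summary` with `mean`, `sd`,
#'   `lower`, `upper` (each 101 x genes) and `n`.
#' @export
average_trajectories <- function(trajs) {
  if (!is.list(trajs) || length(trajs) < 1L ||
      !all(vapply(trajs, inherits, TRUE, "normalized_trajectory")))
    stop_invalid("trajs must be a non-empty list of normalized trajectories")
  genes <- trajs[[1]]$gene_ids
  for (t in trajs)
    if (!identical(t$gene_ids, genes))
      stop_contract("trajectories cover different gene sets")
  n <- length(trajs)
  arr <- array(unlist(lapply(trajs, `[[`, "values")),
               dim = c(101L, length(genes), n))
  m <- apply(arr, c(1, 2), mean)
  s <- if (n > 1L) apply(arr, c(1, 2), stats::sd) else
    matrix(NA_real_, 101L, length(genes))
  half <- 1.96 * s / sqrt(n)
  dimnames(m) <- dimnames(s) <- list(sprintf("%.2f", trajs[[1]]$positions), genes)
  structure(list(mean = m, sd = s, lower = m - half, upper = m + half, n = n),
            class = "trajectory_summary")
}

#' Build the pool of reasonable start/end anchor pairs
#'
#' Mimics how a user would choose anchors on a sample whose layers are
#' stacked across the slide: the candidate start spots `A` and end spots
#' `B` lie on the two outer tissue edges and are ordered top to bottom (by
#' the pixel row, i.e. the y coordinate). Start `a_i` is paired with every
#' end spot within a window of radius `r` around its opposite position
#' `b_i`, so each start has at most `2r + 1` partners and the pairs connect
#' the edges roughly perpendicular to the layer boundaries. When the two
#' edges have different lengths the window is centered at the
#' proportionally scaled position.
#'
#' @param grid a `spot_grid`.
#' @param start_edge,end_edge barcodes of the candidate start and end spots.
#' @param r window radius (default 15).
#' @return An object of class `pair_pool` with `starts`, `ends` (sorted by
#'   y), `r`, and `pairs` (data.frame `start`, `end`).
#' @export
build_pair_pool <- function(grid, start_edge, end_edge, r = 15L) {
  if (length(start_edge) == 0L || length(end_edge) == 0L)
    stop_invalid("edge lists must be non-empty")
  g <- in_tissue_grid(grid)
  for (e in list(start_edge, end_edge)) {
    miss <- setdiff(e, g$barcode)
    if (length(miss))
      stop_invalid("edge spots not in grid: %s",
                   paste(utils::head(miss, 5L), collapse = ", "))
  }
  y <- g$pxl_row[match(start_edge, g$barcode)]
  A <- start_edge[order(y)]
  y <- g$pxl_row[match(end_edge, g$barcode)]
  B <- end_edge[order(y)]
  nA <- length(A); nB <- length(B)
  pairs <- do.call(rbind, lapply(seq_len(nA), function(i) {
    ci <- if (nA == 1L) 1L else round(1 + (i - 1) * (nB - 1) / (nA - 1))
    j <- max(ci - r, 1L):min(ci + r, nB)
    data.frame(start = A[i], end = B[j], stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  structure(list(starts = A, ends = B, r = as.integer(r), pairs = pairs),
            class = "pair_pool")
}

#' @export
print.pair_pool <- function(x, ...) {
  cat(sprintf("pair_pool: %d starts x %d ends, radius %d -> %d pairs\n",
              length(x$starts), length(x$ends), x$r, nrow(x$pairs)))
  invisible(x)
}

#' Sample start/end pairs without replacement
#'
#' @param pool a `pair_pool`.
#' @param n number of pairs (default 100).
#' @param seed integer seed.
#' @return A data.frame of `n` distinct `(start, end)` pairs.
#' @export
sample_pairs <- function(pool, n = 100L, seed = 1L) {
  if (!inherits(pool, "pair_pool")) stop_invalid("pool must be a pair_pool")
  nz <- nrow(pool$pairs)
  if (nz < n)
    stop_invalid("cannot sample %d pairs from a pool of %d", n, nz)
  idx <- with_seed(seed, sample.int(nz, n))
  out <- pool$pairs[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman rank concordance between two trajectories
#'
#' Spearman's rank correlation with average-rank handling of ties; used to
#' quantify agreement between two length-normalized gene trajectories (for
#' example, between an external depth-based alignment and each sampled
#' traversal).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' spearman_concordance(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
spearman_concordance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_invalid("x and y must have equal length >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_invalid("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_degenerate("correlation is undefined for a constant input")
  stats::cor(x, y, method = "spearman")
}
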