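#' Assign every spot to its nearest path tile
#'
#' Projects the slide onto the one-dimensional traversal: each in-tissue
#' spot is assigned to the path index whose tile embedding is nearest in
#' Euclidean distance. Ties are broken by the smallest path index
#' (earliest along the path), so a path spot is always assigned to its own
#' index — its self-distance is zero — and the assignment sets
#' \eqn{S_p = \{s : C(s) = p\}} partition the spot set.
#'
#' @param emb an `embedding_set` covering all spots and all path spots.
#' @param path a `traversal_path`.
#' @return An object of class `assignment_map`: a list with `assignment`
#'   (named integer, 1-based path index per spot) and `path`.
#' @export
assign_spots <- function(emb, path) {
  if (!inherits(path, "traversal_path") || path$k < 1L)
    stop_invalid("path must be a non-empty traversal_path")
  miss <- setdiff(path$spots, rownames(emb))
  if (length(miss))
    stop_contract("embeddings missing for path spots: %s",
                  paste(utils::head(miss, 5L), collapse = ", "))
  E <- unclass(emb)
  P <- E[path$spots, , drop = FALSE]
  # n x k squared distances via the quadratic expansion
  d2 <- outer(rowSums(E^2), rep(1, path$k)) +
    outer(rep(1, nrow(E)), rowSums(P^2)) - 2 * E %*% t(P)
  d2[d2 < 0] <- 0                                    # float guard
  d2[cbind(match(path$spots, rownames(E)), seq_len(path$k))] <- 0  # exact self-distance
  assignment <- apply(d2, 1L, which.min)  # which.min: first index on ties
  names(assignment) <- rownames(E)
  structure(list(assignment = assignment, path = path),
            class = "assignment_map")
}

#' @export
print.assignment_map <- function(x, ...) {
  cat(sprintf("assignment_map: %d spots over %d path tiles\n",
              length(x$assignment), x$path$k))
  invisible(x)
}

#' Average expression within each assignment set
#'
#' Produces the gene expression trajectory: row `p` of the result is the
#' mean normalized expression over the assignment set \eqn{S_p}, ordered
#' along the path from the start anchor to the end anchor. Every set is
#' non-empty because each path spot belongs to its own set. The weighted
#' mean of the rows (weights \eqn{|S_p|}) reconstructs the global per-gene
#' mean exactly.
#'
#' @param counts_norm a normalized [count_matrix()].
#' @param assign an `assignment_map` over the same spots.
#' @return An object of class `trajectory_matrix`: `values` (k x genes),
#'   `path`, `gene_ids`, and `set_sizes`.
#' @export
average_along_path <- function(counts_norm, assign) {
  if (!inherits(counts_norm, "count_matrix") || !counts_norm$normalized)
    stop_invalid("counts_norm must be a normalized count_matrix")
  if (!inherits(assign, "assignment_map"))
    stop_invalid("assign must be an assignment_map")
  if (!setequal(counts_norm$spot_ids, names(assign$assignment)))
    stop_contract("spot ids of counts and assignment do not match")
  a <- assign$assignment[counts_norm$spot_ids]
  k <- assign$path$k
  sizes <- tabulate(a, nbins = k)
  if (any(sizes == 0L))
    stop_contract("empty assignment set encountered (path spot missing)")
  sums <- rowsum(counts_norm$values, group = factor(a, levels = seq_len(k)))
  values <- sums / sizes
  rownames(values) <- assign$path$spots
  structure(list(values = values, path = assign$path,
                 gene_ids = counts_norm$gene_ids, set_sizes = sizes),
            class = "trajectory_matrix")
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("trajectory_matrix: %d path tiles x %d genes (set sizes %d-%d)\n",
              nrow(x$values), ncol(x$values), min(x$set_sizes), max(x$set_sizes)))
  invisible(x)
}

#' Quantize external per-spot depths into assignment levels
#'
#' Adapter for aligners that return a scalar depth per spot (such as
#' conformal-mapping layer methods): each depth is rounded
#' half-away-from-zero to an integer level, and levels are re-indexed to
#' consecutive 1-based integers preserving depth order. The number of
#' levels `k` is the number of unique rounded depths, which can then be
#' length-normalized like any trajectory (linear spacing is assumed).
#'
#' @param depths named numeric vector of finite per-spot depths.
#' @return A list with `levels` (named 1-based integer per spot), `k`, and
#'   `rounded` (the unique rounded depths in increasing order).
#' @export
depths_to_assignments <- function(depths) {
  if (any(!is.finite(depths))) stop_invalid("depths must be finite")
  r <- sign(depths) * floor(abs(depths) + 0.5)   # round half away from zero
  uq <- sort(unique(r))
  levels <- match(r, uq)
  names(levels) <- names(depths)
  list(levels = levels, k = length(uq), rounded = uq)
}
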