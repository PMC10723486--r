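#' Quantize an alignment into discrete tissue layers
#'
#' Uses annotated layer boundaries as an oracle: walking the traversal path
#' from start to end, the first path index whose spot lies on boundary `l`
#' marks the crossing into layer `l + 1` (the boundary spot itself starts
#' the next layer — a half-open convention). The path indices thus split
#' into `L` contiguous runs, layer `l` is the union of the assignment sets
#' of the path tiles in run `l`, and each spot inherits the run of its
#' assigned path tile. Once a later boundary has been crossed, re-entries
#' into an earlier boundary are ignored (only first crossings count), but
#' meeting a later boundary before an earlier one is an annotation error.
#'
#' @param assign an `assignment_map`.
#' @param bounds ordered list of boundary spot sets (character vectors of
#'   barcodes), ordered along the traversal direction; `L - 1` boundaries
#'   define `L` layers. An empty list yields a single layer.
#' @return An object of class `segment_labels`: a list with `labels` (named
#'   1-based integer per spot, non-decreasing in path index), `L`, and
#'   `cuts` (first-crossing path indices).
#' @export
segment_from_path <- function(assign, bounds) {
  if (!inherits(assign, "assignment_map"))
    stop_invalid("assign must be an assignment_map")
  if (!is.list(bounds) && !is.null(bounds))
    stop_invalid("bounds must be a list of barcode sets")
  bounds <- bounds %||% list()
  path <- assign$path
  nb <- length(bounds)
  cuts <- integer(0)
  nxt <- 1L
  if (nb > 0L) {
    membership <- matrix(FALSE, path$k, nb)
    for (l in seq_len(nb))
      membership[, l] <- path$spots %in% bounds[[l]]
    for (i in seq_len(path$k)) {
      hit <- which(membership[i, ])
      hit <- hit[hit >= nxt]             # first crossings only
      if (length(hit)) {
        if (min(hit) > nxt)
          stop_annotation("path crosses boundary %d before boundary %d",
                          min(hit), nxt)
        cuts <- c(cuts, i)
        nxt <- nxt + 1L
        if (nxt > nb) break
      }
    }
    if (nxt <= nb)
      stop_annotation("boundary %d ('%s') is never crossed by the path", nxt,
                      names(bounds)[nxt] %||% as.character(nxt))
  }
  run <- findInterval(seq_len(path$k), cuts) + 1L   # run of each path index
  labels <- run[assign$assignment]
  names(labels) <- names(assign$assignment)
  structure(list(labels = labels, L = nb + 1L, cuts = cuts),
            class = "segment_labels")
}

#' @export
print.segment_labels <- function(x, ...) {
  cat(sprintf("segment_labels: %d spots in %d layers (sizes: %s)\n",
              length(x$labels), x$L,
              paste(tabulate(x$labels, x$L), collapse = ", ")))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same spot set,
#' computed from the contingency table under the permutation model:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12(\sum_i\binom{a_i}{2} + \sum_j\binom{b_j}{2}) - E},}
#' with \eqn{E = \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2} / \binom{n}{2}}.
#' Invariant to label renaming; 1 for identical partitions (including the
#' degenerate case where both partitions are trivial).
#'
#' @param labels_a,labels_b integer/factor label vectors. If both are
#'   named, they are matched by name; otherwise they must be positionally
#'   aligned and of equal length.
#' @return ARI, at most 1.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (inherits(labels_a, "segment_labels")) labels_a <- labels_a$labels
  if (inherits(labels_b, "segment_labels")) labels_b <- labels_b$labels
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stop_contract("labelings cover different spot sets")
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop_contract("labelings have different lengths")
  }
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps * max(1, max_index))
    return(1)   # both partitions trivial and identical in structure
  (sum_ij - expected) / (max_index - expected)
}
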