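#' Embedding-weighted lattice graph
#'
#' Builds the undirected graph whose vertices are the in-tissue spots and
#' whose edges connect hexagonal-lattice-adjacent spots, each edge weighted
#' by the Euclidean distance between the endpoint tile embeddings. Edges of
#' weight exactly zero are legal (identical embeddings); no epsilon floor is
#' added.
#'
#' @param grid a `spot_grid`.
#' @param emb an `embedding_set` covering every in-tissue spot.
#' @return An object of class `lattice_graph` with `vertices` (barcodes) and
#'   `edges` (data.frame `from`, `to`, `weight`).
#' @export
build_graph <- function(grid, emb) {
  g <- in_tissue_grid(grid)
  miss <- setdiff(g$barcode, rownames(emb))
  if (length(miss))
    stop_contract("embeddings missing for spots: %s",
                  paste(utils::head(miss, 5L), collapse = ", "))
  E <- emb[g$barcode, , drop = FALSE]
  nb <- neighbor_index(g)
  from <- integer(0); to <- integer(0)
  for (i in seq_along(nb)) {
    js <- nb[[i]][nb[[i]] > i]   # undirected: record each pair once
    from <- c(from, rep(i, length(js)))
    to <- c(to, js)
  }
  w <- sqrt(rowSums((E[from, , drop = FALSE] - E[to, , drop = FALSE])^2))
  structure(list(vertices = g$barcode,
                 edges = data.frame(from = g$barcode[from],
                                    to = g$barcode[to],
                                    weight = w, stringsAsFactors = FALSE)),
            class = "lattice_graph")
}

#' @export
print.lattice_graph <- function(x, ...) {
  cat(sprintf("lattice_graph: %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

# adjacency list of (neighbor index, weight), symmetric
.adjacency <- function(graph) {
  n <- length(graph$vertices)
  i <- match(graph$edges$from, graph$vertices)
  j <- match(graph$edges$to, graph$vertices)
  adj <- rep(list(list(idx = integer(0), w = numeric(0))), n)
  for (k in seq_along(i)) {
    adj[[i[k]]]$idx <- c(adj[[i[k]]]$idx, j[k])
    adj[[i[k]]]$w <- c(adj[[i[k]]]$w, graph$edges$weight[k])
    adj[[j[k]]]$idx <- c(adj[[j[k]]]$idx, i[k])
    adj[[j[k]]]$w <- c(adj[[j[k]]]$w, graph$edges$weight[k])
  }
  adj
}

.reconstruct <- function(parent, v) {
  path <- v
  while (!is.na(parent[v])) { v <- parent[v]; path <- c(v, path) }
  path
}

# -1 if path a < path b lexicographically on barcodes, 1 if >, 0 if equal
.lex_cmp <- function(a, b, labels) {
  la <- labels[a]; lb <- labels[b]
  n <- min(length(la), length(lb))
  for (k in seq_len(n)) {
    if (la[k] < lb[k]) return(-1L)
    if (la[k] > lb[k]) return(1L)
  }
  sign(length(la) - length(lb))
}

#' Shortest path between two anchor spots
#'
#' Dijkstra's algorithm over the embedding-weighted lattice graph: the
#' returned path minimizes the summed edge weights among all lattice paths
#' from `a` to `b`, so it respects spot adjacency and never skips over
#' spots. Ties are broken first by fewest spots, then by the
#' lexicographically smallest barcode sequence, making the traversal
#' reproducible across runs and platforms.
#'
#' @param graph a `lattice_graph`.
#' @param a,b start and end anchor barcodes (any in-tissue spots).
#' @return An object of class `traversal_path` with `spots` (ordered
#'   barcodes from `a` to `b`), `cost` (total weight) and `k` (path length
#'   in spots).
#' @export
shortest_path <- function(graph, a, b) {
  ia <- match(a, graph$vertices)
  ib <- match(b, graph$vertices)
  if (is.na(ia) || is.na(ib))
    stop_invalid("anchor spots must be vertices of the graph")
  n <- length(graph$vertices)
  adj <- .adjacency(graph)

  dist <- rep(Inf, n); hops <- rep(Inf, n)
  parent <- rep(NA_integer_, n)
  settled <- rep(FALSE, n)
  dist[ia] <- 0; hops[ia] <- 0
  repeat {
    u <- which.min(ifelse(settled, Inf, dist))
    if (!is.finite(dist[u]) || settled[u]) break
    settled[u] <- TRUE
    if (u == ib) break
    for (k in seq_along(adj[[u]]$idx)) {
      v <- adj[[u]]$idx[k]
      if (settled[v]) next
      nd <- dist[u] + adj[[u]]$w[k]
      nh <- hops[u] + 1
      better <- FALSE
      if (nd < dist[v]) better <- TRUE
      else if (nd == dist[v]) {
        if (nh < hops[v]) better <- TRUE
        else if (nh == hops[v] && !is.na(parent[v])) {
          cand <- c(.reconstruct(parent, u), v)
          cur <- .reconstruct(parent, v)
          if (.lex_cmp(cand, cur, graph$vertices) < 0) better <- TRUE
        }
      }
      if (better) { dist[v] <- nd; hops[v] <- nh; parent[v] <- u }
    }
  }
  if (!is.finite(dist[ib])) {
    comp <- .component_of(adj, ia)
    comp_b <- .component_of(adj, ib)
    stop_nopath("no path: '%s' is in component {%s, ...} and '%s' in {%s, ...}",
                a, paste(utils::head(graph$vertices[comp], 3L), collapse = ", "),
                b, paste(utils::head(graph$vertices[comp_b], 3L), collapse = ", "))
  }
  idx <- .reconstruct(parent, ib)
  structure(list(spots = graph$vertices[idx], cost = dist[ib],
                 k = length(idx)),
            class = "traversal_path")
}

.component_of <- function(adj, start) {
  seen <- rep(FALSE, length(adj))
  queue <- start; seen[start] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    new <- adj[[u]]$idx[!seen[adj[[u]]$idx]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  which(seen)
}

#' @export
print.traversal_path <- function(x, ...) {
  cat(sprintf("traversal_path: %d spots from %s to %s, cost %.6g\n",
              x$k, x$spots[1], x$spots[x$k], x$cost))
  invisible(x)
}
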