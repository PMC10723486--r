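# Shared fixtures, built once per test run and cached. The trained study
# fit is the expensive piece (a few seconds); it is shared by the
# alignment, segmentation and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

two_layer_specs <- function(n_genes = 2) {
  list(layer_spec(1, c(205, 120, 165), texture_angle = 0, noise_sd = 6,
                  gene_means = c(100, rep(5, n_genes - 1))),
       layer_spec(2, c(120, 175, 125), texture_angle = 60, noise_sd = 6,
                  gene_means = c(rep(5, n_genes - 1), 100)))
}

small_two_layer_slide <- function() {
  cache_get("slide2", function()
    make_layered_slide(make_visium_grid(12, 12, 10), two_layer_specs(),
                       layer_axis = "x", seed = 11))
}

# The reference study conditions: 3 layers, ~400 spots, 20 genes.
study_slide <- function() cache_get("slide3", function()
  simulate_study_slide(seed = 7))

# Small encoder trained on the study slide (30 epochs); shared downstream.
study_fit <- function() {
  cache_get("fit3", function() {
    sl <- study_slide()
    g <- sl$grid
    lefts <- g$barcode[g$array_col <= 1]
    rights <- g$barcode[g$array_col >= max(g$array_col) - 1]
    fit <- sttraverse(sl$image, g, sl$counts,
                      start = lefts[10], end = rights[10],
                      config = train_config("small", epochs = 30, seed = 7))
    list(fit = fit, slide = sl, lefts = lefts, rights = rights)
  })
}

# Independent shortest-path oracle: exhaustive enumeration of all simple
# paths by depth-first search, returning the minimal total weight.
brute_force_cost <- function(graph, a, b) {
  n <- length(graph$vertices)
  ia <- match(a, graph$vertices); ib <- match(b, graph$vertices)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- match(graph$edges$from[k], graph$vertices)
    j <- match(graph$edges$to[k], graph$vertices)
    w <- graph$edges$weight[k]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  best <- Inf
  visited <- rep(FALSE, n)
  dfs <- function(u, cost) {
    if (cost >= best) return()
    if (u == ib) { best <<- cost; return() }
    visited[u] <<- TRUE
    nbrs <- adj[[u]]
    if (!is.null(nbrs)) for (r in seq_len(nrow(nbrs))) {
      v <- nbrs[r, 1]
      if (!visited[v]) dfs(v, cost + nbrs[r, 2])
    }
    visited[u] <<- FALSE
  }
  dfs(ia, 0)
  best
}

# Random edge weights on a grid's lattice graph (embedding-free), seeded.
random_weight_graph <- function(grid, seed) {
  g <- sttraverse:::in_tissue_grid(grid)
  nb <- sttraverse:::neighbor_index(g)
  from <- integer(0); to <- integer(0)
  for (i in seq_along(nb)) {
    js <- nb[[i]][nb[[i]] > i]
    from <- c(from, rep(i, length(js))); to <- c(to, js)
  }
  w <- sttraverse:::with_seed(seed, stats::runif(length(from), 0.1, 2))
  structure(list(vertices = g$barcode,
                 edges = data.frame(from = g$barcode[from],
                                    to = g$barcode[to], weight = w,
                                    stringsAsFactors = FALSE)),
            class = "lattice_graph")
}
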