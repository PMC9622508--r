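# Independent oracles and small fixtures used across tests.

# Brute-force Euclidean distance transform: per-cell minimum over all pairwise
# centre distances. O(n^2); only for small grids.
brute_distance <- function(mask, grid) {
  out <- matrix(Inf, grid$n_rows, grid$n_cols)
  tr <- which(mask)
  if (length(tr) == 0) return(out)
  xy <- cell_centres(grid)
  txy <- cell_centres(grid, tr)
  for (i in seq_len(nrow(xy))) {
    out[i] <- sqrt(min((txy[, 1] - xy[i, 1])^2 + (txy[, 2] - xy[i, 2])^2))
  }
  out
}

# Exhaustive least-cost-path search by DFS over simple paths with admissible
# cost pruning (exact for strictly positive edge weights). Mirrors the
# package's edge-weight convention: step length x mean endpoint cost + 1e-9.
enumerate_lcp <- function(cost, grid, from, to, barrier = NULL,
                          crossing_cells = integer(0)) {
  nr <- grid$n_rows; nc <- grid$n_cols
  passable <- matrix(TRUE, nr, nc)
  if (!is.null(barrier)) passable <- !barrier
  passable[crossing_cells] <- TRUE
  best <- Inf
  visited <- rep(FALSE, nr * nc)
  step <- function(a, b) {
    dr <- abs((a - 1) %% nr - (b - 1) %% nr)
    dc <- abs((a - 1) %/% nr - (b - 1) %/% nr)
    (if (dr + dc == 2) sqrt(2) else 1) * grid$cell_size
  }
  nbrs <- function(v) {
    r <- (v - 1) %% nr + 1; c2 <- (v - 1) %/% nr + 1
    out <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      rr <- r + di; cc <- c2 + dj
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
        out <- c(out, (cc - 1) * nr + rr)
    }
    out
  }
  dfs <- function(v, acc) {
    if (acc >= best) return()
    if (v == to) { best <<- acc; return() }
    visited[v] <<- TRUE
    for (w in nbrs(v)) {
      if (visited[w] || !passable[w]) next
      dfs(w, acc + step(v, w) * 0.5 * (cost[v] + cost[w]) + 1e-9)
    }
    visited[v] <<- FALSE
  }
  if (!passable[from] || !passable[to]) return(Inf)
  dfs(from, 0)
  best
}

# Shortest-path cost through the package's grid-graph machinery (the engine
# under test), for a given cost surface.
engine_lcp <- function(surface, from, to) {
  gg <- corridorsim:::grid_graph(surface)
  w <- corridorsim:::edge_weights(gg, as.vector(surface$cost))
  as.numeric(igraph::distances(gg$graph, v = from, to = to, weights = w,
                               mode = "all"))
}

# Minimal hand-built cost surface on an n x n grid.
make_surface <- function(cost, barrier = NULL, crossing_cells = integer(0),
                         cell_size = 100) {
  n <- nrow(cost)
  g <- grid_spec(n, ncol(cost), cell_size)
  if (is.null(barrier)) barrier <- matrix(FALSE, n, ncol(cost))
  structure(list(grid = g, cost = cost, barrier = barrier,
                 crossing_cells = as.integer(crossing_cells)),
            class = "cost_surface")
}

# Small cached synthetic worlds so expensive generation runs once per suite.
test_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_landscape(valley_config(n_rows = 50, n_cols = 80,
                                                 rng_seed = 7))
    cache
  }
})

cell_at <- function(grid, row, col) as.integer((col - 1L) * grid$n_rows + row)

# One shared full scenario run (test profile, 10 sampler iterations) reused
# by the slower behavioural checks.
test_pipe <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_pipeline(run_config("test", rng_seed = 1, n_iter = 10))
    cache
  }
})
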