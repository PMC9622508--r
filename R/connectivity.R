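#' Permeability model (resource-selection-style coefficient table)
#'
#' A log-linear habitat model scoring each cell: the linear predictor is the
#' sum of cover-fraction terms plus elevation (km), slope (rise over run) and
#' distance-to-footprint (km) terms; \code{exp()} of the predictor is min-max
#' normalized to a 0-1 permeability index. Normalization bounds may be fixed
#' (via \code{\link{calibrate_bounds}}) so landscapes from different years of
#' one run share a scale and stay comparable.
#'
#' Published regional coefficients are not redistributable inputs, so a
#' documented synthetic default is shipped (see
#' \code{\link{default_permeability_model}}); user-supplied coefficient
#' tables plug in here.
#'
#' @param cover Named numeric vector of per-cover-class coefficients.
#' @param intercept Intercept.
#' @param elevation_km Coefficient on elevation in km.
#' @param slope Coefficient on slope (dimensionless rise/run).
#' @param dist_footprint_km Coefficient on distance to development footprint
#'   in km.
#' @param bounds Optional numeric length-2 normalization bounds on
#'   \code{exp(predictor)}.
#' @return An object of class \code{"permeability_model"}.
#' @export
permeability_model <- function(cover, intercept = 0, elevation_km = 0,
                               slope = 0, dist_footprint_km = 0,
                               bounds = NULL) {
  stopifnot(is.numeric(cover), !is.null(names(cover)))
  structure(list(cover = cover, intercept = intercept,
                 elevation_km = elevation_km, slope = slope,
                 dist_footprint_km = dist_footprint_km, bounds = bounds),
            class = "permeability_model")
}

#' Synthetic default permeability model
#'
#' Encodes the qualitative habitat preferences the analysis relies on:
#' selection for valley-bottom forest and shrub, avoidance of high elevation,
#' steep slopes and all development classes, and mild preference for distance
#' from footprint. Magnitudes are synthetic defaults, not fitted values.
#'
#' @return A \code{permeability_model}.
#' @export
default_permeability_model <- function() {
  # magnitudes are kept moderate (predictor range about 3 log units) so the
  # exponentiated, min-max-normalized surface preserves contrast between
  # valley bottom, midslope and development rather than saturating
  permeability_model(
    cover = c(forest = 0.6, shrub = 0.5, alpine = -0.5, water = -0.4,
              linear = -1.0, recreation_facility = -0.8, settlement = -1.5,
              industrial = -1.2, farmland = -0.3),
    intercept = 0, elevation_km = -0.8, slope = -0.8,
    dist_footprint_km = 0.1)
}

slope_from_elevation <- function(elevation, grid) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  gx <- elevation[, c(2:nc, nc)] - elevation[, c(1, 1:(nc - 1))]
  gy <- elevation[c(2:nr, nr), ] - elevation[c(1, 1:(nr - 1)), ]
  den <- 2 * grid$cell_size
  sqrt((gx / den)^2 + (gy / den)^2)
}

perm_linear_predictor <- function(state, model) {
  stack <- compose_landscape(state)
  g <- state$grid
  eta <- matrix(model$intercept, g$n_rows, g$n_cols)
  for (nm in names(model$cover)) {
    if (!nm %in% names(stack$layers))
      stop(sprintf("model covariate '%s' missing from landscape", nm),
           call. = FALSE)
    eta <- eta + model$cover[[nm]] * stack$layers[[nm]]
  }
  if (model$elevation_km != 0)
    eta <- eta + model$elevation_km * state$elevation / 1000
  if (model$slope != 0)
    eta <- eta + model$slope * slope_from_elevation(state$elevation, g)
  if (model$dist_footprint_km != 0) {
    fp <- footprint_fraction(state) > 1e-9
    d <- distance_to(fp, g)
    d[!is.finite(d)] <- 0
    eta <- eta + model$dist_footprint_km * d / 1000
  }
  eta
}

#' Fix permeability normalization bounds on a reference landscape
#'
#' @param state Reference \code{landscape_state} (typically the current
#'   year).
#' @param model A \code{permeability_model}.
#' @return The model with \code{bounds} set to the min/max of
#'   \code{exp(predictor)} on the reference landscape.
#' @export
calibrate_bounds <- function(state, model) {
  w <- exp(perm_linear_predictor(state, model))
  model$bounds <- range(w)
  model
}

#' Compute the 0-1 permeability index
#'
#' @param state A \code{landscape_state}.
#' @param model A \code{permeability_model}; if its bounds are unset they are
#'   taken from this landscape alone.
#' @return Matrix in [0,1]. A degenerate (constant) predictor yields 1
#'   everywhere.
#' @export
permeability <- function(state, model) {
  w <- exp(perm_linear_predictor(state, model))
  b <- if (is.null(model$bounds)) range(w) else model$bounds
  if (b[2] <= b[1]) return(matrix(1, state$grid$n_rows, state$grid$n_cols))
  pmax(0, pmin(1, (w - b[1]) / (b[2] - b[1])))
}

#' Build the traversal cost surface
#'
#' Cost is 1 minus permeability after two highway modifications: permeability
#' is multiplied by a factor rising linearly from 0 on the highway to 1 at
#' 500 m away (road avoidance), and highway cells themselves are barriers
#' impassable to paths except at wildlife crossings already built by the
#' state's year.
#'
#' @param state A \code{landscape_state} with a highway.
#' @param model A \code{permeability_model}.
#' @return An object of class \code{"cost_surface"} with \code{cost} in
#'   [0,1], logical \code{barrier}, and open \code{crossing_cells}.
#' @export
build_cost_surface <- function(state, model) {
  g <- state$grid
  if (length(state$highway_cells) == 0)
    stop("landscape has no highway layer", call. = FALSE)
  perm <- permeability(state, model)
  hw <- matrix(FALSE, g$n_rows, g$n_cols)
  hw[state$highway_cells] <- TRUE
  d <- distance_to(hw, g)
  perm <- perm * pmin(d / 500, 1)
  open <- state$crossings$cell[state$crossings$year_built <= state$year]
  structure(list(grid = g, cost = 1 - perm, barrier = hw,
                 crossing_cells = as.integer(open)),
            class = "cost_surface")
}

#' @export
print.cost_surface <- function(x, ...) {
  cat(sprintf(
    "<cost_surface> mean cost %.3f, %d barrier cells, %d open crossings\n",
    mean(x$cost), sum(x$barrier), length(x$crossing_cells)))
  invisible(x)
}

# Precompute the 8-connected grid graph over passable cells. Edge data:
# endpoints (cell indices) and geometric step length; per-iteration weights
# are supplied at query time.
grid_graph <- function(surface) {
  g <- surface$grid
  passable <- !surface$barrier
  passable[surface$crossing_cells] <- TRUE
  cells <- which(passable)
  e <- neighbours8(cells, g)
  e <- e[e[, "to"] %in% cells & e[, "from"] < e[, "to"], , drop = FALSE]
  nr <- g$n_rows
  dr <- abs(((e[, "from"] - 1L) %% nr) - ((e[, "to"] - 1L) %% nr))
  dc <- abs(((e[, "from"] - 1L) %/% nr) - ((e[, "to"] - 1L) %/% nr))
  len <- ifelse(dr + dc == 2L, sqrt(2), 1) * g$cell_size
  graph <- igraph::make_graph(rbind(e[, "from"], e[, "to"]),
                              n = g$n_rows * g$n_cols, directed = FALSE)
  list(graph = graph, from = e[, "from"], to = e[, "to"], len = len,
       passable_cells = cells)
}

edge_weights <- function(gg, cost_vec) {
  # accumulated-cost convention: step length times the mean endpoint cost,
  # floored so zero-cost corridors still have unique finite geodesics
  gg$len * 0.5 * (cost_vec[gg$from] + cost_vec[gg$to]) + 1e-9
}

#' Sample a stochastic least-cost-path ensemble
#'
#' Start and end cells are drawn without replacement from cells holding at
#' least two collar locations. Habitat selection is not truly optimal, so
#' each iteration redraws every cell's cost from a Normal distribution with
#' mean equal to its computed cost and standard deviation equal to the
#' study-area standard deviation of cost (truncated below at 1e-6 to keep
#' costs positive); all start-end least-cost paths are computed on that
#' iteration's surface and per-cell crossing counts accumulate over
#' iterations. With the default design of 100 starts, 100 ends and 10
#' iterations, 100,000 paths summarize a landscape.
#'
#' @param surface A \code{cost_surface}.
#' @param collar Data frame of collar locations with columns \code{x},
#'   \code{y} (metres) or \code{cell}.
#' @param n_start,n_end Numbers of start and end cells.
#' @param n_iter Number of perturbation iterations.
#' @param rng_seed Integer seed.
#' @param sd Cost perturbation s.d.; default the s.d. of cost over all
#'   cells. Set 0 to disable perturbation (deterministic paths).
#' @return An object of class \code{"path_ensemble"}: per-cell \code{count}
#'   and \code{proportion} matrices, \code{n_paths}, and the sampled
#'   \code{start_cells}/\code{end_cells}. Pairs disconnected on the perturbed
#'   surface are dropped from the denominator with a warning.
#' @export
sample_paths <- function(surface, collar, n_start = 100, n_end = 100,
                         n_iter = 10, rng_seed = 1, sd = NULL) {
  g <- surface$grid
  cells <- collar_cells(collar, g)
  eligible <- as.integer(names(which(table(cells) >= 2)))
  passable <- !surface$barrier
  passable[surface$crossing_cells] <- TRUE
  eligible <- eligible[passable[eligible]]
  if (length(eligible) < n_start + n_end)
    stop(sprintf(
      "need %d distinct cells with >= 2 collar locations, have %d",
      n_start + n_end, length(eligible)), call. = FALSE)
  set.seed(rng_seed %% .Machine$integer.max)
  pick <- sample(eligible, n_start + n_end)
  starts <- pick[seq_len(n_start)]
  ends <- pick[n_start + seq_len(n_end)]
  if (is.null(sd)) sd <- stats::sd(surface$cost)
  gg <- grid_graph(surface)
  n_cells <- g$n_rows * g$n_cols
  counts <- numeric(n_cells)
  n_fail <- 0L
  for (it in seq_len(n_iter)) {
    pert <- if (sd > 0)
      pmax(stats::rnorm(n_cells, mean = as.vector(surface$cost), sd = sd),
           1e-6)
    else as.vector(surface$cost)
    w <- edge_weights(gg, pert)
    for (s in starts) {
      sp <- suppressWarnings(
        igraph::shortest_paths(gg$graph, from = s, to = ends, weights = w,
                               mode = "all", output = "vpath"))
      vp <- sp$vpath
      empty <- lengths(vp) == 0
      n_fail <- n_fail + sum(empty)
      if (any(!empty))
        counts <- counts + tabulate(unlist(lapply(vp[!empty], as.integer)),
                                    nbins = n_cells)
    }
  }
  n_planned <- n_start * n_end * n_iter
  n_paths <- n_planned - n_fail
  if (n_fail > 0)
    warning(sprintf("%d of %d start-end pairs were disconnected and excluded",
                    n_fail, n_planned))
  structure(list(grid = g, n_paths = n_paths, n_planned = n_planned,
                 count = matrix(counts, g$n_rows, g$n_cols),
                 proportion = matrix(counts / max(n_paths, 1),
                                     g$n_rows, g$n_cols),
                 start_cells = starts, end_cells = ends),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf("<path_ensemble> %d paths, max cell proportion %.4f\n",
              x$n_paths, max(x$proportion)))
  invisible(x)
}

collar_cells <- function(collar, grid) {
  if ("cell" %in% names(collar)) return(as.integer(collar$cell))
  col <- pmin(pmax(floor((collar$x - grid$origin[1]) / grid$cell_size) + 1, 1),
              grid$n_cols)
  row <- pmin(pmax(floor((collar$y - grid$origin[2]) / grid$cell_size) + 1, 1),
              grid$n_rows)
  as.integer((col - 1) * grid$n_rows + row)
}

#' Bin path proportions into the 0-5 connectivity index
#'
#' The distribution of path proportions is highly skewed, so bins widen
#' geometrically: with ratio \code{r} the upper edges are
#' \code{t_k = p_max / r^(5-k)} for k = 1..5, anchored at the maximum
#' observed proportion. Level 0 is reserved for cells no path crosses;
#' level k covers \code{(t_(k-1), t_k]} with t_0 = 0.
#'
#' @param ensemble A \code{path_ensemble}.
#' @param r Geometric ratio between bin edges (default 4).
#' @return An object of class \code{"connectivity_index"} with integer
#'   \code{level} matrix and the bin \code{edges}.
#' @export
bin_connectivity <- function(ensemble, r = 4) {
  p <- ensemble$proportion
  p_max <- max(p)
  g <- ensemble$grid
  if (p_max == 0) {
    warning("all-zero path ensemble: connectivity index is 0 everywhere")
    return(structure(list(grid = g,
                          level = matrix(0L, g$n_rows, g$n_cols),
                          edges = rep(0, 5)),
                     class = "connectivity_index"))
  }
  edges <- p_max / r^(5:1 - 1)      # t_1 .. t_5 (t_5 = p_max)
  lev <- matrix(0L, g$n_rows, g$n_cols)
  lev[p > 0] <- 1L
  for (k in 2:5) lev[p > edges[k - 1]] <- as.integer(k)
  structure(list(grid = g, level = lev, edges = edges),
            class = "connectivity_index")
}
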