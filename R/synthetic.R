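#' Configuration for the synthetic valley generator
#'
#' Describes a mountain-valley study area in the spirit of the Bow Valley:
#' a low-elevation valley flanked by steep slopes, a fenced highway along the
#' valley axis with sparse wildlife crossings, two towns (one free to grow,
#' one fixed inside a national park) plus hamlets, trails radiating from
#' settlement, and recreation activity concentrated near settlement. The
#' default 200 x 450 grid at 100 m covers 900 km^2.
#'
#' @param n_rows,n_cols,cell_size Grid dimensions and cell size (m).
#' @param valley_floor Valley-bottom elevation (m).
#' @param relief Elevation gain from valley floor to grid edge (m).
#' @param noise_amp Amplitude of the smooth random elevation field (m).
#' @param current_year Calendar year of the generated (current) landscape.
#' @param crossing_fracs Positions of wildlife crossings along the highway as
#'   fractions of the east-west extent.
#' @param crossing_years Construction year of each crossing (future years
#'   denote planned structures).
#' @param informal_frac Fraction of generated trails flagged informal.
#' @param n_collar_cells Number of distinct cells receiving collar points;
#'   default scales with grid size (300 on the default grid).
#' @param scale An \code{\link{activity_scale}}.
#' @param rng_seed Integer seed; a fixed seed makes generation byte-identical.
#' @return An object of class \code{"valley_config"}.
#' @export
valley_config <- function(n_rows = 200, n_cols = 450, cell_size = 100,
                          valley_floor = 1300, relief = 1400,
                          noise_amp = 30, current_year = 2020,
                          crossing_fracs = c(0.10, 0.35, 0.50, 0.65, 0.90),
                          crossing_years = c(1965, 1988, 1997, 2014, 2027),
                          informal_frac = 0.4,
                          n_collar_cells = max(60, round(n_rows * n_cols / 300)),
                          scale = activity_scale(),
                          rng_seed = 7) {
  stopifnot(length(crossing_fracs) == length(crossing_years),
            length(crossing_fracs) >= 1)
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 valley_floor = valley_floor, relief = relief,
                 noise_amp = noise_amp, current_year = current_year,
                 crossing_fracs = crossing_fracs,
                 crossing_years = crossing_years,
                 informal_frac = informal_frac,
                 n_collar_cells = n_collar_cells,
                 scale = scale, rng_seed = rng_seed),
            class = "valley_config")
}

cell_of <- function(row, col, nr) as.integer((col - 1L) * nr + row)

# n nearest available cells to a seed: compact, deterministic patch shape.
# row_stretch > 1 elongates the patch across the valley (north-south), the
# way townsites fill the valley floor from the highway outward.
blob <- function(seed_cell, n, avail, grid, row_stretch = 1) {
  sxy <- cell_centres(grid, seed_cell)
  cand <- which(avail)
  xy <- cell_centres(grid, cand)
  d <- (xy[, 1] - sxy[1])^2 + ((xy[, 2] - sxy[2]) / row_stretch)^2
  cand[order(d, cand)][seq_len(min(n, length(cand)))]
}

walk_trail <- function(grid, start_row, start_col, len) {
  nr <- grid$n_rows; nc <- grid$n_cols
  dir <- c(sample(c(-1, 1), 1), sample(c(-1, 0, 1), 1))
  r <- start_row; c2 <- start_col
  cells <- integer(len)
  for (s in seq_len(len)) {
    r <- min(max(r + dir[1] * (stats::runif(1) < 0.8) + sample(-1:1, 1), 1), nr)
    c2 <- min(max(c2 + dir[2] + sample(-1:1, 1), 1), nc)
    cells[s] <- cell_of(r, c2, nr)
  }
  unique(cells)
}

#' Generate the synthetic valley landscape
#'
#' Builds the full fixture set the pipeline consumes: a dated-footprint
#' \code{landscape_state} (U-shaped valley elevation, elevation-banded
#' natural cover, footprint patches concentrated on the valley bottom with
#' patch-level origin years across five eras, a barrier highway with dated
#' crossings, staged town-growth zones and trails), a current-day
#' \code{activity_raster} whose absolute activity is more than 80 percent
#' within 2 km of settlement, and a collar table whose points prefer
#' high-permeability natural habitat.
#'
#' @param cfg A \code{valley_config}.
#' @return List with \code{landscape}, \code{activity}, \code{collar}
#'   (data frame x, y, cell, animal_id, timestamp) and \code{config}.
#' @export
generate_landscape <- function(cfg) {
  set.seed(cfg$rng_seed)
  g <- grid_spec(cfg$n_rows, cfg$n_cols, cfg$cell_size)
  nr <- g$n_rows; nc <- g$n_cols; N <- nr * nc
  centre <- (nr + 1) / 2

  # --- elevation: parabolic cross-valley profile + smooth noise -------------
  rowm <- matrix(seq_len(nr), nr, nc)
  elev <- cfg$valley_floor +
    cfg$relief * ((rowm - centre) / (nr / 2))^2
  noise <- focal_mean(matrix(stats::rnorm(N), nr, nc),
                      5 * g$cell_size, g) * cfg$noise_amp * 3
  elev <- elev + noise
  h <- pmax(elev - cfg$valley_floor, 0)

  # --- natural cover by elevation band --------------------------------------
  w_forest <- exp(-h / 600)
  w_shrub <- 0.5 * exp(-h / 250)
  w_alpine <- 1 / (1 + exp(-(h - 600) / 100))
  river_row <- centre - 2
  w_water <- 0.9 * exp(-((rowm - river_row) / 1.2)^2)
  tot <- w_forest + w_shrub + w_alpine + w_water
  natural <- list(forest = w_forest / tot, shrub = w_shrub / tot,
                  alpine = w_alpine / tot, water = w_water / tot)

  # --- footprint events ------------------------------------------------------
  events <- list()
  avail <- matrix(TRUE, nr, nc)
  add_event <- function(class, year, cells) {
    avail[cells] <<- FALSE
    events[[length(events) + 1]] <<- list(class = class, origin_year = year,
                                          cells = as.integer(cells), frac = 1)
  }
  hw_row <- as.integer(round(centre) + max(2L, nr %/% 40))
  rail_row <- as.integer(round(centre) - max(4L, nr %/% 30))
  highway_cells <- cell_of(rep(hw_row, nc), seq_len(nc), nr)
  add_event("linear", 1955, highway_cells)
  add_event("linear", 1900, cell_of(rep(rail_row, nc), seq_len(nc), nr))

  bcol <- round(0.27 * nc); ccol <- round(0.73 * nc)
  # towns straddle the highway and stretch across the valley floor on both
  # sides, past the highway's 500 m avoidance band: like real valley
  # townsites they block the bottomland, so movement must detour upslope
  town_off <- 7L
  b_row <- hw_row - 1L
  c_row <- hw_row + 1L
  b_seed <- cell_of(max(1L, b_row), bcol, nr)
  c_seed <- cell_of(min(nr, c_row), ccol, nr)

  # settlement patches with era rings (inner = oldest); the row stretch is
  # chosen so the patch half-depth clears the avoidance band regardless of
  # grid size
  era_years <- c(1955, 1980, 1995, 2005, 2015)
  era_frac <- c(0.45, 0.20, 0.15, 0.12, 0.08)
  half_depth <- 5 + max(3, nr %/% 16)
  add_town <- function(seed, n_total) {
    stretch <- max(1.5, pi * half_depth^2 / n_total)
    cells <- blob(seed, n_total, avail, g, row_stretch = stretch)
    sizes <- diff(c(0, round(cumsum(era_frac) * n_total)))
    start <- 1
    for (i in seq_along(era_years)) {
      if (sizes[i] == 0) next
      add_event("settlement", era_years[i],
                cells[start:(start + sizes[i] - 1)])
      start <- start + sizes[i]
    }
    cells
  }
  b_cells <- add_town(b_seed, round(0.0035 * N))
  c_cells <- add_town(c_seed, round(0.006 * N))
  # hamlets (rural settlement)
  ham_seeds <- cell_of(pmin(nr, pmax(1L, hw_row + c(-town_off, town_off,
                                                    -town_off))),
                       round(c(0.15, 0.50, 0.88) * nc), nr)
  ham_cells <- integer(0)
  for (s in ham_seeds) {
    cells <- blob(s, round(0.00067 * N), avail, g)
    add_event("settlement", sample(c(1955, 1980, 1995), 1), cells)
    ham_cells <- c(ham_cells, cells)
  }

  # recreation facilities: golf near the park town, nordic centre beside the
  # growing town, ski area upslope
  golf <- blob(cell_of(max(1L, b_row - 6L), bcol + 6, nr),
               round(0.004 * N), avail, g)
  add_event("recreation_facility", 1960, golf)
  nordic <- blob(cell_of(min(nr, c_row + 4L), ccol - 8, nr),
                 round(0.005 * N), avail, g)
  add_event("recreation_facility", 1985, nordic)
  ski <- blob(cell_of(round(nr * 0.15), bcol - 10, nr),
              round(0.005 * N), avail, g)
  add_event("recreation_facility", 1970, ski)

  add_event("industrial", 1980,
            blob(cell_of(max(1L, b_row), round(0.93 * nc), nr),
                 round(0.005 * N), avail, g))
  add_event("industrial", 2005,
            blob(cell_of(min(nr, c_row), round(0.60 * nc), nr),
                 round(0.003 * N), avail, g))
  add_event("farmland", 1940,
            blob(cell_of(min(nr, c_row + 4L), round(0.97 * nc), nr),
                 round(0.0005 * N), avail, g))

  # --- crossings, zones ------------------------------------------------------
  crossings <- data.frame(
    cell = cell_of(rep(hw_row, length(cfg$crossing_fracs)),
                   pmax(1, round(cfg$crossing_fracs * nc)), nr),
    year_built = cfg$crossing_years)

  dist_to_cell <- function(seed) {
    sxy <- cell_centres(g, seed)
    xy <- cell_centres(g)
    matrix(sqrt((xy[, 1] - sxy[1])^2 + (xy[, 2] - sxy[2])^2), nr, nc)
  }
  db <- dist_to_cell(b_seed); dc <- dist_to_cell(c_seed)
  colm <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  r_town <- 12 * g$cell_size * max(1, round(nc / 150))
  banff_zone <- which(db <= r_town)
  canmore_zone <- setdiff(which(dc <= 2.5 * r_town), banff_zone)
  # thin ring of buildable cells around the town: roughly 15 percent of the
  # 30-year expansion, so the staged area-to-be-determined east of town
  # absorbs the bulk of growth
  n_gb <- max(2, round(0.18 * 0.87 * length(c_cells)))
  growth_boundary <- blob(c_seed, n_gb, avail, g)
  atbd <- setdiff(intersect(canmore_zone,
                            which(avail & colm > ccol + 2 & rowm != hw_row)),
                  growth_boundary)
  zones <- list(
    banff = banff_zone, canmore = canmore_zone,
    nordic_centre = as.integer(nordic),
    growth_boundary = as.integer(growth_boundary),
    area_to_be_determined = as.integer(atbd),
    town_center = c_seed,
    rural = setdiff(seq_len(N), c(banff_zone, canmore_zone)))

  # --- trails ----------------------------------------------------------------
  sett_all <- list(b_cells, c_cells, ham_cells, nordic)
  trails <- list(); tid <- 1L
  for (patch in sett_all) {
    n_tr <- max(3, length(patch) %/% 10)
    for (k in seq_len(n_tr)) {
      s <- patch[sample(length(patch), 1)]
      cells <- walk_trail(g, (s - 1L) %% nr + 1L, (s - 1L) %/% nr + 1L,
                          len = min(22, 5 + stats::rpois(1, 10)))
      trails[[length(trails) + 1]] <-
        data.frame(trail_id = tid, cell = cells,
                   designated = stats::runif(1) >= cfg$informal_frac)
      tid <- tid + 1L
    }
  }
  trails <- do.call(rbind, trails)

  state <- landscape_state(g, natural, events, cfg$current_year, crossings,
                           highway_cells, zones, elev, trails)

  # --- recreation activity ---------------------------------------------------
  d_sett <- distance_to(settlement_mask(state), g)
  absact <- matrix(0, nr, nc)
  tr_cells <- unique(trails$cell)
  amp <- cfg$scale$A0 * cfg$scale$g^4.2
  absact[tr_cells] <- amp * exp(-d_sett[tr_cells] / 800)
  recfac <- class_cells(state, "recreation_facility", 1e-9)
  absact[recfac] <- amp * 0.5 * exp(-d_sett[recfac] / 1500)
  sett_cells <- class_cells(state, "settlement", 1e-9)
  absact[sett_cells] <- amp
  # off-trail halo: recorded activity spreads beyond the mapped line work
  # (heatmap-style areal footprint around trails and facilities)
  absact <- absact + focal_mean(absact, 3 * g$cell_size, g)
  frac2km <- sum(absact[d_sett <= 2000]) / sum(absact)
  if (frac2km <= 0.80)
    stop(sprintf(paste0(
      "generation error: only %.1f%% of recreation activity fell within ",
      "2 km of settlement (need > 80%%); widen towns or shorten trails"),
      100 * frac2km), call. = FALSE)
  activity <- activity_raster(g, absact, cfg$scale, trails)

  # --- collar locations: prefer permeable natural habitat --------------------
  perm <- permeability(state, default_permeability_model())
  fp <- footprint_fraction(state)
  nat_cells <- which(fp < 0.05 & !(seq_len(N) %in% highway_cells))
  pr <- perm[nat_cells]^2
  chosen <- sample(nat_cells, cfg$n_collar_cells, prob = pr)
  pts_per <- 2L + (stats::runif(length(chosen)) < 0.3)
  cells_rep <- rep(chosen, pts_per)
  xy <- cell_centres(g, cells_rep)
  collar <- data.frame(
    x = xy[, 1] + stats::runif(length(cells_rep), -0.5, 0.5) * g$cell_size,
    y = xy[, 2] + stats::runif(length(cells_rep), -0.5, 0.5) * g$cell_size,
    cell = cells_rep,
    animal_id = sample(15, length(cells_rep), replace = TRUE),
    timestamp = as.POSIXct("2019-06-01", tz = "UTC") +
      seq_along(cells_rep) * 3600)

  list(landscape = state, activity = activity, collar = collar, config = cfg)
}

#' Deterministic toy landscape for oracle tests
#'
#' An n x n fixture (n <= 20) with uniform natural cover, one highway row
#' with exactly one open crossing, and one settlement patch dated 1995, so
#' barrier handling and backcasting can be checked by hand.
#'
#' @param n Grid side (cells), at most 20.
#' @return A \code{landscape_state}.
#' @export
toy_landscape <- function(n = 5) {
  stopifnot(n >= 3, n <= 20)
  g <- grid_spec(n, n)
  natural <- list(forest = matrix(0.7, n, n), shrub = matrix(0.3, n, n),
                  alpine = matrix(0, n, n), water = matrix(0, n, n))
  hw_row <- as.integer(ceiling(n / 2))
  cross_col <- as.integer(ceiling(n / 2))
  highway_cells <- cell_of(rep(hw_row, n), seq_len(n), n)
  sett <- c(cell_of(1, 1, n), cell_of(2, 1, n), cell_of(1, 2, n),
            cell_of(2, 2, n))
  events <- list(
    list(class = "linear", origin_year = 1955, cells = highway_cells,
         frac = 1),
    list(class = "settlement", origin_year = 1995, cells = sett, frac = 1))
  crossings <- data.frame(cell = cell_of(hw_row, cross_col, n),
                          year_built = 1950)
  zones <- list(banff = integer(0), canmore = sett,
                nordic_centre = integer(0),
                growth_boundary = setdiff(which(matrix(TRUE, n, n)),
                                          c(highway_cells, sett)),
                area_to_be_determined = integer(0),
                town_center = sett[1],
                rural = integer(0))
  elev <- matrix(1400, n, n) + outer(seq_len(n), rep(0, n))  # gentle tilt
  trails <- data.frame(trail_id = 1L, cell = cell_of(seq_len(n), pmin(3, n), n),
                       designated = TRUE)
  landscape_state(g, natural, events, 2020, crossings, highway_cells,
                  zones, elev, trails)
}
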