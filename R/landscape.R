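#' Construct a landscape state
#'
#' A \code{landscape_state} is the simulated world at one time step. It stores
#' the pristine natural composition (fractions summing to 1 per cell) and the
#' list of dated anthropogenic footprint events; the composed cover stack is a
#' pure function of these via \code{\link{compose_landscape}}. Because events
#' carry their own cells and fractions, removing and re-applying an event is
#' exact: backcasting is lossless by construction.
#'
#' @param grid A \code{grid_spec}.
#' @param natural Named list of natural cover-fraction matrices summing to 1
#'   per cell.
#' @param events List of footprint events, each a list with \code{class}
#'   (anthropogenic class name), \code{origin_year}, \code{cells} (integer
#'   cell indices) and \code{frac} (fraction converted, scalar or per cell).
#' @param year Calendar year this state represents.
#' @param crossings Data frame with columns \code{cell}, \code{year_built}
#'   (wildlife crossing structures on the highway).
#' @param highway_cells Integer cell indices of the (fenced) highway.
#' @param zones Named list of integer cell-index vectors
#'   (\code{banff}, \code{canmore}, \code{rural}, \code{growth_boundary},
#'   \code{area_to_be_determined}, \code{town_center}, \code{nordic_centre}).
#' @param elevation Elevation matrix (m).
#' @param trails Data frame with columns \code{trail_id}, \code{cell},
#'   \code{designated}.
#' @return An object of class \code{"landscape_state"}.
#' @export
landscape_state <- function(grid, natural, events, year, crossings,
                            highway_cells, zones, elevation,
                            trails = NULL) {
  tot <- Reduce(`+`, natural)
  if (max(abs(tot - 1)) > 1e-9)
    stop("natural cover fractions must sum to 1 per cell", call. = FALSE)
  ord <- order(vapply(events, `[[`, numeric(1), "origin_year"))
  structure(list(grid = grid, natural = natural, events = events[ord],
                 year = year, crossings = crossings,
                 highway_cells = as.integer(highway_cells),
                 zones = zones, elevation = elevation, trails = trails),
            class = "landscape_state")
}

#' @export
print.landscape_state <- function(x, ...) {
  cat(sprintf("<landscape_state> year %s, %d footprint events, %d x %d grid\n",
              x$year, length(x$events), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

anthro_classes <- c("linear", "recreation_facility", "settlement",
                    "industrial", "farmland")

#' Compose a landscape state into a cover stack
#'
#' Accumulates the anthropogenic fraction of each cell from the state's
#' footprint events and rescales the natural fractions to fill the remainder,
#' so every cell sums to 1 exactly.
#'
#' @param state A \code{landscape_state}.
#' @return A \code{cover_stack}.
#' @export
compose_landscape <- function(state) {
  g <- state$grid
  zero <- matrix(0, g$n_rows, g$n_cols)
  anth <- stats::setNames(lapply(anthro_classes, function(i) zero),
                          anthro_classes)
  for (ev in state$events) {
    anth[[ev$class]][ev$cells] <- anth[[ev$class]][ev$cells] + ev$frac
  }
  tot <- Reduce(`+`, anth)
  if (max(tot) > 1 + 1e-9)
    stop("overlapping footprint events exceed full cell coverage", call. = FALSE)
  tot <- pmin(tot, 1)
  nat <- lapply(state$natural, function(m) m * (1 - tot))
  cover_stack(g, c(nat, anth), anthropogenic = anthro_classes)
}

#' Total anthropogenic fraction per cell
#' @param state A \code{landscape_state}.
#' @return Numeric matrix in [0,1].
#' @export
footprint_fraction <- function(state) {
  g <- state$grid
  tot <- matrix(0, g$n_rows, g$n_cols)
  for (ev in state$events) tot[ev$cells] <- tot[ev$cells] + ev$frac
  pmin(tot, 1)
}

class_cells <- function(state, class, frac_min = 0.5) {
  g <- state$grid
  tot <- matrix(0, g$n_rows, g$n_cols)
  for (ev in state$events)
    if (ev$class == class) tot[ev$cells] <- tot[ev$cells] + ev$frac
  which(tot >= frac_min)
}

#' Backcast a landscape to an earlier year
#'
#' Reconstructs the historical landscape by removing every footprint event
#' whose origin postdates \code{target_year}; the affected cells' natural
#' fractions are restored by renormalization. Wildlife crossings built after
#' \code{target_year} are removed likewise.
#'
#' @param state A \code{landscape_state}.
#' @param target_year Year at or before \code{state$year}.
#' @return A \code{landscape_state} at \code{target_year}.
#' @export
backcast <- function(state, target_year) {
  if (target_year > state$year)
    stop("target_year is in the future; use forecast()", call. = FALSE)
  keep <- vapply(state$events, function(e) e$origin_year <= target_year,
                 logical(1))
  landscape_state(state$grid, state$natural, state$events[keep], target_year,
                  state$crossings[state$crossings$year_built <= target_year, ,
                                  drop = FALSE],
                  state$highway_cells, state$zones, state$elevation,
                  state$trails)
}

#' Re-apply footprint events to a (backcast) landscape
#'
#' The exact inverse of \code{\link{backcast}}: appending the removed events
#' (and restoring the crossing inventory) reproduces the original composed
#' stack bit for bit.
#'
#' @param state A \code{landscape_state}.
#' @param events Events to add back.
#' @param crossings Full crossing inventory to restore (default: keep).
#' @param year New state year (default: latest event year).
#' @return A \code{landscape_state}.
#' @export
reapply_events <- function(state, events, crossings = state$crossings,
                           year = NULL) {
  all_ev <- c(state$events, events)
  if (is.null(year))
    year <- max(state$year,
                vapply(all_ev, `[[`, numeric(1), "origin_year"))
  landscape_state(state$grid, state$natural, all_ev, year, crossings,
                  state$highway_cells, state$zones, state$elevation,
                  state$trails)
}

#' Settlement growth specification
#'
#' Thirty-year settlement growth fractions: rural footprint follows the
#' municipal-district population projection (+61 percent over 30 years), the
#' larger town grows by 87 percent (its 97 percent population projection less
#' roughly 10 percent accommodated by infill), and the national-park townsite
#' is fixed because expansion is not permitted. Growth is allocated per
#' decade with multiplier \code{(1+g)^(1/3)}.
#'
#' @param rural_growth_frac_30yr,canmore_growth_frac_30yr,banff_growth_frac
#'   30-year area growth fractions.
#' @param staging Zone order exhausted in sequence for town expansion.
#' @param neighbor_exponent Power on adjacent-patch size in rural allocation
#'   weights.
#' @return An object of class \code{"growth_spec"}.
#' @export
growth_spec <- function(rural_growth_frac_30yr = 0.61,
                        canmore_growth_frac_30yr = 0.87,
                        banff_growth_frac = 0,
                        staging = c("growth_boundary", "area_to_be_determined"),
                        neighbor_exponent = 1) {
  stopifnot(rural_growth_frac_30yr >= 0, canmore_growth_frac_30yr >= 0,
            banff_growth_frac >= 0)
  structure(list(rural_growth_frac_30yr = rural_growth_frac_30yr,
                 canmore_growth_frac_30yr = canmore_growth_frac_30yr,
                 banff_growth_frac = banff_growth_frac,
                 staging = staging,
                 neighbor_exponent = neighbor_exponent),
            class = "growth_spec")
}

neighbours8 <- function(cells, grid) {
  nr <- grid$n_rows
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  off <- expand.grid(di = -1:1, dj = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0), ]
  out <- lapply(seq_len(nrow(off)), function(k) {
    r <- row + off$di[k]; c2 <- col + off$dj[k]
    ok <- r >= 1 & r <= nr & c2 >= 1 & c2 <= grid$n_cols
    cbind(from = cells[ok], to = (c2[ok] - 1L) * nr + r[ok])
  })
  do.call(rbind, out)
}

# Connected components (8-neighbourhood) of a set of cells; returns a vector
# of patch labels parallel to `cells`.
label_patches <- function(cells, grid) {
  if (length(cells) == 0) return(integer(0))
  idx <- stats::setNames(seq_along(cells), cells)
  e <- neighbours8(cells, grid)
  e <- e[e[, "to"] %in% cells, , drop = FALSE]
  g <- igraph::make_graph(rbind(idx[as.character(e[, "from"])],
                                idx[as.character(e[, "to"])]),
                          n = length(cells), directed = FALSE)
  igraph::components(g)$membership
}

#' Allocation weights for new rural development
#'
#' New development is more likely next to larger patches of existing
#' footprint: an undeveloped cell 8-adjacent to settlement gets weight
#' proportional to the adjacent patch's cell count raised to
#' \code{neighbor_exponent} (largest adjacent patch if several), normalized
#' over all candidates in the zone. Cells with no settlement neighbour have
#' weight 0 until adjacency emerges.
#'
#' @param state A \code{landscape_state}.
#' @param zone Integer cell indices delimiting where growth may occur.
#' @param exponent Patch-size exponent (default 1).
#' @return Matrix of probabilities summing to 1 (or all zero if no candidate).
#' @export
candidate_weights <- function(state, zone, exponent = 1) {
  g <- state$grid
  if (length(zone) == 0) stop("zone is empty", call. = FALSE)
  w <- matrix(0, g$n_rows, g$n_cols)
  dev <- footprint_fraction(state)
  sett <- class_cells(state, "settlement")
  if (length(sett) == 0) return(w)
  memb <- label_patches(sett, g)
  psize <- tabulate(memb)
  nb <- neighbours8(sett, g)
  # candidate = undeveloped zone cell adjacent to a settlement cell
  cand <- nb[nb[, "to"] %in% zone & dev[nb[, "to"]] < 0.5, , drop = FALSE]
  if (nrow(cand) == 0) return(w)
  patch_of <- stats::setNames(memb, sett)
  sz <- psize[patch_of[as.character(cand[, "from"])]]
  best <- tapply(sz, cand[, "to"], max)
  cells <- as.integer(names(best))
  w[cells] <- as.numeric(best)^exponent
  w / sum(w)
}

grow_decadal_target <- function(area_cells, frac_30yr) {
  # per-decade multiplier from a 30-year growth fraction
  area_cells * ((1 + frac_30yr)^(1 / 3) - 1)
}

allocate_town <- function(state, n_new, spec) {
  # outward from the town centre, exhausting staged zones in order
  g <- state$grid
  dev <- footprint_fraction(state)
  centre <- state$zones$town_center[1]
  cxy <- cell_centres(g, centre)
  chosen <- integer(0)
  for (zn in spec$staging) {
    if (n_new <= 0) break
    zone <- state$zones[[zn]]
    avail <- zone[dev[zone] < 0.5]
    avail <- setdiff(avail, c(chosen, state$highway_cells))
    if (length(avail) == 0) next
    xy <- cell_centres(g, avail)
    d <- sqrt((xy[, 1] - cxy[1])^2 + (xy[, 2] - cxy[2])^2)
    take <- avail[order(d, avail)][seq_len(min(n_new, length(avail)))]
    chosen <- c(chosen, take)
    n_new <- n_new - length(take)
  }
  if (n_new > 0)
    stop(sprintf(
      "allocation error: zones %s exhausted with %d cells still to place",
      paste(spec$staging, collapse = "+"), n_new), call. = FALSE)
  chosen
}

allocate_rural <- function(state, n_new, spec) {
  chosen <- integer(0)
  st <- state
  while (n_new > 0) {
    w <- candidate_weights(st, st$zones$rural, spec$neighbor_exponent)
    cand <- which(w > 0)
    if (length(cand) == 0)
      stop("allocation error: no allocatable cells in zone 'rural'",
           call. = FALSE)
    k <- min(n_new, length(cand))
    take <- if (k == length(cand)) cand else
      sample(cand, k, prob = w[cand])
    chosen <- c(chosen, take)
    n_new <- n_new - k
    if (n_new > 0)  # adjacency must emerge before more cells can convert
      st <- reapply_events(st, list(list(class = "settlement",
                                         origin_year = st$year,
                                         cells = take, frac = 1)),
                           year = st$year)
  }
  chosen
}

#' Forecast settlement expansion
#'
#' Simulates decadal settlement growth from the current landscape. The town
#' zone grows outward from the town centre, converting growth-boundary cells
#' before area-to-be-determined cells; rural settlement grows by weighted
#' sampling biased toward larger existing patches; the park townsite stays
#' fixed. Newly converted cells become 100 percent settlement and are recorded
#' as dated footprint events, so forecast states backcast exactly.
#'
#' @param state Current \code{landscape_state}.
#' @param spec A \code{growth_spec}.
#' @param horizon_years Forecast length in years (multiple of 10, >= 10).
#' @param rng_seed Integer seed for the rural allocation sampling.
#' @return List of \code{landscape_state}, one per decade.
#' @export
forecast <- function(state, spec, horizon_years = 30, rng_seed = 1) {
  stopifnot(horizon_years >= 10)
  decades <- seq(state$year + 10, state$year + horizon_years, by = 10)
  out <- vector("list", length(decades))
  st <- state
  set.seed(rng_seed %% .Machine$integer.max)
  for (i in seq_along(decades)) {
    yr <- decades[i]
    ev <- list()
    # town (Canmore-like): staged outward growth
    town_cells <- intersect(class_cells(st, "settlement"), st$zones$canmore)
    n_town <- round(grow_decadal_target(length(town_cells),
                                        spec$canmore_growth_frac_30yr))
    if (n_town > 0) {
      cells <- allocate_town(st, n_town, spec)
      ev <- c(ev, list(list(class = "settlement", origin_year = yr,
                            cells = cells, frac = 1)))
    }
    # rural hamlets: patch-size-biased accretion
    rural_cells <- intersect(class_cells(st, "settlement"), st$zones$rural)
    n_rur <- round(grow_decadal_target(length(rural_cells),
                                       spec$rural_growth_frac_30yr))
    if (n_rur > 0) {
      cells <- allocate_rural(st, n_rur, spec)
      ev <- c(ev, list(list(class = "settlement", origin_year = yr,
                            cells = cells, frac = 1)))
    }
    # park townsite (Banff-like): banff_growth_frac is 0 by policy; any
    # configured growth would use the same staged mechanism, unsupported here
    if (spec$banff_growth_frac != 0)
      stop("non-zero banff growth is not supported: expansion is not allowed",
           call. = FALSE)
    st <- reapply_events(st, ev, year = yr)
    out[[i]] <- st
  }
  out
}
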