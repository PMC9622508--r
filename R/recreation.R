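#' Exponential activity scale
#'
#' Maps heatmap-style activity levels 0-5 to absolute activity. Level 0 is no
#' activity; levels 1..5 carry \code{A0 * g^(k-1)} units, so use rises
#' exponentially across levels and categorical change lags absolute change.
#'
#' @param A0 Absolute activity at level 1 (arbitrary units, default 1).
#' @param g Growth factor between successive levels (> 1, default 3).
#' @return An object of class \code{"activity_scale"}.
#' @export
activity_scale <- function(A0 = 1, g = 3) {
  stopifnot(A0 > 0, g > 1)
  structure(list(A0 = A0, g = g), class = "activity_scale")
}

#' Convert activity levels to absolute activity
#'
#' @param level Integer matrix (or vector) with values in 0..5.
#' @param scale An \code{activity_scale}.
#' @return Absolute activity, same shape as \code{level}.
#' @export
level_to_absolute <- function(level, scale = activity_scale()) {
  if (any(is.na(level)) || any(level < 0 | level > 5 | level != round(level)))
    stop("activity levels must be integers in 0..5", call. = FALSE)
  out <- ifelse(level == 0, 0, scale$A0 * scale$g^(level - 1))
  if (is.matrix(level)) out <- matrix(out, nrow(level), ncol(level))
  out
}

#' Convert absolute activity to levels
#'
#' Zero maps to level 0; positive activity maps to
#' \code{min(5, max(1, 1 + floor(log_g(a / A0))))}, the inverse of
#' \code{\link{level_to_absolute}} on representable levels.
#'
#' @param absolute Non-negative matrix (or vector).
#' @param scale An \code{activity_scale}.
#' @return Integer levels in 0..5, same shape.
#' @export
absolute_to_level <- function(absolute, scale = activity_scale()) {
  if (any(is.na(absolute)) || any(absolute < 0))
    stop("absolute activity must be non-negative", call. = FALSE)
  k <- 1 + floor(log(pmax(absolute, scale$A0 * 1e-12) / scale$A0) /
                   log(scale$g) + 1e-9)
  out <- ifelse(absolute == 0, 0L, pmin(5, pmax(1, k)))
  if (is.matrix(absolute)) out <- matrix(as.integer(out),
                                         nrow(absolute), ncol(absolute))
  else out <- as.integer(out)
  out
}

#' Construct an activity raster
#'
#' Paired absolute recreation activity and its 0-5 level classification; the
#' level band is always recomputed from the absolute band through the scale,
#' which enforces the level-0 if and only if zero-activity invariant.
#'
#' @param grid A \code{grid_spec}.
#' @param absolute Non-negative activity matrix.
#' @param scale An \code{activity_scale}.
#' @param trails Data frame (\code{trail_id}, \code{cell}, \code{designated}).
#' @return An object of class \code{"activity_raster"}.
#' @export
activity_raster <- function(grid, absolute, scale = activity_scale(),
                            trails = NULL) {
  check_raster(absolute, grid, "absolute activity")
  structure(list(grid = grid, absolute = absolute,
                 level = absolute_to_level(absolute, scale),
                 scale = scale, trails = trails),
            class = "activity_raster")
}

#' @export
print.activity_raster <- function(x, ...) {
  cat(sprintf("<activity_raster> mean level %.3f, total activity %.1f\n",
              mean(x$level), sum(x$absolute)))
  invisible(x)
}

settlement_mask <- function(state) {
  g <- state$grid
  m <- matrix(FALSE, g$n_rows, g$n_cols)
  m[class_cells(state, "settlement", frac_min = 1e-9)] <- TRUE
  m
}

#' Backcast recreation activity to a historical landscape
#'
#' Two rules reconstruct unavailable historical activity layers:
#' activity inside recreation facilities or within 2 km of settlement
#' footprint is assumed to be generated by that development, so it is zeroed
#' wherever the associated footprint postdates the backcast year; remaining
#' activity is scaled by one regional factor so total activity growth from
#' the backcast year to the present matches population growth.
#'
#' @param current Present-day \code{activity_raster}.
#' @param landscape_now Present-day \code{landscape_state} (dates the
#'   footprint).
#' @param landscape_t Backcast \code{landscape_state} at the target year.
#' @param pop_growth Fractional population growth from \code{landscape_t$year}
#'   to the present (e.g. 1.0 = doubled).
#' @return An \code{activity_raster} for the historical year.
#' @export
backcast_activity <- function(current, landscape_now, landscape_t,
                              pop_growth) {
  g <- current$grid
  d_now <- distance_to(settlement_mask(landscape_now), g)
  d_t <- distance_to(settlement_mask(landscape_t), g)
  recfac_now <- matrix(FALSE, g$n_rows, g$n_cols)
  recfac_now[class_cells(landscape_now, "recreation_facility", 1e-9)] <- TRUE
  recfac_t <- matrix(FALSE, g$n_rows, g$n_cols)
  recfac_t[class_cells(landscape_t, "recreation_facility", 1e-9)] <- TRUE
  # zero where tied to development that postdates the target year: inside a
  # facility not yet built, or within 2 km of settlement only in the present
  zero <- (recfac_now & !recfac_t) |
    (d_now <= 2000 & d_t > 2000)
  abs_t <- current$absolute
  abs_t[zero] <- 0
  total_target <- sum(current$absolute) / (1 + pop_growth)
  rem <- sum(abs_t)
  if (rem > 0) abs_t <- abs_t * (total_target / rem)
  activity_raster(g, abs_t, current$scale, current$trails)
}

new_trails_near <- function(grid, new_cells, n_trails, mean_len,
                            start_id = 1L) {
  # short random walks seeded on new settlement edge cells; every generated
  # trail cell stays within 2 km of a new settlement cell by construction
  # (walk length <= 2 km / cell size)
  nr <- grid$n_rows
  rows <- (new_cells - 1L) %% nr + 1L
  cols <- (new_cells - 1L) %/% nr + 1L
  max_steps <- floor(2000 / grid$cell_size)
  out <- list()
  for (t in seq_len(n_trails)) {
    i <- sample(length(new_cells), 1)
    r <- rows[i]; c2 <- cols[i]
    len <- min(max_steps, max(3, stats::rpois(1, mean_len)))
    dir <- sample(c(-1, 0, 1), 2, replace = TRUE)
    if (all(dir == 0)) dir <- c(1, 0)
    cells <- integer(len)
    for (s in seq_len(len)) {
      r <- min(max(r + dir[1] + sample(-1:1, 1), 1), nr)
      c2 <- min(max(c2 + dir[2] + sample(-1:1, 1), 1), grid$n_cols)
      cells[s] <- (c2 - 1L) * nr + r
    }
    out[[t]] <- data.frame(trail_id = start_id + t - 1L,
                           cell = unique(cells), designated = FALSE)
  }
  do.call(rbind, out)
}

#' Forecast recreation activity for one decade
#'
#' In growing municipalities, total new activity equals the growth fraction
#' times the current municipal total: half intensifies existing trails
#' (added proportionally to current use) and half is placed on newly
#' generated trails within 2 km of new settlement cells. In the park
#' townsite zone, use of existing trails instead grows 25 percent per decade
#' and no new trails appear.
#'
#' @param current \code{activity_raster} at the decade start.
#' @param landscape \code{landscape_state} at the decade end (zones).
#' @param new_cells Integer indices of settlement cells added this decade.
#' @param growth Named fractions, e.g. \code{c(canmore = 0.23, rural = 0.17)},
#'   of decadal activity growth per municipality.
#' @param banff_decadal_growth Park-townsite trail intensification per decade
#'   (default 0.25).
#' @param rng_seed Seed for new-trail placement.
#' @return An \code{activity_raster}.
#' @export
forecast_activity <- function(current, landscape, new_cells, growth,
                              banff_decadal_growth = 0.25, rng_seed = 1) {
  stopifnot(all(growth >= 0))
  g <- current$grid
  set.seed(rng_seed %% .Machine$integer.max)
  abs_new <- current$absolute
  trails <- current$trails
  zones <- landscape$zones
  in_zone <- function(zone) {
    m <- matrix(FALSE, g$n_rows, g$n_cols); m[zones[[zone]]] <- TRUE; m
  }
  for (muni in names(growth)) {
    if (growth[[muni]] == 0) next
    zm <- in_zone(muni)
    tot <- sum(current$absolute[zm])
    add <- growth[[muni]] * tot
    if (add == 0) next
    tr_cells <- intersect(trails$cell, which(zm))
    if (length(tr_cells) == 0)
      stop(sprintf("allocation error: no existing trails in municipality '%s'",
                   muni), call. = FALSE)
    # half intensification of existing trails, proportional to current use
    base <- current$absolute[tr_cells]
    wts <- if (sum(base) > 0) base / sum(base) else rep(1 / length(base),
                                                        length(base))
    abs_new[tr_cells] <- abs_new[tr_cells] + 0.5 * add * wts
    # half on new trails near new settlement in this municipality
    muni_new <- intersect(new_cells, which(zm))
    nt <- NULL
    if (length(muni_new) > 0) {
      nid <- if (!is.null(trails) && nrow(trails)) max(trails$trail_id) + 1L else 1L
      nt <- new_trails_near(g, muni_new,
                            n_trails = max(3, length(muni_new) %/% 3),
                            mean_len = 10, start_id = nid)
      nt <- nt[nt$cell %in% which(zm), , drop = FALSE]  # keep mass in zone
      if (nrow(nt) == 0) nt <- NULL
    }
    if (!is.null(nt)) {
      per <- table(nt$cell)  # accumulate duplicates across trails exactly
      cells <- as.integer(names(per))
      abs_new[cells] <- abs_new[cells] +
        0.5 * add * as.integer(per) / nrow(nt)
      trails <- rbind(trails, nt)
    } else {
      # no new settlement here this decade: all growth intensifies trails
      abs_new[tr_cells] <- abs_new[tr_cells] + 0.5 * add * wts
    }
  }
  bz <- in_zone("banff")
  btr <- intersect(trails$cell, which(bz))
  abs_new[btr] <- abs_new[btr] * (1 + banff_decadal_growth)
  activity_raster(g, abs_new, current$scale, trails)
}

#' Mitigation-scenario specification
#'
#' Returns the knobs a scenario turns: a multiplier on town growth inputs
#' (footprint and activity), whether the area-to-be-determined zone is open
#' to development, and which post-hoc activity modification
#' \code{\link{apply_scenario}} performs.
#'
#' @param scenario One of \code{"base"}, \code{"limited_urban_expansion"},
#'   \code{"no_informal_trails"}, \code{"restricted_recreation"}.
#' @return List with \code{growth_scale}, \code{allow_atbd},
#'   \code{activity_rule}.
#' @export
scenario_spec <- function(scenario) {
  switch(scenario,
    base = list(growth_scale = 1, allow_atbd = TRUE, activity_rule = "none"),
    limited_urban_expansion =
      list(growth_scale = 0.15, allow_atbd = FALSE, activity_rule = "none"),
    no_informal_trails =
      list(growth_scale = 1, allow_atbd = TRUE,
           activity_rule = "no_informal_trails"),
    restricted_recreation =
      list(growth_scale = 1, allow_atbd = TRUE,
           activity_rule = "restricted_recreation"),
    stop(sprintf("unknown scenario '%s'", scenario), call. = FALSE))
}

#' Apply a mitigation scenario's activity modification
#'
#' \code{no_informal_trails} eliminates activity everywhere off designated
#' trails and off development footprint; \code{restricted_recreation} halves
#' activity at least 100 m away from settlement footprint;
#' \code{base} and \code{limited_urban_expansion} leave activity unchanged
#' here (the latter acts through pre-scaled growth inputs instead, see
#' \code{\link{scenario_spec}}).
#'
#' @param activity An \code{activity_raster}.
#' @param landscape The matching \code{landscape_state}.
#' @param scenario Scenario id.
#' @return An \code{activity_raster} with activity never exceeding the input.
#' @export
apply_scenario <- function(activity, landscape, scenario) {
  spec <- scenario_spec(scenario)
  g <- activity$grid
  a <- activity$absolute
  if (spec$activity_rule == "no_informal_trails") {
    keep <- footprint_fraction(landscape) > 1e-9
    des <- activity$trails$cell[activity$trails$designated]
    keep[des] <- TRUE
    a[!keep] <- 0
  } else if (spec$activity_rule == "restricted_recreation") {
    d <- distance_to(settlement_mask(landscape), g)
    a[d >= 100] <- a[d >= 100] * 0.5
  }
  activity_raster(g, a, activity$scale, activity$trails)
}
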