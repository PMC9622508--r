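risk_categories <- c("none", "very_low", "low", "moderate", "high")

#' Human-bear conflict risk index
#'
#' Risk is the cellwise product of the 400 m moving-window averages of the
#' connectivity index (0-5) and the recreation activity level (0-5):
#' overlap of high connectivity and high human activity creates risk of
#' conflict. The index therefore lies in [0, 25].
#'
#' @param conn A \code{connectivity_index}.
#' @param act An \code{activity_raster} on the same grid.
#' @param window_radius Moving-window radius in metres (default 400).
#' @return An object of class \code{"risk_raster"} with \code{index} and a
#'   \code{category} matrix from \code{\link{classify_risk}}.
#' @export
risk_index <- function(conn, act, window_radius = 400) {
  g <- conn$grid
  check_raster(act$level, g, "activity level")
  wc <- focal_mean(conn$level, window_radius, g)
  wa <- focal_mean(act$level, window_radius, g)
  idx <- wc * wa
  structure(list(grid = g, index = idx, category = classify_risk(idx)),
            class = "risk_raster")
}

#' Classify conflict risk values into categories
#'
#' Cut points follow the interpretation that risk above 9 means connectivity
#' and activity both exceed moderate values (3 x 3) on average, above 4 both
#' exceed low values (2 x 2), and above 1 both exceed very low values
#' (1 x 1): (9, 25] high, (4, 9] moderate, (1, 4] low, (0, 1] very low, and
#' exactly 0 a separate "none" class.
#'
#' @param index Numeric matrix (or vector) of risk values in [0, 25].
#' @return Character matrix/vector with values in
#'   \code{c("none", "very_low", "low", "moderate", "high")}.
#' @export
classify_risk <- function(index) {
  if (any(!is.finite(index)) || any(index < 0 | index > 25 + 1e-9))
    stop("risk index values must be finite and within [0, 25]", call. = FALSE)
  out <- ifelse(index > 9, "high",
         ifelse(index > 4, "moderate",
         ifelse(index > 1, "low",
         ifelse(index > 0, "very_low", "none"))))
  if (is.matrix(index)) out <- matrix(out, nrow(index), ncol(index))
  out
}

#' Summarize risk extents across years and scenarios
#'
#' Converts category rasters into km^2 per category, year and scenario, and
#' computes the percent change of the combined moderate-or-high extent of
#' each mitigation scenario relative to the Base Case of the same year.
#'
#' @param risks Nested named list: \code{risks[[scenario]][[year]]} is a
#'   \code{risk_raster}; must include scenario \code{"base"}.
#' @return Data frame (\code{year}, \code{scenario}, \code{category},
#'   \code{km2}); the moderate-or-high comparison is in
#'   \code{attr(, "mod_high")} with columns \code{year}, \code{scenario},
#'   \code{km2}, \code{pct_change_vs_base}.
#' @export
extent_summary <- function(risks) {
  rows <- list(); mh <- list()
  for (sc in names(risks)) for (yr in names(risks[[sc]])) {
    r <- risks[[sc]][[yr]]
    a <- cell_area_km2(r$grid)
    km2 <- vapply(risk_categories,
                  function(k) sum(r$category == k) * a, numeric(1))
    rows[[paste(sc, yr)]] <- data.frame(
      year = yr, scenario = sc, category = risk_categories,
      km2 = unname(km2), stringsAsFactors = FALSE)
    mh[[paste(sc, yr)]] <- data.frame(
      year = yr, scenario = sc,
      km2 = unname(km2[["moderate"]] + km2[["high"]]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(rows))
  mh <- do.call(rbind, unname(mh))
  if (identical(unique(mh$scenario), "base")) {
    attr(out, "mod_high") <- mh   # nothing to compare against: no change column
    return(out)
  }
  base <- mh[mh$scenario == "base", c("year", "km2")]
  names(base)[2] <- "base_km2"
  mh <- merge(mh, base, by = "year", all.x = TRUE, sort = FALSE)
  mh$pct_change_vs_base <-
    ifelse(mh$base_km2 > 0, 100 * (mh$km2 - mh$base_km2) / mh$base_km2,
           ifelse(mh$km2 > 0, Inf, 0))
  mh$base_km2 <- NULL
  attr(out, "mod_high") <- mh
  out
}
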