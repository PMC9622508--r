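#' Write a raster (or multi-band stack) to TIFF with a JSON sidecar
#'
#' Bands are min/max-normalized to [0,1] for 32-bit float TIFF storage; the
#' sidecar (\code{<path>.json}) records per-band min/max, band names and the
#' grid geometry so \code{read_raster()} restores values and georeferencing.
#'
#' @param x Numeric matrix, or named list of matrices (bands).
#' @param path Output file path (".tif").
#' @param grid A \code{grid_spec}.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(x, path, grid) {
  if (is.matrix(x)) x <- list(band1 = x)
  stopifnot(is.list(x), length(x) > 0)
  if (is.null(names(x))) names(x) <- paste0("band", seq_along(x))
  meta <- list(n_rows = grid$n_rows, n_cols = grid$n_cols,
               cell_size = grid$cell_size, origin = grid$origin,
               bands = list())
  imgs <- vector("list", length(x))
  for (i in seq_along(x)) {
    check_raster(x[[i]], grid, names(x)[i])
    lo <- min(x[[i]]); hi <- max(x[[i]])
    span <- if (hi > lo) hi - lo else 1
    imgs[[i]] <- (x[[i]] - lo) / span
    meta$bands[[names(x)[i]]] <- list(min = lo, max = hi)
  }
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster written by \code{write_raster}
#'
#' @param path Path to the ".tif" file (sidecar expected at
#'   \code{<path>.json}).
#' @return List with \code{grid} and \code{bands} (named list of matrices).
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- grid_spec(meta$n_rows, meta$n_cols, meta$cell_size, meta$origin)
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  nms <- names(meta$bands)
  bands <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    b <- meta$bands[[i]]
    span <- if (b$max > b$min) b$max - b$min else 1
    bands[[i]] <- matrix(imgs[[i]], grid$n_rows, grid$n_cols) * span + b$min
  }
  names(bands) <- nms
  list(grid = grid, bands = bands)
}

#' Write an area report as CSV
#' @param report An \code{area_report}.
#' @param path Output CSV path.
#' @export
write_area_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

cells_to_coords <- function(cells, grid) {
  xy <- cell_centres(grid, cells)
  lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1], xy[i, 2]))
}

#' Write trails as GeoJSON
#'
#' Each trail becomes a LineString feature through its cell centres, with a
#' boolean \code{designated} property.
#'
#' @param trails Data frame with columns \code{trail_id}, \code{cell},
#'   \code{designated}.
#' @param grid A \code{grid_spec}.
#' @param path Output path.
#' @export
write_trails_geojson <- function(trails, grid, path) {
  feats <- lapply(split(trails, trails$trail_id), function(tr) {
    list(type = "Feature",
         properties = list(trail_id = tr$trail_id[1],
                           designated = tr$designated[1]),
         geometry = list(type = "LineString",
                         coordinates = cells_to_coords(tr$cell, grid)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = unname(feats)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write wildlife crossings as GeoJSON points with construction year
#'
#' @param crossings Data frame with columns \code{cell}, \code{year_built}.
#' @param grid A \code{grid_spec}.
#' @param path Output path.
#' @export
write_crossings_geojson <- function(crossings, grid, path) {
  xy <- cell_centres(grid, crossings$cell)
  feats <- lapply(seq_len(nrow(crossings)), function(i) {
    list(type = "Feature",
         properties = list(year_built = crossings$year_built[i]),
         geometry = list(type = "Point", coordinates = c(xy[i, 1], xy[i, 2])))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = unname(feats)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
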