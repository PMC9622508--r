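#' Define a raster grid
#'
#' A grid is the shared spatial frame for every raster in the pipeline: a
#' row-major matrix of square cells in a planar metric coordinate system.
#' Cell centres sit at \code{origin + (index - 0.5) * cell_size}.
#'
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param cell_size Cell edge length in metres (default 100).
#' @param origin Numeric length-2, (x, y) of the grid's lower-left corner in
#'   metres.
#' @return An object of class \code{"grid_spec"}.
#' @examples
#' g <- grid_spec(200, 450)        # 20 km x 45 km = 900 km^2 at 100 m
#' grid_area_km2(g)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 100, origin = c(0, 0)) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, length(origin) == 2)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, origin = as.numeric(origin)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells at %g m (%.1f km2)\n",
              x$n_rows, x$n_cols, x$cell_size, grid_area_km2(x)))
  invisible(x)
}

#' Total grid area in square kilometres
#' @param grid A \code{grid_spec}.
#' @export
grid_area_km2 <- function(grid) {
  grid$n_rows * grid$n_cols * (grid$cell_size / 1000)^2
}

#' Area of one cell in square kilometres
#' @param grid A \code{grid_spec}.
#' @export
cell_area_km2 <- function(grid) (grid$cell_size / 1000)^2

check_raster <- function(x, grid, what = "raster") {
  if (!is.matrix(x) || nrow(x) != grid$n_rows || ncol(x) != grid$n_cols)
    stop(sprintf("%s dimensions (%s) do not match grid (%d x %d)",
                 what, paste(dim(x), collapse = " x "),
                 grid$n_rows, grid$n_cols), call. = FALSE)
  invisible(TRUE)
}

#' Cell centre coordinates
#'
#' @param grid A \code{grid_spec}.
#' @param cells Optional integer vector of cell indices (column-major, as
#'   returned by \code{which()} on a matrix); defaults to all cells.
#' @return Matrix with columns \code{x}, \code{y} in metres.
#' @export
cell_centres <- function(grid, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(grid$n_rows * grid$n_cols)
  row <- (cells - 1L) %% grid$n_rows + 1L
  col <- (cells - 1L) %/% grid$n_rows + 1L
  cbind(x = grid$origin[1] + (col - 0.5) * grid$cell_size,
        y = grid$origin[2] + (row - 0.5) * grid$cell_size)
}

#' Euclidean distance to the nearest masked cell
#'
#' Exact Euclidean distance (metres) from every cell centre to the nearest
#' cell centre where \code{mask} is \code{TRUE}. Masked cells get 0. An empty
#' mask returns \code{Inf} everywhere.
#'
#' @param mask Logical matrix on \code{grid}.
#' @param grid A \code{grid_spec}.
#' @return Numeric matrix of distances in metres.
#' @export
distance_to <- function(mask, grid) {
  check_raster(mask, grid, "mask")
  mask <- mask & !is.na(mask)
  if (!any(mask)) {
    return(matrix(Inf, grid$n_rows, grid$n_cols))
  }
  # EBImage::distmap: per-pixel distance (in pixels) to the nearest
  # background (zero) pixel, so invert the mask.
  d <- EBImage::distmap(matrix(as.numeric(!mask), grid$n_rows, grid$n_cols),
                        metric = "euclidean")
  matrix(as.numeric(d), grid$n_rows, grid$n_cols) * grid$cell_size
}

#' Circular moving-window mean
#'
#' Mean of \code{values} over cells whose centres lie within \code{radius}
#' metres of the focal cell centre (focal cell included). At the grid edge the
#' window shrinks to its in-bounds subset, so boundary averages are unbiased.
#' \code{radius = 0} returns the input unchanged.
#'
#' @param values Numeric matrix on \code{grid}.
#' @param radius Window radius in metres (>= 0).
#' @param grid A \code{grid_spec}.
#' @return Numeric matrix of windowed means.
#' @export
focal_mean <- function(values, radius, grid) {
  check_raster(values, grid, "values")
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) || radius < 0)
    stop("radius must be a single non-negative number", call. = FALSE)
  k <- floor(radius / grid$cell_size)
  if (k == 0) return(values)
  nr <- grid$n_rows; nc <- grid$n_cols
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  r2 <- (radius / grid$cell_size)^2
  for (di in -k:k) for (dj in -k:k) {
    if (di * di + dj * dj > r2 + 1e-12) next
    sr <- max(1, 1 - di):min(nr, nr - di)   # target rows receiving shift
    sc <- max(1, 1 - dj):min(nc, nc - dj)
    acc[sr, sc] <- acc[sr, sc] + values[sr + di, sc + dj]
    cnt[sr, sc] <- cnt[sr, sc] + 1
  }
  acc / cnt
}

#' Construct a cover-fraction stack
#'
#' Landscape composition as the fraction of each cell covered by each cover
#' class. Fractions of every cell must sum to 1 (tolerance 1e-9).
#'
#' @param grid A \code{grid_spec}.
#' @param layers Named list of fraction matrices, one per cover class.
#' @param anthropogenic Character vector naming which classes are development
#'   footprint; the rest are natural.
#' @return An object of class \code{"cover_stack"}.
#' @export
cover_stack <- function(grid, layers, anthropogenic = character()) {
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  for (nm in names(layers)) {
    check_raster(layers[[nm]], grid, nm)
    rng <- range(layers[[nm]])
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop(sprintf("fractions of class '%s' outside [0,1]", nm), call. = FALSE)
  }
  tot <- Reduce(`+`, layers)
  if (max(abs(tot - 1)) > 1e-9)
    stop("cell cover fractions do not sum to 1", call. = FALSE)
  if (!all(anthropogenic %in% names(layers)))
    stop("unknown anthropogenic class name", call. = FALSE)
  structure(list(grid = grid, layers = layers,
                 anthropogenic = anthropogenic,
                 natural = setdiff(names(layers), anthropogenic)),
            class = "cover_stack")
}

#' @export
print.cover_stack <- function(x, ...) {
  cat(sprintf("<cover_stack> %d classes (%d anthropogenic) on %d x %d grid\n",
              length(x$layers), length(x$anthropogenic),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Per-class area accounting
#'
#' Sums cover fractions into km^2 per class; the development footprint total
#' is the exact sum of the anthropogenic class areas.
#'
#' @param stack A \code{cover_stack}.
#' @return A data frame of class \code{"area_report"} with columns
#'   \code{class}, \code{type} (natural/anthropogenic) and \code{km2}; the
#'   anthropogenic total is in \code{attr(, "total_footprint_km2")}.
#' @export
area_report <- function(stack) {
  stopifnot(inherits(stack, "cover_stack"))
  a <- cell_area_km2(stack$grid)
  km2 <- vapply(stack$layers, function(m) sum(m) * a, numeric(1))
  out <- data.frame(class = names(km2),
                    type = ifelse(names(km2) %in% stack$anthropogenic,
                                  "anthropogenic", "natural"),
                    km2 = unname(km2), stringsAsFactors = FALSE)
  attr(out, "total_footprint_km2") <-
    sum(out$km2[out$type == "anthropogenic"])
  class(out) <- c("area_report", "data.frame")
  out
}

#' Relative change between two values, in percent
#'
#' @param from,to Numeric values (e.g. mean activity levels at two periods).
#' @return 100 * (to - from) / from.
#' @export
percent_change <- function(from, to) 100 * (to - from) / from
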