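#' Grid specification for a planar raster stack
#'
#' All rasters in a [landscape()] share one grid: `n_rows * n_cols` square
#' cells of `cell_area` square kilometres each, in an abstract planar CRS
#' with kilometre units (row 1 is the northern edge). Rasters are plain
#' numeric matrices with `NA` as no-data.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param cell_area area of one cell in km^2 (> 0); the default 1 km^2
#'   matches the working resolution of regional conservation assessments.
#' @param origin numeric length-2, planar (x, y) of the grid's upper-left
#'   corner in km.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_area = 1, origin = c(0, 0)) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_area > 0, length(origin) == 2)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_area = as.numeric(cell_area), origin = as.numeric(origin)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g km^2 (origin %g, %g)\n",
              x$n_rows, x$n_cols, x$cell_area, x$origin[1], x$origin[2]))
  invisible(x)
}

cell_side_km <- function(grid) sqrt(grid$cell_area)

#' Cell-centre coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return list with matrices `x` and `y` (km), same dim as the grid.
#'   y decreases with row index (row 1 is north).
#' @keywords internal
cell_centers <- function(grid) {
  s <- cell_side_km(grid)
  x <- matrix(grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * s,
              grid$n_rows, grid$n_cols, byrow = TRUE)
  y <- matrix(grid$origin[2] - (seq_len(grid$n_rows) - 0.5) * s,
              grid$n_rows, grid$n_cols)
  list(x = x, y = y)
}

same_grid <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_area, b$cell_area)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

check_aligned <- function(raster, grid, name = "layer") {
  if (!is.matrix(raster) || nrow(raster) != grid$n_rows ||
      ncol(raster) != grid$n_cols) {
    stop(sprintf(
      "layer '%s' is not aligned to the grid: expected %d x %d matrix, got %s",
      name, grid$n_rows, grid$n_cols,
      if (is.matrix(raster)) paste(dim(raster), collapse = " x ")
      else class(raster)[1]), call. = FALSE)
  }
  invisible(raster)
}
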