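#' Define a rectangular model domain
#'
#' A regular projected grid of square cells. Row 1 is the southern edge and
#' rows increase northward; column 1 is the western edge and columns increase
#' eastward. Coordinates are kilometres in an arbitrary projected frame with
#' `origin` at the domain's southwest corner.
#'
#' @param n_rows,n_cols Number of grid rows (south-north) and columns
#'   (west-east). Must be at least 1.
#' @param cell_size Cell edge length in km. Default 12, a typical regional
#'   air-quality model resolution.
#' @param origin Length-2 numeric, (x, y) km of the southwest corner.
#' @return An object of class `domain_grid`.
#' @examples
#' g <- domain_grid(20, 20)
#' cell_centers(g)[1, ]
#' @export
domain_grid <- function(n_rows, n_cols, cell_size = 12, origin = c(0, 0)) {
  stopifnot(
    length(n_rows) == 1, length(n_cols) == 1,
    n_rows >= 1, n_cols >= 1,
    n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
    length(cell_size) == 1, cell_size > 0,
    length(origin) == 2, is.numeric(origin)
  )
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size = as.numeric(cell_size), origin = as.numeric(origin)
    ),
    class = "domain_grid"
  )
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf(
    "domain_grid: %d x %d cells of %g km (%g x %g km), origin (%g, %g)\n",
    x$n_rows, x$n_cols, x$cell_size,
    x$n_rows * x$cell_size, x$n_cols * x$cell_size,
    x$origin[1], x$origin[2]
  ))
  invisible(x)
}

#' Cell-center coordinates of a domain grid
#'
#' @param grid A [domain_grid()].
#' @return A data.frame with columns `row`, `col`, `x`, `y` (km), one row per
#'   cell in column-major order (row varies fastest).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "domain_grid"))
  row <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  data.frame(
    row = row, col = col,
    x = grid$origin[1] + (col - 0.5) * grid$cell_size,
    y = grid$origin[2] + (row - 0.5) * grid$cell_size
  )
}

#' Number of cells in a grid
#' @param grid A [domain_grid()].
#' @return Integer cell count.
#' @export
n_cells <- function(grid) grid$n_rows * grid$n_cols

# linear cell index, row varies fastest (matches R matrix storage)
cell_index <- function(grid, row, col) (col - 1L) * grid$n_rows + row
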