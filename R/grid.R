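#' Regular equal-area analysis grid
#'
#' Builds the spatial frame used throughout the package: a lattice of square
#' cells of edge length \code{grain} km on a planar equal-area coordinate
#' frame. The real-world analogue is a Behrmann-projected grid, whose only
#' property used here is that all cells share one area; synthetic grids
#' satisfy it by construction, so no projection code is involved.
#'
#' Cell indexing is 0-based row-major from the south-west corner: cell
#' \code{row * n_cols + col}, with row 0 the southernmost row. All interfaces
#' in the package use these integer cell ids.
#'
#' @param n_rows,n_cols lattice dimensions (counts of cells).
#' @param grain cell edge length in km.
#' @param origin planar coordinates (km) of the grid's south-west corner.
#' @return An object of class \code{endem_grid} with elements \code{cells}
#'   (data frame: \code{cell}, \code{row}, \code{col}, centroid \code{x},
#'   \code{y} in km), \code{n_rows}, \code{n_cols}, \code{grain},
#'   \code{cell_area} (km^2) and \code{origin}.
#' @examples
#' g <- endem_grid(4, 5, grain = 100)
#' head(g$cells)
#' @export
endem_grid <- function(n_rows, n_cols, grain = 100, origin = c(0, 0)) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid must have at least one row and one column", call. = FALSE)
  if (!is.numeric(grain) || grain <= 0)
    stop("'grain' must be a positive cell edge length in km", call. = FALSE)
  cell <- seq_len(n_rows * n_cols) - 1L
  row <- cell %/% n_cols
  col <- cell %% n_cols
  cells <- data.frame(
    cell = cell, row = row, col = col,
    x = origin[1] + (col + 0.5) * grain,
    y = origin[2] + (row + 0.5) * grain
  )
  structure(
    list(cells = cells, n_rows = n_rows, n_cols = n_cols, grain = grain,
         cell_area = grain^2, origin = origin),
    class = "endem_grid"
  )
}

#' @export
print.endem_grid <- function(x, ...) {
  cat(sprintf("endem_grid: %d x %d cells, grain %g km (cell area %g km^2)\n",
              x$n_rows, x$n_cols, x$grain, x$cell_area))
  invisible(x)
}

n_cells <- function(grid) nrow(grid$cells)

is_endem_grid <- function(x) inherits(x, "endem_grid")

# rook (4-neighbour) adjacency of one 0-based cell id
rook_neighbours <- function(grid, cell) {
  r <- cell %/% grid$n_cols
  c <- cell %% grid$n_cols
  nb <- c(
    if (r > 0L) cell - grid$n_cols,
    if (r < grid$n_rows - 1L) cell + grid$n_cols,
    if (c > 0L) cell - 1L,
    if (c < grid$n_cols - 1L) cell + 1L
  )
  as.integer(nb)
}

#' Coarsen a grid by an integer aggregation factor
#'
#' Blocks of \code{factor} x \code{factor} fine cells become one coarse cell,
#' doubling (etc.) the grain. Trailing rows/columns beyond the largest
#' divisible block are dropped with a warning so coarse cells stay equal-area.
#'
#' @param grid an \code{\link{endem_grid}}.
#' @param factor integer aggregation factor, \code{>= 2}.
#' @return A coarser \code{endem_grid} with \code{grain * factor}.
#' @export
aggregate_grid <- function(grid, factor) {
  stopifnot(is_endem_grid(grid))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L)
    stop("'factor' must be an integer >= 2", call. = FALSE)
  nr2 <- grid$n_rows %/% factor
  nc2 <- grid$n_cols %/% factor
  if (nr2 < 1L || nc2 < 1L)
    stop("grid too small for this aggregation factor", call. = FALSE)
  if (nr2 * factor != grid$n_rows || nc2 * factor != grid$n_cols)
    warning(sprintf(
      "dropping %d trailing row(s) and %d trailing column(s) not divisible by %d",
      grid$n_rows - nr2 * factor, grid$n_cols - nc2 * factor, factor
    ), call. = FALSE)
  endem_grid(nr2, nc2, grain = grid$grain * factor, origin = grid$origin)
}

# map fine 0-based cell ids to coarse ids (NA for dropped trailing cells)
coarse_index <- function(grid, factor) {
  factor <- as.integer(factor)
  nr2 <- grid$n_rows %/% factor
  nc2 <- grid$n_cols %/% factor
  r <- grid$cells$row
  c <- grid$cells$col
  idx <- (r %/% factor) * nc2 + (c %/% factor)
  idx[r >= nr2 * factor | c >= nc2 * factor] <- NA_integer_
  as.integer(idx)
}
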