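#' Presence-absence community matrix on a grid
#'
#' @name endem_comm
#' @details A community is a logical cells-by-taxa matrix plus the grid it
#'   lives on. Row names are cell ids (as characters of the 0-based integer
#'   id); column names are taxon labels. The global range of taxon t,
#'   \code{R_t}, is its column sum in cells; every retained taxon has
#'   \code{R_t >= 1}.
NULL

new_comm <- function(presence, grid) {
  stopifnot(is.logical(presence), is.matrix(presence), is_endem_grid(grid))
  if (anyDuplicated(colnames(presence)))
    stop("duplicate taxon labels in community", call. = FALSE)
  structure(list(presence = presence, grid = grid), class = "endem_comm")
}

is_endem_comm <- function(x) inherits(x, "endem_comm")

#' @export
print.endem_comm <- function(x, ...) {
  cat(sprintf("endem_comm: %d cells x %d taxa on a %d x %d grid (grain %g km)\n",
              nrow(x$presence), ncol(x$presence),
              x$grid$n_rows, x$grid$n_cols, x$grid$grain))
  invisible(x)
}

# ray-casting point-in-polygon; poly is a 2-column (x, y) vertex matrix
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize species ranges into a presence-absence community matrix
#'
#' Each range is either an explicit set of 0-based cell ids, or a polygon
#' outline (a 2-column x/y vertex matrix in the grid's km frame). Polygon
#' membership is decided by a cell-centroid-in-polygon test. Taxa whose
#' rasterized range is empty are dropped with a warning.
#'
#' @param ranges named list: taxon -> integer cell ids, or taxon -> polygon
#'   vertex matrix.
#' @param grid an \code{\link{endem_grid}}.
#' @return An \code{endem_comm} whose presence entry (cell, t) is 1 iff the
#'   cell belongs to the range of t.
#' @examples
#' g <- endem_grid(1, 2, grain = 100)
#' cm <- ranges_to_community(list(A = 0L, B = c(0L, 1L)), g)
#' colSums(cm$presence)  # range sizes 1 and 2
#' @export
ranges_to_community <- function(ranges, grid) {
  stopifnot(is_endem_grid(grid))
  if (!is.list(ranges) || length(ranges) == 0L)
    stop("'ranges' must be a non-empty named list", call. = FALSE)
  if (is.null(names(ranges)) || any(names(ranges) == "") ||
      anyDuplicated(names(ranges)))
    stop("'ranges' must have unique non-empty taxon names", call. = FALSE)
  cells <- grid$cells
  membership <- lapply(seq_along(ranges), function(i) {
    r <- ranges[[i]]
    if (is.matrix(r)) {
      cells$cell[point_in_polygon(cells$x, cells$y, r)]
    } else {
      r <- unique(as.integer(r))
      bad <- setdiff(r, cells$cell)
      if (length(bad))
        stop(sprintf("unknown cell id(s) for taxon '%s': %s",
                     names(ranges)[i],
                     paste(utils::head(bad, 5L), collapse = ", ")),
             call. = FALSE)
      r
    }
  })
  names(membership) <- names(ranges)
  empty <- lengths(membership) == 0L
  if (all(empty))
    stop("all taxa have empty rasterized ranges", call. = FALSE)
  if (any(empty)) {
    warning(sprintf("dropping %d taxon/taxa with empty rasterized ranges: %s",
                    sum(empty), paste(names(membership)[empty], collapse = ", ")),
            call. = FALSE)
    membership <- membership[!empty]
  }
  presence <- matrix(FALSE, nrow(cells), length(membership),
                     dimnames = list(as.character(cells$cell), names(membership)))
  for (j in seq_along(membership))
    presence[as.character(membership[[j]]), j] <- TRUE
  new_comm(presence, grid)
}

#' Per-cell species richness
#'
#' @param comm an \code{endem_comm}.
#' @return Named integer vector over cells: number of taxa present.
#' @export
species_richness <- function(comm) {
  stopifnot(is_endem_comm(comm))
  counts <- rowSums(comm$presence)
  storage.mode(counts) <- "integer"
  counts
}

#' Global range sizes in cells
#'
#' @param comm an \code{endem_comm}.
#' @return Named integer vector over taxa: R_t, the number of occupied cells.
#' @export
range_sizes <- function(comm) {
  stopifnot(is_endem_comm(comm))
  counts <- colSums(comm$presence)
  storage.mode(counts) <- "integer"
  counts
}

#' Aggregate a community matrix to a coarser grain
#'
#' Coarse-cell presence is the logical OR of the fine cells in each
#' \code{factor} x \code{factor} block; the taxon set is unchanged. Grids not
#' divisible by \code{factor} lose their trailing rows/columns (warning), as
#' in \code{\link{aggregate_grid}}.
#'
#' @param comm an \code{endem_comm} covering the full grid.
#' @param factor integer aggregation factor \code{>= 2}.
#' @return An \code{endem_comm} on the coarsened grid.
#' @export
aggregate_grain <- function(comm, factor) {
  stopifnot(is_endem_comm(comm))
  if (nrow(comm$presence) != n_cells(comm$grid))
    stop("aggregate_grain() needs a community covering the full grid",
         call. = FALSE)
  grid2 <- aggregate_grid(comm$grid, factor)
  idx <- coarse_index(comm$grid, factor)
  keep <- !is.na(idx)
  p <- comm$presence[keep, , drop = FALSE] * 1L
  agg <- rowsum(p, group = idx[keep])  # groups sorted ascending = coarse ids
  presence2 <- agg > 0L
  rownames(presence2) <- as.character(sort(unique(idx[keep])))
  dropped <- colSums(presence2) == 0L
  if (any(dropped)) {  # only possible when a range sat entirely in dropped margins
    warning(sprintf("dropping taxa lost to the trailing-cell drop: %s",
                    paste(colnames(presence2)[dropped], collapse = ", ")),
            call. = FALSE)
    presence2 <- presence2[, !dropped, drop = FALSE]
  }
  new_comm(presence2, grid2)
}
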