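#' Per-cell endemism surface
#'
#' Container for one metric (WE or PE) evaluated per grid cell under one
#' scale configuration. Values are non-negative and cells with no taxa carry
#' value 0; \code{occupied} records which cells hold at least one taxon
#' (quantile thresholds for hotspots are taken over occupied cells only).
#'
#' @param values named numeric vector over cell ids.
#' @param occupied named logical vector over the same cells.
#' @param metric "WE" or "PE".
#' @param grid the \code{\link{endem_grid}} the cells belong to.
#' @param config optional list recording the scale configuration (grain,
#'   extent, lumping depth, ...).
#' @return An object of class \code{endem_surface}.
#' @export
endem_surface <- function(values, occupied, metric, grid, config = list()) {
  stopifnot(is.numeric(values), is.logical(occupied),
            length(values) == length(occupied),
            identical(names(values), names(occupied)),
            metric %in% c("WE", "PE"), is_endem_grid(grid))
  if (any(values < -1e-12))
    stop("endemism values must be non-negative", call. = FALSE)
  structure(list(values = values, occupied = occupied, metric = metric,
                 grid = grid, config = config),
            class = "endem_surface")
}

#' @export
print.endem_surface <- function(x, ...) {
  cat(sprintf("endem_surface [%s]: %d cells (%d occupied), max %.4g, sum %.4g\n",
              x$metric, length(x$values), sum(x$occupied),
              max(x$values), sum(x$values)))
  invisible(x)
}

#' Weighted endemism: richness inversely weighted by range size
#'
#' For each cell, WE = sum over resident taxa of r_t / R_t, where R_t is the
#' taxon's global range in cells and r_t its range within the focal
#' neighbourhood. With the default \code{neighbourhood = 0} the neighbourhood
#' is the focal cell alone (r_t = 1 for residents), so per-cell values sum to
#' the number of taxa over the whole grid — the conservation identity used by
#' the tests.
#'
#' @param comm an \code{endem_comm}.
#' @param neighbourhood Manhattan (rook graph) radius of the local
#'   neighbourhood in cells; 0 = focal cell only.
#' @return An \code{endem_surface} with \code{metric = "WE"}.
#' @examples
#' g <- endem_grid(1, 3)
#' cm <- ranges_to_community(list(A = 0L, B = 0:2), g)
#' weighted_endemism(cm)$values  # 1 + 1/3, 1/3, 1/3
#' @export
weighted_endemism <- function(comm, neighbourhood = 0) {
  stopifnot(is_endem_comm(comm))
  p <- comm$presence
  R <- colSums(p)
  stopifnot(all(R >= 1L))
  if (neighbourhood == 0) {
    r_local <- p * 1
  } else {
    ids <- as.integer(rownames(p))
    r <- ids %/% comm$grid$n_cols
    c <- ids %% comm$grid$n_cols
    # counts of occupied neighbourhood cells per (focal cell, taxon)
    r_local <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
    for (i in seq_len(nrow(p))) {
      nb <- abs(r - r[i]) + abs(c - c[i]) <= neighbourhood
      r_local[i, ] <- colSums(p[nb, , drop = FALSE])
    }
  }
  values <- as.vector(r_local %*% (1 / R))
  names(values) <- rownames(p)
  endem_surface(values, rowSums(p) > 0, "WE", comm$grid,
                config = list(neighbourhood = neighbourhood))
}

# Occupancy of every tree node over the community's cells, bottom-up.
# absent_tips: "error" rejects tree tips missing from the community;
# "zero" treats them as occupying no cell (used for regional extents where
# taxa were truncated away but branch proportions keep the full tree).
edge_occupancy <- function(comm, tree, absent_tips = c("error", "zero")) {
  absent_tips <- match.arg(absent_tips)
  taxa <- colnames(comm$presence)
  extra <- setdiff(taxa, tree$tip.label)
  if (length(extra))
    warning(sprintf("%d community taxa absent from tree are ignored: %s",
                    length(extra),
                    paste(utils::head(extra, 5L), collapse = ", ")),
            call. = FALSE)
  missing <- setdiff(tree$tip.label, taxa)
  if (length(missing) && absent_tips == "error")
    stop(sprintf("tree tip(s) absent from community: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  ntip <- length(tree$tip.label)
  ncell <- nrow(comm$presence)
  occ <- matrix(FALSE, ncell, ntip + tree$Nnode)
  shared <- intersect(tree$tip.label, taxa)
  occ[, match(shared, tree$tip.label)] <- comm$presence[, shared, drop = FALSE]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    occ[, eo[k, 1L]] <- occ[, eo[k, 1L]] | occ[, eo[k, 2L]]
  rownames(occ) <- rownames(comm$presence)
  occ
}

#' Clade range sizes per branch
#'
#' For each branch of the tree, R_i = number of cells occupied by the union
#' of its descendant tips' ranges, computed bottom-up. A parent branch's R_i
#' is therefore at least each child's.
#'
#' @param comm an \code{endem_comm}.
#' @param tree a rooted \code{phylo}; tips must occur in the community
#'   (community taxa absent from the tree are ignored with a warning).
#' @return Data frame with one row per edge: \code{edge}, \code{parent},
#'   \code{child} (ape node ids) and \code{R} (cells).
#' @export
branch_ranges <- function(comm, tree) {
  stopifnot(is_endem_comm(comm))
  validate_phylogeny(tree, ultrametric = FALSE)
  occ <- edge_occupancy(comm, tree, absent_tips = "error")
  R <- colSums(occ)[tree$edge[, 2L]]
  data.frame(edge = seq_len(nrow(tree$edge)),
             parent = tree$edge[, 1L], child = tree$edge[, 2L],
             R = as.integer(R))
}

#' Phylogenetic endemism: branch lengths weighted by inverse clade range
#'
#' For each cell, PE = sum over the branches connecting the cell's resident
#' taxa to the root of L_i / R_i, each branch counted once. By default L_i is
#' the branch length expressed as a proportion of the total tree length, so
#' that with complete tip sampling the per-cell values sum to 1 over the
#' grid; \code{normalized = FALSE} keeps raw Myr units. The root's subtending
#' edge, if present, is not a branch of the set.
#'
#' @param comm an \code{endem_comm}.
#' @param tree a rooted \code{phylo} with branch lengths.
#' @param normalized express L_i as a proportion of total tree length.
#' @param absent_tips what to do with tree tips missing from the community:
#'   \code{"error"} (default) or \code{"zero"} (they occupy no cell; used for
#'   regional extents, where branch proportions still refer to the full
#'   tree).
#' @return An \code{endem_surface} with \code{metric = "PE"}.
#' @examples
#' g <- endem_grid(1, 2)
#' cm <- ranges_to_community(list(A = 0L, B = 0:1), g)
#' tr <- read_newick("(A:1,B:1);")
#' phylo_endemism(cm, tr)$values  # 0.75, 0.25
#' @export
phylo_endemism <- function(comm, tree, normalized = TRUE,
                           absent_tips = c("error", "zero")) {
  stopifnot(is_endem_comm(comm))
  validate_phylogeny(tree, ultrametric = FALSE)
  absent_tips <- match.arg(absent_tips)
  occ <- edge_occupancy(comm, tree, absent_tips = absent_tips)
  L <- tree$edge.length
  if (normalized) L <- L / sum(L)
  child <- tree$edge[, 2L]
  Rv <- colSums(occ)[child]
  use <- Rv > 0
  w <- numeric(length(L))
  w[use] <- L[use] / Rv[use]
  values <- as.vector(occ[, child, drop = FALSE] %*% w)
  names(values) <- rownames(comm$presence)
  richness <- rowSums(comm$presence[, intersect(colnames(comm$presence),
                                                tree$tip.label),
                                    drop = FALSE])
  endem_surface(values, richness > 0, "PE", comm$grid,
                config = list(normalized = normalized))
}

#' Restrict a community to one region (continent or country)
#'
#' Implements extent restriction: cells whose centroid falls outside the
#' region are removed, taxa with no remaining presence are dropped, and range
#' sizes are implicitly recomputed within the region. Phylogenetic endemism
#' on the result (with \code{absent_tips = "zero"} and the full tree) yields
#' regional PE, which can only exceed global PE cell-wise because regional
#' clade ranges are subsets of global ones.
#'
#' @param comm an \code{endem_comm}.
#' @param regions data frame with columns \code{cell}, \code{continent},
#'   \code{country} (see \code{\link{partition_regions}}).
#' @param extent a region label present in the chosen \code{level} column.
#' @param level "continent" or "country".
#' @return An \code{endem_comm} over the region's cells only.
#' @export
restrict_extent <- function(comm, regions, extent,
                            level = c("continent", "country")) {
  stopifnot(is_endem_comm(comm))
  level <- match.arg(level)
  if (!extent %in% regions[[level]])
    stop(sprintf("unknown %s label '%s'", level, extent), call. = FALSE)
  keep_cells <- as.character(regions$cell[regions[[level]] == extent])
  rows <- rownames(comm$presence) %in% keep_cells
  p <- comm$presence[rows, , drop = FALSE]
  keep_taxa <- colSums(p) > 0L
  if (!any(keep_taxa))
    stop(sprintf("no taxa occur within %s '%s'", level, extent), call. = FALSE)
  out <- new_comm(p[, keep_taxa, drop = FALSE], comm$grid)
  attr(out, "extent") <- list(level = level, label = extent)
  out
}
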