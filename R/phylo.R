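#' Read a rooted ultrametric phylogeny from Newick
#'
#' Thin wrapper around \code{ape::read.tree} that enforces the contracts the
#' slicing and endemism code relies on: branch lengths present and
#' non-negative, unique tip labels, and (by default) ultrametricity within
#' \code{tol} — all tip depths equal, so node ages are well defined.
#' Branch lengths are interpreted as Myr.
#'
#' @param text Newick string, or \code{NULL} to read from \code{file}.
#' @param file path to a Newick file with a single tree.
#' @param ultrametric reject non-ultrametric trees (default); set to
#'   \code{FALSE} to skip the check.
#' @param tol ultrametricity tolerance in Myr.
#' @return An \code{ape} \code{phylo} object.
#' @export
read_newick <- function(text = NULL, file = NULL, ultrametric = TRUE,
                        tol = 1e-6) {
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else ape::read.tree(file = file)
  if (is.null(tree))
    stop("could not parse Newick input", call. = FALSE)
  if (inherits(tree, "multiPhylo"))
    stop("input holds several trees; use read_newick_set()", call. = FALSE)
  validate_phylogeny(tree, ultrametric = ultrametric, tol = tol)
  tree
}

#' Read a set of trees (one Newick per line), e.g. a posterior sample
#'
#' @inheritParams read_newick
#' @return A list of validated \code{phylo} objects.
#' @export
read_newick_set <- function(file, ultrametric = TRUE, tol = 1e-6) {
  trees <- ape::read.tree(file = file)
  if (is.null(trees)) stop("could not parse Newick input", call. = FALSE)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  lapply(trees, validate_phylogeny, ultrametric = ultrametric, tol = tol)
  trees
}

#' Write trees as Newick text
#'
#' @param tree a \code{phylo} or list of them.
#' @param file output path, or \code{NULL} to return the text.
#' @param digits significant digits for branch lengths; the default round-trips
#'   doubles to well below 1e-9.
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  if (inherits(tree, "phylo")) tree <- list(tree)
  class(tree) <- "multiPhylo"
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

validate_phylogeny <- function(tree, ultrametric = TRUE, tol = 1e-6) {
  if (!inherits(tree, "phylo"))
    stop("not a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative and complete", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels", call. = FALSE)
  if (ultrametric) {
    d <- ape::node.depth.edgelength(tree)
    tipd <- d[seq_along(tree$tip.label)]
    if (max(tipd) - min(tipd) > tol)
      stop(sprintf("tree is not ultrametric (tip depth spread %.3g > tol %.3g)",
                   max(tipd) - min(tipd), tol), call. = FALSE)
  }
  invisible(tree)
}

#' Node ages of an ultrametric tree
#'
#' Age = distance to the tips (present = 0), computed from the mean tip depth
#' so near-ultrametric trees (within the read tolerance) get consistent ages.
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @return Numeric vector over all node ids (tips first, then internals).
#' @export
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  h <- mean(d[seq_along(tree$tip.label)])
  ages <- h - d
  ages[seq_along(tree$tip.label)] <- pmax(ages[seq_along(tree$tip.label)], 0)
  ages
}

root_height <- function(tree) {
  node_ages(tree)[length(tree$tip.label) + 1L]
}

# tips under every node, as sorted label vectors (postorder accumulation)
clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  total <- ntip + tree$Nnode
  sets <- vector("list", total)
  sets[seq_len(ntip)] <- as.list(tree$tip.label)
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    sets[[eo[k, 1L]]] <- c(sets[[eo[k, 1L]]], sets[[eo[k, 2L]]])
  lapply(sets, sort)
}

#' Slice a tree at a time depth and return the induced tip partition
#'
#' A clade is merged when its crown node is younger than \code{depth}
#' (strictly: crown age < depth; a node exactly at the slice age is not
#' collapsed). The returned tip sets are the maximal such clades plus
#' singletons for tips whose subtending branch crosses the slice alone; they
#' always partition the tip set. \code{depth = 0} returns singletons;
#' \code{depth >= root age} returns one set with all tips.
#'
#' @param tree a rooted ultrametric \code{phylo} (Myr branch lengths).
#' @param depth slice age in Myr, \code{>= 0}.
#' @param tol tolerance used only for the root-age comparison.
#' @return List of character vectors (sorted tip labels), ordered by each
#'   set's first tip's position in the tree.
#' @examples
#' tr <- read_newick("((A:0.5,B:0.5):1.5,C:2);")
#' get_clades(tr, 1)  # list(c("A","B"), "C")
#' @export
get_clades <- function(tree, depth, tol = 1e-8) {
  validate_phylogeny(tree, ultrametric = FALSE)
  if (!is.numeric(depth) || length(depth) != 1L || is.na(depth) || depth < 0)
    stop("'depth' must be a single non-negative age in Myr", call. = FALSE)
  ntip <- length(tree$tip.label)
  singletons <- function() {
    sets <- as.list(tree$tip.label)
    names(sets) <- NULL
    sets
  }
  if (depth == 0) return(singletons())
  ages <- node_ages(tree)
  root <- ntip + 1L
  if (depth >= ages[root] - tol)
    return(list(sort(tree$tip.label)))
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent_of[root] <- root  # sentinel; the root is excluded below
  ids <- seq_len(ntip + tree$Nnode)
  heads <- ids[ids != root &
               ages[ids] < depth & ages[parent_of[ids]] >= depth]
  sets <- clade_tip_sets(tree)[heads]
  # order deterministically by first member's tip index
  first_idx <- vapply(sets, function(s) match(s[1L], tree$tip.label), 0L)
  sets[order(first_idx)]
}

#' Collapse a tree and community at a time depth (taxonomic lumping)
#'
#' Each tip set from \code{\link{get_clades}} becomes a single lumped tip,
#' labelled by its first member (sorted order). The lumped tip's subtending
#' branch extends to the present, so the lumped tree stays ultrametric with
#' the original root height. The lumped range is the union (logical OR) of
#' the member tips' ranges; the grid is unchanged.
#'
#' @param tree a rooted ultrametric \code{phylo}; tip labels must equal the
#'   community's taxon labels.
#' @param comm an \code{endem_comm}.
#' @param depth slice age in Myr, \code{>= 0}.
#' @return An object of class \code{endem_lumping}: \code{depth},
#'   \code{tree} (lumped), \code{comm} (lumped), and \code{tip_map}
#'   (named character: original tip -> lumped tip).
#' @export
collapse_at_depth <- function(tree, comm, depth) {
  stopifnot(is_endem_comm(comm))
  validate_phylogeny(tree, ultrametric = FALSE)
  taxa <- colnames(comm$presence)
  missing_in_comm <- setdiff(tree$tip.label, taxa)
  missing_in_tree <- setdiff(taxa, tree$tip.label)
  if (length(missing_in_comm) || length(missing_in_tree))
    stop(sprintf(
      "tree/community label mismatch: tree-only [%s]; community-only [%s]",
      paste(utils::head(missing_in_comm, 5L), collapse = ", "),
      paste(utils::head(missing_in_tree, 5L), collapse = ", ")),
      call. = FALSE)
  sets <- get_clades(tree, depth)
  reps <- vapply(sets, `[`, character(1L), 1L)
  tip_map <- stats::setNames(rep(reps, lengths(sets)), unlist(sets))
  ntip <- length(tree$tip.label)
  if (length(sets) == ntip) {
    return(structure(list(depth = depth, tree = tree, comm = comm,
                          tip_map = stats::setNames(taxa, taxa)),
                     class = "endem_lumping"))
  }
  if (length(sets) == 1L) {
    h <- root_height(tree)
    ltree <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                            edge.length = h, tip.label = reps,
                            Nnode = 1L), class = "phylo")
  } else {
    ltree <- ape::keep.tip(tree, reps)
  }
  presence2 <- vapply(sets, function(s)
    rowSums(comm$presence[, s, drop = FALSE]) > 0L,
    logical(nrow(comm$presence)))
  colnames(presence2) <- reps
  rownames(presence2) <- rownames(comm$presence)
  structure(list(depth = depth, tree = ltree,
                 comm = new_comm(presence2, comm$grid), tip_map = tip_map),
            class = "endem_lumping")
}

#' @export
print.endem_lumping <- function(x, ...) {
  cat(sprintf("endem_lumping: depth %g Myr, %d -> %d taxa\n",
              x$depth, length(x$tip_map), length(unique(x$tip_map))))
  invisible(x)
}

#' Per-cell median of endemism surfaces across a posterior tree set
#'
#' Integrates over phylogenetic uncertainty by taking, for each grid cell,
#' the median metric value across per-tree surfaces (even counts give the
#' midpoint of the two central values).
#'
#' @param surfaces list of \code{endem_surface} objects sharing one grid,
#'   metric, and cell set.
#' @return A single \code{endem_surface} of per-cell medians.
#' @export
summarize_over_trees <- function(surfaces) {
  if (!is.list(surfaces) || length(surfaces) == 0L)
    stop("'surfaces' must be a non-empty list of endem_surface objects",
         call. = FALSE)
  stopifnot(all(vapply(surfaces, inherits, TRUE, "endem_surface")))
  ref <- surfaces[[1L]]
  for (s in surfaces[-1L]) {
    if (!identical(names(s$values), names(ref$values)) ||
        !identical(s$metric, ref$metric))
      stop("surfaces must share one grid, cell set and metric", call. = FALSE)
    if (!identical(unname(s$occupied), unname(ref$occupied)))
      stop("surfaces disagree on cell occupancy", call. = FALSE)
  }
  mat <- vapply(surfaces, function(s) s$values, numeric(length(ref$values)))
  med <- apply(as.matrix(mat), 1L, stats::median)
  names(med) <- names(ref$values)
  endem_surface(med, ref$occupied, ref$metric, ref$grid,
                config = c(ref$config, list(n_trees = length(surfaces))))
}
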