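#' Simulate a pure-birth (Yule) ultrametric tree
#'
#' Constant-rate birth process: while k lineages are extant the waiting time
#' to the next split is Exponential(k * birth_rate); the splitting lineage is
#' chosen uniformly. The tree is sampled just before the (n+1)-th birth, so
#' with n tips the expected root height is sum_{k=2..n} 1 / (k * birth_rate).
#' All tips end at the present: the tree is ultrametric by construction, with
#' branch lengths in Myr.
#'
#' @param n_tips number of tips, \code{>= 2}.
#' @param birth_rate speciation rate per lineage per Myr. The default 0.05 is
#'   a realistic vertebrate-scale rate: a 100-tip tree has an expected root
#'   height near 84 Myr, so Myr-scale lumping depths are shallow cuts.
#' @param seed integer seed, or \code{NULL} to use the current RNG stream.
#' @param tip_labels optional character vector of tip labels (recycled
#'   default \code{t001, t002, ...}).
#' @return A rooted binary ultrametric \code{phylo}.
#' @examples
#' tr <- simulate_yule_tree(10, birth_rate = 0.1, seed = 1)
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 0.05, seed = NULL,
                               tip_labels = NULL) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L)
    stop("'n_tips' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(birth_rate) || birth_rate <= 0)
    stop("'birth_rate' must be a positive per-Myr rate", call. = FALSE)
  if (is.null(tip_labels))
    tip_labels <- sprintf("t%03d", seq_len(n_tips))
  if (length(tip_labels) != n_tips || anyDuplicated(tip_labels))
    stop("'tip_labels' must be n_tips unique labels", call. = FALSE)
  with_seed(seed, {
    waits <- stats::rexp(n_tips, rate = birth_rate * seq_len(n_tips))
    times <- cumsum(waits)      # event j at times[j]; present after n-th period
    present <- times[n_tips]
    # node bookkeeping: internal nodes in creation order, root first
    parent <- integer(0)        # parent internal id (0 = root)
    btime <- numeric(0)
    new_internal <- function(p, b) {
      parent[length(parent) + 1L] <<- p
      btime[length(btime) + 1L] <<- b
      length(parent)
    }
    root <- new_internal(0L, times[1L])
    active_parent <- c(root, root)
    active_birth <- c(times[1L], times[1L])
    if (n_tips > 2L) {
      for (j in 2:(n_tips - 1L)) {
        i <- sample.int(length(active_parent), 1L)
        v <- new_internal(active_parent[i], times[j])
        active_parent <- c(active_parent[-i], v, v)
        active_birth <- c(active_birth[-i], times[j], times[j])
      }
    }
    # assemble ape edge matrix: tips 1..n, internals n+1 .. 2n-1 (root n+1)
    int_id <- function(k) n_tips + k
    n_int <- n_tips - 1L
    edge <- matrix(0L, 2L * n_tips - 2L, 2L)
    elen <- numeric(2L * n_tips - 2L)
    e <- 0L
    for (k in seq_len(n_int)) {
      if (parent[k] > 0L) {
        e <- e + 1L
        edge[e, ] <- c(int_id(parent[k]), int_id(k))
        elen[e] <- btime[k] - btime[parent[k]]
      }
    }
    for (i in seq_along(active_parent)) {
      e <- e + 1L
      edge[e, ] <- c(int_id(active_parent[i]), i)
      elen[e] <- present - active_birth[i]
    }
    tree <- structure(list(edge = edge, edge.length = elen,
                           tip.label = tip_labels, Nnode = n_int),
                      class = "phylo")
    ape::reorder.phylo(tree, "cladewise")
  })
}

#' Simulate a posterior-like set of trees sharing one tip-label set
#'
#' Independent Yule draws with a common label set stand in for a Bayesian
#' posterior sample: downstream analyses only need topology and
#' branch-length variation across trees.
#'
#' @inheritParams simulate_yule_tree
#' @param n_trees number of trees.
#' @return List of \code{phylo} objects with identical tip labels.
#' @export
simulate_posterior_trees <- function(n_tips, n_trees, birth_rate = 0.05,
                                     seed = NULL) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L)
    stop("'n_trees' must be an integer >= 1", call. = FALSE)
  seeds <- derive_seeds(seed, n_trees)
  labels <- sprintf("t%03d", seq_len(n_tips))
  lapply(seeds, function(s)
    simulate_yule_tree(n_tips, birth_rate, seed = s, tip_labels = labels))
}

# spreading-dye growth of one contiguous range of `size` cells
spread_range <- function(grid, size) {
  n <- n_cells(grid)
  in_set <- logical(n)
  start <- sample.int(n, 1L) - 1L
  in_set[start + 1L] <- TRUE
  frontier <- setdiff(rook_neighbours(grid, start), start)
  while (sum(in_set) < size) {
    frontier <- frontier[!in_set[frontier + 1L]]
    if (!length(frontier)) break  # whole grid filled
    pick <- frontier[sample.int(length(frontier), 1L)]
    in_set[pick + 1L] <- TRUE
    frontier <- c(frontier[frontier != pick],
                  rook_neighbours(grid, pick))
  }
  which(in_set) - 1L
}

#' Simulate contiguous species ranges (spreading-dye model)
#'
#' Range sizes are drawn from a right-skewed lognormal (meanlog chosen so the
#' untruncated mean equals \code{mean_range}; \code{skew} is the sdlog shape
#' parameter), rounded and truncated to [1, n_cells] — many small-ranged and
#' few widespread taxa, the structure that makes endemism non-trivial. Each
#' range is grown from a uniformly chosen seed cell over the rook-adjacency
#' graph, so every range is a contiguous cell set.
#'
#' @param grid an \code{\link{endem_grid}} with at least one cell.
#' @param taxa character vector of taxon labels, or a \code{phylo} whose tip
#'   labels are used.
#' @param mean_range target mean range size in cells (>= 1, <= n_cells).
#' @param skew lognormal sdlog; larger = heavier right tail.
#' @param seed integer seed or \code{NULL}.
#' @return Named list: taxon -> integer vector of 0-based cell ids.
#' @export
simulate_ranges <- function(grid, taxa, mean_range = 6, skew = 1,
                            seed = NULL) {
  stopifnot(is_endem_grid(grid))
  if (inherits(taxa, "phylo")) taxa <- taxa$tip.label
  if (!length(taxa)) stop("no taxa given", call. = FALSE)
  n <- n_cells(grid)
  if (n < 1L) stop("empty grid", call. = FALSE)
  if (mean_range < 1 || mean_range > n)
    stop("'mean_range' must lie in [1, n_cells]", call. = FALSE)
  with_seed(seed, {
    sizes <- stats::rlnorm(length(taxa),
                           meanlog = log(mean_range) - skew^2 / 2,
                           sdlog = skew)
    sizes <- pmin(pmax(round(sizes), 1), n)
    out <- lapply(sizes, function(s) spread_range(grid, s))
    names(out) <- taxa
    out
  })
}

# separable Gaussian smoothing with edge renormalisation
smooth_matrix <- function(z, len) {
  if (len <= 0) return(z)
  r <- max(1L, ceiling(3 * len))
  kern <- stats::dnorm(seq(-r, r), sd = len)
  conv1 <- function(mat) {
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      w <- kern[j - i + r + 1L]
      out[i, ] <- crossprod(w, mat[j, , drop = FALSE]) / sum(w)
    }
    out
  }
  z <- conv1(z)
  t(conv1(t(z)))
}

#' Simulate fine-resolution environmental layers
#'
#' Four layers (temperature, precipitation, productivity, elevation), each a
#' value per subcell of a k x k block inside every grid cell — emulating
#' fine rasters inside coarse analysis cells, whose within-cell standard
#' deviation is the heterogeneity predictor. Each layer is an independent
#' realization of smoothed Gaussian noise (Gaussian kernel with standard
#' deviation \code{autocorr_length} cells) plus a latitudinal gradient
#' (elevation carries no gradient). \code{autocorr_length = Inf} yields a
#' spatially constant layer (the zero-heterogeneity limit).
#'
#' @param grid an \code{\link{endem_grid}}.
#' @param subcells_per_cell perfect square >= 4; each cell holds a
#'   sqrt(subcells_per_cell)^2 block of subcells.
#' @param autocorr_length smoothing length in units of grid cells.
#' @param seed integer seed or \code{NULL}.
#' @return Object of class \code{endem_env}: \code{values} (data frame with
#'   fine-lattice coordinates \code{frow}, \code{fcol} and the four layers),
#'   \code{k}, and the base \code{grid}.
#' @export
simulate_environment <- function(grid, subcells_per_cell = 16,
                                 autocorr_length = 2, seed = NULL) {
  stopifnot(is_endem_grid(grid))
  k <- sqrt(subcells_per_cell)
  if (subcells_per_cell < 4 || k != round(k))
    stop("'subcells_per_cell' must be a perfect square >= 4", call. = FALSE)
  k <- as.integer(round(k))
  FR <- grid$n_rows * k
  FC <- grid$n_cols * k
  lat <- (matrix(rep(seq_len(FR), FC), FR, FC) - 0.5) / FR * 2 - 1  # -1..1 S->N
  layer_specs <- list(
    temperature   = list(mean = 15,   grad = -12,  noise = 3),
    precipitation = list(mean = 1200, grad = -500, noise = 400),
    productivity  = list(mean = 0.8,  grad = -0.5, noise = 0.25),
    elevation     = list(mean = 600,  grad = 0,    noise = 450)
  )
  with_seed(seed, {
    vals <- lapply(layer_specs, function(sp) {
      if (is.infinite(autocorr_length)) {
        field <- matrix(sp$mean + sp$noise * stats::rnorm(1L), FR, FC)
      } else {
        noise <- smooth_matrix(matrix(stats::rnorm(FR * FC), FR, FC),
                               autocorr_length * k)
        noise <- noise / stats::sd(noise)
        field <- sp$mean + sp$grad * lat + sp$noise * noise
      }
      as.vector(field)  # column-major: frow fastest
    })
    values <- data.frame(
      frow = rep(seq_len(FR), FC) - 1L,
      fcol = rep(seq_len(FC), each = FR) - 1L
    )
    for (nm in names(vals)) values[[nm]] <- vals[[nm]]
    structure(list(values = values, k = k, grid = grid),
              class = "endem_env")
  })
}

# round-robin contiguous growth of n_regions over a cell subset
grow_regions <- function(grid, cells, n_regions, labels) {
  pos <- match(cells, grid$cells$cell)
  in_subset <- logical(n_cells(grid))
  in_subset[pos] <- TRUE
  assign <- rep(NA_integer_, n_cells(grid))
  seeds <- cells[sample.int(length(cells), n_regions)]
  assign[seeds + 1L] <- seq_len(n_regions)
  frontiers <- lapply(seeds, function(s) {
    nb <- rook_neighbours(grid, s)
    nb[in_subset[nb + 1L]]
  })
  remaining <- length(cells) - n_regions
  while (remaining > 0L) {
    progressed <- FALSE
    for (g in seq_len(n_regions)) {
      fr <- frontiers[[g]]
      fr <- fr[is.na(assign[fr + 1L])]
      frontiers[[g]] <- fr
      if (!length(fr)) next
      pick <- fr[sample.int(length(fr), 1L)]
      assign[pick + 1L] <- g
      remaining <- remaining - 1L
      nb <- rook_neighbours(grid, pick)
      frontiers[[g]] <- c(fr[fr != pick], nb[in_subset[nb + 1L]])
      progressed <- TRUE
      if (remaining == 0L) break
    }
    if (!progressed)
      stop("region growth stalled; cell subset not connected", call. = FALSE)
  }
  stats::setNames(labels[assign[cells + 1L]], as.character(cells))
}

#' Partition the grid into contiguous continents and nested countries
#'
#' Continents are grown from random seed cells by round-robin spreading-dye
#' expansion (so each is contiguous on rook adjacency); countries are grown
#' the same way within each continent. Every cell gets exactly one continent
#' and one country label, and countries nest within continents.
#'
#' @param grid an \code{\link{endem_grid}}.
#' @param n_continents number of continents, >= 1.
#' @param countries_per_continent number of countries inside each continent.
#' @param seed integer seed or \code{NULL}.
#' @return Data frame with columns \code{cell}, \code{continent} (labels
#'   \code{C1, C2, ...}) and \code{country} (\code{C1_1, C1_2, ...}).
#' @export
partition_regions <- function(grid, n_continents = 2,
                              countries_per_continent = 2, seed = NULL) {
  stopifnot(is_endem_grid(grid))
  n_continents <- as.integer(n_continents)
  countries_per_continent <- as.integer(countries_per_continent)
  if (n_continents < 1L || countries_per_continent < 1L)
    stop("region counts must be >= 1", call. = FALSE)
  if (n_continents * countries_per_continent > n_cells(grid))
    stop("more regions than grid cells", call. = FALSE)
  with_seed(seed, {
    all_cells <- grid$cells$cell
    cont <- grow_regions(grid, all_cells, n_continents,
                         paste0("C", seq_len(n_continents)))
    country <- character(length(all_cells))
    names(country) <- as.character(all_cells)
    for (cl in unique(cont)) {
      sub <- all_cells[cont == cl]
      if (length(sub) < countries_per_continent)
        stop(sprintf("continent %s has %d cells, fewer than %d countries",
                     cl, length(sub), countries_per_continent), call. = FALSE)
      country[as.character(sub)] <-
        grow_regions(grid, sub, countries_per_continent,
                     paste0(cl, "_", seq_len(countries_per_continent)))
    }
    data.frame(cell = all_cells,
               continent = unname(cont[as.character(all_cells)]),
               country = unname(country[as.character(all_cells)]))
  })
}

#' Simulate a patchy protected-area layer
#'
#' Per-cell protected fractions are independent Beta draws with mean
#' \code{mean_coverage} and first shape parameter \code{patchiness}; small
#' \code{patchiness} gives a right-skewed layer with most cells near zero
#' coverage, mirroring the sparse, uneven footprint of real protected-area
#' networks.
#'
#' @param grid an \code{\link{endem_grid}}.
#' @param mean_coverage target grid-wide mean protected fraction in [0, 1].
#'   The default 0.15 is close to the global terrestrial protected fraction.
#' @param patchiness Beta shape-1 parameter; smaller = patchier.
#' @param seed integer seed or \code{NULL}.
#' @return Named numeric vector over cell ids: protected fraction in [0, 1].
#' @export
simulate_protection <- function(grid, mean_coverage = 0.15, patchiness = 0.5,
                                seed = NULL) {
  stopifnot(is_endem_grid(grid))
  if (!is.numeric(mean_coverage) || mean_coverage < 0 || mean_coverage > 1)
    stop("'mean_coverage' must lie in [0, 1]", call. = FALSE)
  n <- n_cells(grid)
  ids <- as.character(grid$cells$cell)
  if (mean_coverage == 0) return(stats::setNames(rep(0, n), ids))
  if (mean_coverage == 1) return(stats::setNames(rep(1, n), ids))
  with_seed(seed, {
    a <- patchiness
    b <- a * (1 - mean_coverage) / mean_coverage
    stats::setNames(stats::rbeta(n, a, b), ids)
  })
}

#' Simulate a complete synthetic world
#'
#' Bundles a grid, a posterior-like tree set, contiguous ranges, fine
#' environmental layers, a nested continent/country partition, and a patchy
#' protection layer — everything the scale-dependence pipeline consumes.
#' Identical seeds give identical worlds.
#'
#' @param n_rows,n_cols,grain grid shape (see \code{\link{endem_grid}}).
#' @param n_taxa number of taxa (tree tips).
#' @param n_trees number of posterior trees.
#' @param birth_rate Yule speciation rate per Myr.
#' @param mean_range,skew range-size law (see \code{\link{simulate_ranges}}).
#' @param n_continents,countries_per_continent region partition.
#' @param subcells_per_cell,autocorr_length environment generator.
#' @param mean_coverage,patchiness protection generator.
#' @param seed integer seed.
#' @return Object of class \code{endem_world} with elements \code{grid},
#'   \code{trees}, \code{ranges}, \code{env}, \code{regions},
#'   \code{protection}, \code{params}, \code{seed}.
#' @export
simulate_world <- function(n_rows = 10, n_cols = 10, grain = 100,
                           n_taxa = 40, n_trees = 10, birth_rate = 0.05,
                           mean_range = 6, skew = 1,
                           n_continents = 2, countries_per_continent = 2,
                           subcells_per_cell = 16, autocorr_length = 2,
                           mean_coverage = 0.15, patchiness = 0.5,
                           seed = NULL) {
  params <- list(n_rows = n_rows, n_cols = n_cols, grain = grain,
                 n_taxa = n_taxa, n_trees = n_trees, birth_rate = birth_rate,
                 mean_range = mean_range, skew = skew,
                 n_continents = n_continents,
                 countries_per_continent = countries_per_continent,
                 subcells_per_cell = subcells_per_cell,
                 autocorr_length = autocorr_length,
                 mean_coverage = mean_coverage, patchiness = patchiness)
  seeds <- derive_seeds(seed, 5L)
  grid <- endem_grid(n_rows, n_cols, grain)
  trees <- simulate_posterior_trees(n_taxa, n_trees, birth_rate,
                                    seed = seeds[[1]])
  ranges <- simulate_ranges(grid, trees[[1]], mean_range, skew,
                            seed = seeds[[2]])
  env <- simulate_environment(grid, subcells_per_cell, autocorr_length,
                              seed = seeds[[3]])
  regions <- partition_regions(grid, n_continents, countries_per_continent,
                               seed = seeds[[4]])
  protection <- simulate_protection(grid, mean_coverage, patchiness,
                                    seed = seeds[[5]])
  world <- structure(list(grid = grid, trees = trees, ranges = ranges,
                          env = env, regions = regions,
                          protection = protection,
                          params = params, seed = seed),
                     class = "endem_world")
  validate_world(world)
  world
}

#' Validate the cross-reference invariants of a synthetic world
#'
#' Checks that every taxon in the ranges is a tip of every tree and vice
#' versa, and that every cell referenced by ranges, regions, environment and
#' protection exists in the grid.
#'
#' @param world an \code{endem_world}.
#' @return \code{TRUE} invisibly; errors otherwise.
#' @export
validate_world <- function(world) {
  stopifnot(inherits(world, "endem_world"))
  taxa <- names(world$ranges)
  for (tr in world$trees)
    if (!setequal(tr$tip.label, taxa))
      stop("tree tip labels do not match range taxa", call. = FALSE)
  cells <- world$grid$cells$cell
  if (!all(unlist(world$ranges) %in% cells))
    stop("range cell outside grid", call. = FALSE)
  if (!setequal(world$regions$cell, cells))
    stop("region labels do not cover the grid exactly", call. = FALSE)
  if (!setequal(as.integer(names(world$protection)), cells))
    stop("protection layer does not cover the grid exactly", call. = FALSE)
  k <- world$env$k
  if (nrow(world$env$values) != length(cells) * k^2)
    stop("environment subcell count does not match grid", call. = FALSE)
  if (any(lengths(world$ranges) < 1L))
    stop("every taxon must occupy at least one cell", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.endem_world <- function(x, ...) {
  cat(sprintf(
    "endem_world: %d x %d grid (grain %g km), %d taxa, %d trees, %d continents, seed %s\n",
    x$grid$n_rows, x$grid$n_cols, x$grid$grain,
    length(x$ranges), length(x$trees),
    length(unique(x$regions$continent)),
    if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}
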