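#' Aggregate region labels to a coarser grain (centroid rule)
#'
#' Each coarse cell takes the labels of the fine cell containing its
#' centroid; for even factors the centroid falls on a fine-cell corner and
#' the tie is broken to the north-east fine cell, deterministically.
#'
#' @param regions data frame \code{cell}, \code{continent}, \code{country}.
#' @param grid the fine \code{endem_grid} the labels refer to.
#' @param factor integer aggregation factor >= 2.
#' @return Region data frame on the coarse grid.
#' @export
aggregate_regions <- function(regions, grid, factor) {
  factor <- as.integer(factor)
  grid2 <- suppressWarnings(aggregate_grid(grid, factor))
  R <- grid2$cells$row
  C <- grid2$cells$col
  fine <- (R * factor + factor %/% 2L) * grid$n_cols +
    (C * factor + factor %/% 2L)
  i <- match(fine, regions$cell)
  data.frame(cell = grid2$cells$cell,
             continent = regions$continent[i],
             country = regions$country[i])
}

#' Aggregate a protection layer to a coarser grain
#'
#' The coarse protected fraction is the mean of the block's fine fractions
#' (cells are equal-area, so this is the area-weighted overlap fraction).
#'
#' @param protection named numeric vector over fine cell ids.
#' @param grid the fine \code{endem_grid}.
#' @param factor integer aggregation factor >= 2.
#' @return Named numeric vector over coarse cell ids.
#' @export
aggregate_protection <- function(protection, grid, factor) {
  idx <- coarse_index(grid, factor)
  keep <- !is.na(idx)
  v <- protection[as.character(grid$cells$cell)][keep]
  agg <- tapply(v, idx[keep], mean)
  stats::setNames(as.numeric(agg), names(agg))
}

# median WE surface across trees at one lumping depth
median_we_surface <- function(comm, trees, depth) {
  surfaces <- lapply(trees, function(tr)
    weighted_endemism(collapse_at_depth(tr, comm, depth)$comm))
  summarize_over_trees(surfaces)
}

# median PE surface across trees at one extent ("global" or a continent)
median_pe_surface <- function(comm, trees, regions = NULL, extent = "global") {
  if (identical(extent, "global")) {
    surfaces <- lapply(trees, function(tr) phylo_endemism(comm, tr))
  } else {
    rcomm <- restrict_extent(comm, regions, extent, level = "continent")
    surfaces <- lapply(trees, function(tr)
      phylo_endemism(rcomm, tr, absent_tips = "zero"))
  }
  summarize_over_trees(surfaces)
}

#' Run the full factorial scale experiment on a world
#'
#' For every combination of grain (aggregation factor), metric, lumping depth
#' (WE branch), extent (PE branch) and hotspot threshold: build the community
#' at that grain, compute per-tree surfaces, take per-cell medians across the
#' posterior set, detect hotspots, and score their protected-area coverage.
#' A failing configuration point is logged and skipped; the rest proceed.
#'
#' @param world an \code{endem_world} (or a list with the same elements built
#'   from user data).
#' @param grains integer aggregation factors relative to the world's base
#'   grid; 1 = base grain.
#' @param depths lumping depths in Myr for the WE branch.
#' @param probs hotspot percentages.
#' @param extents \code{"auto"} (global plus every continent) or an explicit
#'   character vector containing \code{"global"} and/or continent labels.
#' @param target protected-fraction target for the gap analysis.
#' @param fit_models also fit, per grain, the heterogeneity mixed model to
#'   the depth-0 global WE surface; coefficient tables are stored in
#'   \code{attr(result, "models")}.
#' @return A long-format data frame, one row per realized configuration:
#'   metric, grain_km, extent, lump_depth, prob, n_occupied,
#'   n_hotspot_cells, threshold, prop_protected, n_meeting_target,
#'   hotspot_cells (comma-separated ids). A run manifest (seed, parameters,
#'   failures, package version) is attached as \code{attr(result,
#'   "manifest")}.
#' @export
run_scale_experiment <- function(world, grains = c(1, 2), depths = 0:5,
                                 probs = c(2.5, 5), extents = "auto",
                                 target = 0.10, fit_models = FALSE) {
  stopifnot(inherits(world, "endem_world") || is.list(world))
  comm0 <- ranges_to_community(world$ranges, world$grid)
  if (identical(extents, "auto"))
    extents <- c("global", sort(unique(world$regions$continent)))
  rows <- list()
  models <- list()
  failures <- character(0)
  note <- function(msg) message("[endemscale] ", msg)
  for (f in grains) {
    if (f == 1) {
      comm <- comm0
      regions <- world$regions
      protection <- world$protection
      grid <- world$grid
    } else {
      comm <- aggregate_grain(comm0, f)
      regions <- aggregate_regions(world$regions, world$grid, f)
      protection <- aggregate_protection(world$protection, world$grid, f)
      grid <- comm$grid
    }
    grain_km <- grid$grain
    note(sprintf("grain %g km (%d cells)", grain_km, n_cells(grid)))
    # WE branch: lumping depths at global extent
    for (depth in depths) {
      res <- tryCatch({
        surf <- median_we_surface(comm, world$trees, depth)
        lapply(probs, function(p) {
          mask <- hotspots(surf, p)
          rep_ <- protection_coverage(mask, protection, target)
          data.frame(metric = "WE", grain_km = grain_km, extent = "global",
                     lump_depth = depth, prob = p,
                     n_occupied = sum(surf$occupied),
                     n_hotspot_cells = rep_$n_hotspot_cells,
                     threshold = mask$threshold,
                     prop_protected = rep_$proportion_meeting_target,
                     n_meeting_target = rep_$n_meeting_target,
                     hotspot_cells = paste(mask$hotspot_cells, collapse = ";"))
        })
      }, error = function(e) {
        failures <<- c(failures,
                       sprintf("WE grain=%g depth=%g: %s", grain_km, depth,
                               conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) rows <- c(rows, res)
    }
    # PE branch: spatial extents at depth 0
    for (ext in extents) {
      res <- tryCatch({
        surf <- median_pe_surface(comm, world$trees, regions, ext)
        lapply(probs, function(p) {
          mask <- hotspots(surf, p)
          rep_ <- protection_coverage(mask, protection, target)
          data.frame(metric = "PE", grain_km = grain_km, extent = ext,
                     lump_depth = 0, prob = p,
                     n_occupied = sum(surf$occupied),
                     n_hotspot_cells = rep_$n_hotspot_cells,
                     threshold = mask$threshold,
                     prop_protected = rep_$proportion_meeting_target,
                     n_meeting_target = rep_$n_meeting_target,
                     hotspot_cells = paste(mask$hotspot_cells, collapse = ";"))
        })
      }, error = function(e) {
        failures <<- c(failures,
                       sprintf("PE grain=%g extent=%s: %s", grain_km, ext,
                               conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) rows <- c(rows, res)
    }
    if (fit_models) {
      mres <- tryCatch({
        surf <- median_we_surface(comm, world$trees, 0)
        het <- env_heterogeneity(world$env, factor = f)
        md <- assemble_model_data(surf, het, regions)
        fit <- fit_endemism_model(md)
        cbind(grain_km = grain_km, fit$coefficients)
      }, error = function(e) {
        failures <<- c(failures, sprintf("model grain=%g: %s", grain_km,
                                         conditionMessage(e)))
        NULL
      })
      if (!is.null(mres)) models[[as.character(grain_km)]] <- mres
    }
  }
  if (!length(rows))
    stop("every configuration point failed; see messages", call. = FALSE)
  result <- do.call(rbind, rows)
  rownames(result) <- NULL
  attr(result, "manifest") <- list(
    seed = if (!is.null(world$seed)) world$seed else NA,
    params = world$params %||% list(),
    grains = grains, depths = depths, probs = probs, extents = extents,
    target = target, n_trees = length(world$trees),
    failures = failures,
    package = "endemscale",
    version = as.character(utils::packageVersion("endemscale"))
  )
  if (length(models))
    attr(result, "models") <- do.call(rbind, c(models, make.row.names = FALSE))
  if (length(failures))
    note(sprintf("%d configuration point(s) failed", length(failures)))
  result
}

#' Write an experiment result with its manifest
#'
#' Writes \code{results.csv}, \code{manifest.json}, and (when model fits are
#' attached) \code{models.csv} into \code{dir}. Tables are written via a
#' temporary file and renamed, so a partial write never masquerades as a
#' finished one. No timestamps are recorded: identical runs are
#' byte-identical.
#'
#' @param result the data frame from \code{\link{run_scale_experiment}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atomically <- function(write_fun, path) {
    tmp <- paste0(path, ".tmp")
    write_fun(tmp)
    file.rename(tmp, path)
  }
  atomically(function(p) utils::write.csv(result, p, row.names = FALSE),
             file.path(dir, "results.csv"))
  manifest <- attr(result, "manifest")
  atomically(function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                                              digits = NA, pretty = TRUE),
             file.path(dir, "manifest.json"))
  models <- attr(result, "models")
  if (!is.null(models))
    atomically(function(p) utils::write.csv(models, p, row.names = FALSE),
               file.path(dir, "models.csv"))
  invisible(dir)
}
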