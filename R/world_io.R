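#' Write a synthetic world to a directory of plain-text files
#'
#' Layout: \code{trees.nwk} (one Newick per line), \code{ranges.csv}
#' (long table \code{species,cell}), \code{environment.csv} (fine-lattice
#' \code{frow,fcol} plus the four layers), \code{regions.csv},
#' \code{protection.csv}, and \code{manifest.json} recording the seed and
#' generator parameters.
#'
#' @param world an \code{endem_world}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "endem_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(world$trees, file.path(dir, "trees.nwk"))
  ranges <- data.frame(
    species = rep(names(world$ranges), lengths(world$ranges)),
    cell = unlist(world$ranges, use.names = FALSE)
  )
  utils::write.csv(ranges, file.path(dir, "ranges.csv"), row.names = FALSE)
  utils::write.csv(world$env$values, file.path(dir, "environment.csv"),
                   row.names = FALSE)
  utils::write.csv(world$regions, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(cell = as.integer(names(world$protection)),
               protected_fraction = unname(world$protection)),
    file.path(dir, "protection.csv"), row.names = FALSE)
  manifest <- c(world$params,
                list(seed = world$seed %||% NA,
                     k = world$env$k,
                     package = "endemscale",
                     version = as.character(utils::packageVersion("endemscale"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic world back from a directory
#'
#' Inverse of \code{\link{write_world}}; the grid is rebuilt from the
#' manifest's dimensions and grain.
#'
#' @param dir directory written by \code{\link{write_world}}.
#' @return An \code{endem_world}.
#' @export
read_world <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  grid <- endem_grid(manifest$n_rows, manifest$n_cols, manifest$grain)
  trees <- read_newick_set(file.path(dir, "trees.nwk"))
  rtab <- utils::read.csv(file.path(dir, "ranges.csv"))
  ranges <- split(as.integer(rtab$cell), rtab$species)
  env_values <- utils::read.csv(file.path(dir, "environment.csv"))
  env <- structure(list(values = env_values, k = as.integer(manifest$k),
                        grid = grid), class = "endem_env")
  regions <- utils::read.csv(file.path(dir, "regions.csv"))
  ptab <- utils::read.csv(file.path(dir, "protection.csv"))
  protection <- stats::setNames(ptab$protected_fraction,
                                as.character(ptab$cell))
  seed <- manifest$seed
  if (is.null(seed) || is.na(seed)) seed <- NULL
  params <- manifest[setdiff(names(manifest),
                             c("seed", "k", "package", "version"))]
  world <- structure(list(grid = grid, trees = trees, ranges = ranges,
                          env = env, regions = regions,
                          protection = protection,
                          params = params, seed = seed),
                     class = "endem_world")
  validate_world(world)
  world
}
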