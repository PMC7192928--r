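#' Percentile hotspots of an endemism surface
#'
#' Hotspots are the \code{prob}\% of cells with the highest metric values:
#' the threshold is the (100 - prob)-th percentile (linear-interpolation
#' quantile, \code{type = 7}) of the values over occupied cells, and every
#' cell with value >= threshold is included — ties at the threshold are all
#' kept, so the hotspot fraction can exceed \code{prob}\% under ties.
#' Quantiles are computed over occupied cells only by default, so structural
#' zeros (empty ocean cells) do not shift the threshold.
#'
#' @param surface an \code{\link{endem_surface}}.
#' @param prob hotspot percentage in (0, 50); the conventional thresholds
#'   are 2.5 and 5.
#' @param include_empty include unoccupied cells in the threshold quantile
#'   and candidate set (documented switch; default \code{FALSE}).
#' @return An object of class \code{endem_hotspots}: \code{hotspot_cells}
#'   (character cell ids), \code{eval_cells}, \code{threshold}, \code{prob},
#'   \code{metric}, \code{grid}.
#' @export
hotspots <- function(surface, prob = 2.5, include_empty = FALSE) {
  stopifnot(inherits(surface, "endem_surface"))
  if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob >= 50)
    stop("'prob' must be a percentage in (0, 50)", call. = FALSE)
  v <- surface$values
  occ <- if (include_empty) rep(TRUE, length(v)) else surface$occupied
  if (!any(occ))
    stop("surface has no occupied cells", call. = FALSE)
  threshold <- stats::quantile(v[occ], 1 - prob / 100, names = FALSE, type = 7)
  hot <- occ & v >= threshold
  structure(list(hotspot_cells = names(v)[hot],
                 eval_cells = names(v)[occ],
                 threshold = threshold, prob = prob,
                 metric = surface$metric, grid = surface$grid),
            class = "endem_hotspots")
}

#' @export
print.endem_hotspots <- function(x, ...) {
  cat(sprintf("endem_hotspots [%s]: %d of %d cells at prob %g%% (threshold %.4g)\n",
              x$metric, length(x$hotspot_cells), length(x$eval_cells),
              x$prob, x$threshold))
  invisible(x)
}

#' Two-tier hotspot classification (top 2.5\% within top 5\%)
#'
#' @param surface an \code{endem_surface}.
#' @param probs increasing pair of percentages; default \code{c(2.5, 5)}.
#' @param include_empty see \code{\link{hotspots}}.
#' @return Data frame with columns \code{cell} and \code{tier}, a factor with
#'   levels \code{none}, \code{top5}, \code{top2.5}; the top2.5 cells are a
#'   subset of the top5 cells by construction.
#' @export
hotspot_tiers <- function(surface, probs = c(2.5, 5), include_empty = FALSE) {
  stopifnot(length(probs) == 2L, probs[1] < probs[2])
  inner <- hotspots(surface, probs[1], include_empty)
  outer <- hotspots(surface, probs[2], include_empty)
  cells <- outer$eval_cells
  tier <- rep("none", length(cells))
  tier[cells %in% outer$hotspot_cells] <- "top5"
  tier[cells %in% inner$hotspot_cells] <- "top2.5"
  data.frame(cell = cells,
             tier = factor(tier, levels = c("none", "top5", "top2.5")))
}

#' Protected-area coverage of hotspot cells
#'
#' A hotspot cell meets the protection target when its protected fraction is
#' at least \code{target} (the conventional minimum is 10\% coverage).
#'
#' @param mask an \code{\link{endem_hotspots}} object.
#' @param protection named numeric vector over cell ids: protected fraction
#'   of each cell, in [0, 1].
#' @param target minimum protected fraction, default 0.10.
#' @return An object of class \code{endem_protection_report}:
#'   \code{n_hotspot_cells}, \code{n_meeting_target},
#'   \code{proportion_meeting_target}, \code{target}, \code{prob},
#'   \code{threshold}.
#' @examples
#' # fractions (0.05, 0.10, 0.2, 0.0) against a 10% target -> proportion 0.5
#' @export
protection_coverage <- function(mask, protection, target = 0.10) {
  stopifnot(inherits(mask, "endem_hotspots"))
  if (!is.numeric(target) || target < 0 || target > 1)
    stop("'target' must be a fraction in [0, 1]", call. = FALSE)
  if (is.null(names(protection)) ||
      !all(mask$eval_cells %in% names(protection)))
    stop("protection layer does not cover the hotspot grid", call. = FALSE)
  if (any(protection < 0 | protection > 1))
    stop("protected fractions must lie in [0, 1]", call. = FALSE)
  frac <- protection[mask$hotspot_cells]
  n <- length(frac)
  meet <- sum(frac >= target)
  structure(list(n_hotspot_cells = n, n_meeting_target = meet,
                 proportion_meeting_target = if (n > 0L) meet / n else NA_real_,
                 target = target, prob = mask$prob,
                 threshold = mask$threshold),
            class = "endem_protection_report")
}

#' @export
print.endem_protection_report <- function(x, ...) {
  cat(sprintf(
    "endem_protection_report: %d/%d hotspot cells (%.1f%%) meet the %g%% coverage target\n",
    x$n_meeting_target, x$n_hotspot_cells,
    100 * x$proportion_meeting_target, 100 * x$target))
  invisible(x)
}
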