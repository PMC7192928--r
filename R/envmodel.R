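#' Per-cell environmental heterogeneity (within-cell standard deviations)
#'
#' Heterogeneity of each layer is the sample standard deviation (denominator
#' n - 1) of the subcell values inside each analysis cell. With
#' \code{factor > 1} the subcells of each \code{factor} x \code{factor} block
#' of base cells are pooled first, giving the heterogeneity of the coarser
#' grain directly (trailing rows/columns not divisible by the factor are
#' dropped, mirroring \code{\link{aggregate_grid}}).
#'
#' @param env an \code{endem_env} from \code{\link{simulate_environment}} (or
#'   any object with the same structure).
#' @param factor integer grain aggregation factor (1 = the base grid).
#' @return Data frame keyed by \code{cell} (0-based id on the grain's grid)
#'   with columns \code{temperature}, \code{precipitation},
#'   \code{productivity}, \code{elevation}: the per-cell SDs.
#' @export
env_heterogeneity <- function(env, factor = 1) {
  stopifnot(inherits(env, "endem_env"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("'factor' must be an integer >= 1", call. = FALSE)
  k <- env$k
  grid <- env$grid
  block <- k * factor
  nr2 <- grid$n_rows %/% factor
  nc2 <- grid$n_cols %/% factor
  fr <- env$values$frow
  fc <- env$values$fcol
  keep <- fr < nr2 * block & fc < nc2 * block
  cell <- (fr[keep] %/% block) * nc2 + fc[keep] %/% block
  counts <- table(cell)
  if (any(counts < 2L))
    stop(sprintf("cell %s has fewer than 2 subcells",
                 names(counts)[counts < 2L][1L]), call. = FALSE)
  layers <- c("temperature", "precipitation", "productivity", "elevation")
  out <- data.frame(cell = sort(unique(cell)))
  for (nm in layers)
    out[[nm]] <- as.numeric(tapply(env$values[[nm]][keep], cell, stats::sd))
  out
}

#' Spatial autocovariate of a response surface
#'
#' For each cell, the weighted mean of the response over its lattice
#' neighbours within the chosen order: order 1 is the 4 rook neighbours,
#' order 2 adds the next ring (all cells at Manhattan distance 2; 12
#' neighbours for an interior cell). Weights are inverse centroid distance
#' or equal. Edge cells use their existing neighbours only; a cell with no
#' neighbours gets 0 with a warning. Computed once from the response itself
#' (an autoregressive covariate), not iterated.
#'
#' @param x an \code{endem_surface}, or a named numeric vector over cell ids.
#' @param grid the \code{\link{endem_grid}} the cells belong to (taken from
#'   the surface when \code{x} is one).
#' @param order neighbourhood order, 1 or 2 (Manhattan radius).
#' @param weighting "inverse" (1 / centroid distance) or "equal".
#' @return Named numeric vector over the same cells.
#' @export
spatial_autocovariate <- function(x, grid = NULL, order = 1,
                                  weighting = c("inverse", "equal")) {
  weighting <- match.arg(weighting)
  if (inherits(x, "endem_surface")) {
    grid <- x$grid
    x <- x$values
  }
  stopifnot(is_endem_grid(grid), is.numeric(x), !is.null(names(x)))
  if (!order %in% c(1, 2))
    stop("'order' must be 1 or 2", call. = FALSE)
  ids <- as.integer(names(x))
  r <- ids %/% grid$n_cols
  c <- ids %% grid$n_cols
  out <- numeric(length(x))
  warned <- FALSE
  for (i in seq_along(x)) {
    d <- abs(r - r[i]) + abs(c - c[i])
    nb <- which(d > 0L & d <= order)
    if (!length(nb)) {
      if (!warned) {
        warning("cell(s) with no neighbours get autocovariate 0",
                call. = FALSE)
        warned <- TRUE
      }
      out[i] <- 0
      next
    }
    w <- if (weighting == "equal") rep(1, length(nb)) else {
      dist <- sqrt((r[nb] - r[i])^2 + (c[nb] - c[i])^2) * grid$grain
      1 / dist
    }
    out[i] <- sum(w * x[nb]) / sum(w)
  }
  names(out) <- names(x)
  out
}

#' Assemble the endemism-heterogeneity model frame
#'
#' One row per occupied cell: the endemism response, the four heterogeneity
#' predictors at the surface's grain, the spatial autocovariate of the
#' response, and the cell's continent label.
#'
#' @param surface an \code{endem_surface} on the same grid/grain as
#'   \code{het}.
#' @param het heterogeneity table from \code{\link{env_heterogeneity}} at the
#'   matching grain.
#' @param regions region labels at the matching grain.
#' @param order,weighting passed to \code{\link{spatial_autocovariate}}.
#' @return Data frame with columns \code{cell}, \code{endemism},
#'   \code{temperature}, \code{precipitation}, \code{productivity},
#'   \code{elevation}, \code{autocov}, \code{continent}.
#' @export
assemble_model_data <- function(surface, het, regions, order = 1,
                                weighting = "inverse") {
  stopifnot(inherits(surface, "endem_surface"))
  autocov <- spatial_autocovariate(surface, order = order,
                                   weighting = weighting)
  occ <- surface$occupied
  cells <- as.integer(names(surface$values)[occ])
  hi <- match(cells, het$cell)
  ri <- match(cells, regions$cell)
  if (anyNA(hi) || anyNA(ri))
    stop("heterogeneity table or regions do not cover the occupied cells",
         call. = FALSE)
  data.frame(cell = cells,
             endemism = unname(surface$values[occ]),
             temperature = het$temperature[hi],
             precipitation = het$precipitation[hi],
             productivity = het$productivity[hi],
             elevation = het$elevation[hi],
             autocov = unname(autocov[occ]),
             continent = regions$continent[ri])
}

#' Fit the endemism-heterogeneity linear mixed model
#'
#' Fits Y = X beta + s + e with a random intercept per continent by maximum
#' likelihood (not REML, so nested fits are likelihood-comparable). All
#' predictors are standardised to mean 0 and SD 1 before fitting, so the
#' fixed-effect estimates are comparable effect sizes; 95\% Wald confidence
#' intervals accompany each estimate. With a single continent the model
#' degrades to a fixed-effects-only least-squares fit with a warning.
#'
#' @param data model frame, e.g. from \code{\link{assemble_model_data}}.
#' @param response name of the response column.
#' @param predictors names of the fixed-effect columns to standardise and
#'   include.
#' @param group name of the random-intercept grouping column.
#' @param level confidence level for the intervals.
#' @param lrt also compute, per predictor, a likelihood-ratio test against
#'   the model with that predictor removed (adds a \code{p_lrt} column).
#' @return Object of class \code{endem_model_fit}: \code{coefficients}
#'   (term, estimate, se, lower, upper[, p_lrt]), \code{sigma_group},
#'   \code{sigma_resid}, \code{n}, \code{logLik} and the underlying fit.
#' @export
fit_endemism_model <- function(data, response = "endemism",
                               predictors = c("temperature", "precipitation",
                                              "productivity", "elevation",
                                              "autocov"),
                               group = "continent", level = 0.95,
                               lrt = FALSE) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)), group %in% names(data))
  X <- data[predictors]
  if (anyNA(X) || anyNA(data[[response]]))
    stop("missing values in response or predictors", call. = FALSE)
  sds <- vapply(X, stats::sd, 0)
  if (any(sds == 0))
    stop(sprintf("constant predictor(s): %s",
                 paste(predictors[sds == 0], collapse = ", ")), call. = FALSE)
  d <- data.frame(.y = data[[response]], scale(X),
                  .g = factor(data[[group]]), check.names = FALSE)
  gsizes <- table(d$.g)
  if (nlevels(d$.g) >= 2L && any(gsizes < 3L))
    warning("some grouping levels have fewer than 3 cells", call. = FALSE)
  rhs <- paste(predictors, collapse = " + ")
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (nlevels(d$.g) < 2L) {
    warning("single grouping level; fitting fixed-effects-only model",
            call. = FALSE)
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
    cf <- summary(fit)$coefficients
    sigma_group <- NA_real_
    sigma_resid <- summary(fit)$sigma
    ll <- as.numeric(stats::logLik(fit))
  } else {
    fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .g)"))
    fit <- lme4::lmer(fml, data = d, REML = FALSE)
    cf <- summary(fit)$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_group <- vc$sdcor[vc$grp == ".g"]
    sigma_resid <- vc$sdcor[vc$grp == "Residual"]
    ll <- as.numeric(stats::logLik(fit))
  }
  keep <- rownames(cf) %in% predictors
  coefs <- data.frame(term = rownames(cf)[keep],
                      estimate = cf[keep, 1L],
                      se = cf[keep, 2L],
                      lower = cf[keep, 1L] - z * cf[keep, 2L],
                      upper = cf[keep, 1L] + z * cf[keep, 2L],
                      row.names = NULL)
  if (lrt) {
    coefs$p_lrt <- vapply(coefs$term, function(tm) {
      rhs0 <- paste(setdiff(predictors, tm), collapse = " + ")
      if (rhs0 == "") rhs0 <- "1"
      if (nlevels(d$.g) < 2L) {
        fit0 <- stats::lm(stats::as.formula(paste(".y ~", rhs0)), data = d)
      } else {
        fit0 <- lme4::lmer(stats::as.formula(paste(".y ~", rhs0, "+ (1 | .g)")),
                           data = d, REML = FALSE)
      }
      dev <- 2 * (ll - as.numeric(stats::logLik(fit0)))
      stats::pchisq(max(dev, 0), df = 1L, lower.tail = FALSE)
    }, 0)
  }
  structure(list(coefficients = coefs, sigma_group = sigma_group,
                 sigma_resid = sigma_resid, n = nrow(d), logLik = ll,
                 residuals = stats::residuals(fit), fit = fit),
            class = "endem_model_fit")
}

#' @export
print.endem_model_fit <- function(x, ...) {
  cat(sprintf("endem_model_fit: n = %d, sigma_group = %.3g, sigma_resid = %.3g\n",
              x$n, x$sigma_group, x$sigma_resid))
  print(x$coefficients, digits = 3)
  invisible(x)
}
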