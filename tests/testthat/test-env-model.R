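test_that("env_heterogeneity computes sample SDs per cell and layer", {
  g <- endem_grid(2, 2)
  env <- simulate_environment(g, subcells_per_cell = 4, seed = 5)
  het <- env_heterogeneity(env)
  expect_equal(het$cell, 0:3)

  # independent per-cell SD: two-pass formula over the same subcells
  k <- env$k
  for (cl in het$cell) {
    rows <- env$values$frow %/% k == cl %/% 2 & env$values$fcol %/% k == cl %% 2
    x <- env$values$temperature[rows]
    expect_length(x, 4)
    manual <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
    expect_equal(het$temperature[het$cell == cl], manual, tolerance = 1e-12)
  }

  # two-point check: subcells (0, 2) -> SD sqrt(2); incomplete k x k blocks
  # are fine as long as each cell keeps >= 2 subcells
  fake <- structure(list(
    values = data.frame(frow = c(0L, 0L), fcol = c(0L, 1L),
                        temperature = c(0, 2), precipitation = c(1, 1),
                        productivity = c(0, 2), elevation = c(5, 5)),
    k = 2L, grid = endem_grid(1, 1)), class = "endem_env")
  het2 <- env_heterogeneity(fake)
  expect_equal(het2$temperature, sqrt(2))
  expect_equal(het2$precipitation, 0)

  # fewer than 2 subcells in a cell is an error naming the cell
  fake1 <- structure(list(
    values = data.frame(frow = 0L, fcol = 0L, temperature = 1,
                        precipitation = 1, productivity = 1, elevation = 1),
    k = 2L, grid = endem_grid(1, 1)), class = "endem_env")
  expect_error(env_heterogeneity(fake1), "fewer than 2 subcells")
})

test_that("heterogeneity pools subcells under grain aggregation", {
  g <- endem_grid(4, 4)
  env <- simulate_environment(g, 16, autocorr_length = 1, seed = 8)
  het1 <- env_heterogeneity(env, factor = 1)
  het2 <- env_heterogeneity(env, factor = 2)
  het4 <- env_heterogeneity(env, factor = 4)
  expect_equal(nrow(het2), 4)
  expect_equal(nrow(het4), 1)
  expect_true(all(as.matrix(het2[-1]) >= 0))
  # gradient layers: pooled blocks span more latitude, so the median SD of a
  # gradient-bearing layer is non-decreasing with grain
  expect_lte(median(het1$temperature), median(het2$temperature) + 1e-9)
  expect_lte(median(het2$temperature), het4$temperature + 1e-9)
  # pooled SD equals a direct SD over the merged block's subcells
  rows <- env$values$frow < 8 & env$values$fcol < 8
  expect_equal(het2$temperature[het2$cell == 0],
               sd(env$values$temperature[rows]), tolerance = 1e-12)
})

test_that("spatial_autocovariate averages neighbours correctly", {
  g <- endem_grid(5, 5)
  ids <- as.character(0:24)
  const <- stats::setNames(rep(4.2, 25), ids)
  for (ord in 1:2) for (wt in c("inverse", "equal"))
    expect_equal(unname(spatial_autocovariate(const, g, ord, wt)),
                 rep(4.2, 25))

  # single interior cell = 1 (cell 12, centre): order-1 equal weights give
  # its 4 rook neighbours 0.25
  pulse <- stats::setNames(rep(0, 25), ids)
  pulse["12"] <- 1
  ac <- spatial_autocovariate(pulse, g, 1, "equal")
  expect_equal(unname(ac[c("7", "11", "13", "17")]), rep(0.25, 4))
  expect_equal(unname(ac["12"]), 0)
  expect_equal(sum(ac > 0), 4)

  # brute-force oracle on random surfaces, all orders and weightings
  set.seed(13)
  for (i in 1:10) {
    vals <- stats::setNames(runif(25), ids)
    for (ord in 1:2) for (wt in c("inverse", "equal"))
      expect_equal(spatial_autocovariate(vals, g, ord, wt),
                   oracle_autocov(vals, g, ord, wt), tolerance = 1e-12)
  }

  # isolated cell: no neighbours -> 0 with a warning
  g1 <- endem_grid(1, 1)
  expect_warning(z <- spatial_autocovariate(stats::setNames(5, "0"), g1, 1),
                 "no neighbours")
  expect_equal(unname(z), 0)
})

sim_model_frame <- function(n_groups, per_group, beta, sigma_g, sigma_e) {
  n <- n_groups * per_group
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- c("temperature", "precipitation", "productivity",
                   "elevation", "autocov")
  gid <- rep(paste0("C", seq_len(n_groups)), each = per_group)
  b <- rnorm(n_groups, 0, sigma_g)
  y <- as.vector(X %*% beta) + b[match(gid, unique(gid))] + rnorm(n, 0, sigma_e)
  data.frame(endemism = y, X, continent = gid)
}

test_that("fit_endemism_model standardises, recovers parameters, degrades gracefully", {
  set.seed(17)
  beta <- c(0.5, 0, 0, 0, 0.3)
  d <- sim_model_frame(6, 40, beta, sigma_g = 0.5, sigma_e = 1)
  fit <- fit_endemism_model(d)
  expect_s3_class(fit, "endem_model_fit")
  expect_equal(fit$n, 240)
  ord <- match(c("temperature", "precipitation", "productivity",
                 "elevation", "autocov"), fit$coefficients$term)
  est <- fit$coefficients$estimate[ord]
  se <- fit$coefficients$se[ord]
  expect_true(all(abs(est - beta) < 4 * se + 0.05))
  expect_true(all(fit$coefficients$lower < fit$coefficients$upper))

  # standardisation invariance: shifting/scaling raw predictors leaves the
  # standardized-coefficient estimates unchanged
  d2 <- d
  d2$temperature <- d$temperature * 100 + 7
  d2$autocov <- d$autocov / 3 - 2
  fit2 <- fit_endemism_model(d2)
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-6)

  # likelihood-ratio option: strong predictor small p, null predictor large
  fitl <- fit_endemism_model(d, lrt = TRUE)
  p <- stats::setNames(fitl$coefficients$p_lrt, fitl$coefficients$term)
  expect_lt(p[["temperature"]], 1e-6)
  expect_gt(p[["precipitation"]], 0.001)

  # single continent -> fixed-effects-only fallback with warning
  d1 <- d; d1$continent <- "C1"
  expect_warning(fit1 <- fit_endemism_model(d1), "single grouping")
  expect_equal(nrow(fit1$coefficients), 5)

  dbad <- d; dbad$elevation <- 1
  expect_error(fit_endemism_model(dbad), "constant predictor")
})

test_that("assemble_model_data joins surface, heterogeneity and regions", {
  w <- simulate_world(seed = 19, n_taxa = 15, n_trees = 1, n_rows = 6,
                      n_cols = 6)
  cm <- ranges_to_community(w$ranges, w$grid)
  surf <- weighted_endemism(cm)
  het <- env_heterogeneity(w$env)
  md <- assemble_model_data(surf, het, w$regions)
  expect_equal(nrow(md), sum(surf$occupied))  # fitted cells = occupied cells
  expect_true(all(c("endemism", "temperature", "autocov", "continent")
                  %in% names(md)))
  expect_false(anyNA(md))
  fit <- fit_endemism_model(md)
  Z <- scale(md[c("temperature", "precipitation", "productivity",
                  "elevation", "autocov")])
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-9))
})
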