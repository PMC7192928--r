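test_that("simulate_yule_tree produces valid ultrametric trees", {
  expect_error(simulate_yule_tree(1), "n_tips")

  tr2 <- simulate_yule_tree(2, birth_rate = 1.0, seed = 7)
  expect_s3_class(tr2, "phylo")
  expect_length(tr2$tip.label, 2)
  d <- ape::node.depth.edgelength(tr2)
  expect_equal(d[1], d[2], tolerance = 1e-12)

  tr50 <- simulate_yule_tree(50, birth_rate = 1.0, seed = 1)
  expect_length(tr50$tip.label, 50)
  expect_equal(tr50$Nnode, 49)  # binary tree node count
  tipd <- ape::node.depth.edgelength(tr50)[1:50]
  expect_lt(max(tipd) - min(tipd), 1e-9)
  expect_false(anyDuplicated(tr50$tip.label) > 0)

  # determinism: identical seed, identical tree
  expect_identical(write_newick(simulate_yule_tree(20, 0.1, seed = 5)),
                   write_newick(simulate_yule_tree(20, 0.1, seed = 5)))
})

test_that("Yule root height matches the closed-form expectation", {
  # E[root height] = sum_{k=2..n} 1/(k*lambda); n = 2, lambda = 1 -> 0.5,
  # with per-replicate SD 0.5 so the 2000-rep mean has SE ~ 0.011
  set.seed(101)
  h <- replicate(2000, root_h <- {
    tr <- simulate_yule_tree(2, birth_rate = 1.0)
    max(ape::node.depth.edgelength(tr))
  })
  expect_equal(mean(h), 0.5, tolerance = 0.1)  # |err| < 0.05 absolute
  expect_lt(abs(mean(h) - 0.5), 5 * 0.5 / sqrt(2000))
})

test_that("posterior tree sets share a tip-label set and vary in topology", {
  trees <- simulate_posterior_trees(15, 5, birth_rate = 0.1, seed = 3)
  expect_length(trees, 5)
  for (tr in trees) expect_setequal(tr$tip.label, trees[[1]]$tip.label)
  nwk <- vapply(trees, write_newick, "")
  expect_gt(length(unique(nwk)), 1)
})

test_that("simulate_ranges: contiguity, truncation and skew", {
  g1 <- endem_grid(1, 1)
  r1 <- simulate_ranges(g1, c("A", "B"), mean_range = 1, seed = 2)
  expect_identical(unname(r1), list(0L, 0L))

  g <- endem_grid(10, 10)
  tr <- simulate_yule_tree(20, 0.1, seed = 4)
  rr <- simulate_ranges(g, tr, mean_range = 5, seed = 3)
  expect_named(rr, tr$tip.label)
  for (cells in rr) {
    expect_gte(length(cells), 1)
    expect_true(all(cells >= 0 & cells < 100))
    expect_true(oracle_connected(cells, 10, 10))
  }

  # empirical mean within 15% of mean_range; right-skew: median < mean
  big <- endem_grid(40, 40)
  sizes <- lengths(simulate_ranges(big, sprintf("s%03d", 1:500),
                                   mean_range = 8, skew = 1, seed = 11))
  expect_lt(abs(mean(sizes) - 8) / 8, 0.15)
  expect_lt(median(sizes), mean(sizes))
})

test_that("simulate_environment: shape contract, constant limit, autocorrelation", {
  g <- endem_grid(5, 5)
  expect_error(simulate_environment(g, subcells_per_cell = 3), "perfect square")

  env <- simulate_environment(g, subcells_per_cell = 16, seed = 2)
  expect_equal(nrow(env$values), 25 * 16)
  layers <- c("temperature", "precipitation", "productivity", "elevation")
  expect_true(all(layers %in% names(env$values)))
  expect_false(anyNA(env$values))

  # constant-field limit: infinite correlation length -> per-cell SD 0
  env_inf <- simulate_environment(g, 16, autocorr_length = Inf, seed = 2)
  het <- env_heterogeneity(env_inf)
  expect_true(all(abs(as.matrix(het[layers])) < 1e-12))

  # lag-1 spatial autocorrelation beats shuffled (i.i.d.) values
  v <- matrix(env$values$temperature, nrow = 20)  # fine lattice 20 x 20
  lag_cor <- function(m) cor(as.vector(m[-nrow(m), ]), as.vector(m[-1, ]))
  set.seed(9)
  shuffled <- matrix(sample(as.vector(v)), nrow = nrow(v))
  expect_gt(lag_cor(v), lag_cor(shuffled) + 0.3)
})

test_that("partition_regions: nesting, sizes and contiguity", {
  g1 <- endem_grid(2, 2)
  reg1 <- partition_regions(g1, 1, 1, seed = 1)
  expect_equal(unique(reg1$continent), "C1")
  expect_length(unique(reg1$country), 1)

  g <- endem_grid(10, 10)
  expect_error(partition_regions(endem_grid(1, 2), 3, 1, seed = 1),
               "more regions")
  reg <- partition_regions(g, 2, 3, seed = 5)
  expect_length(unique(reg$continent), 2)
  expect_length(unique(reg$country), 6)
  # nesting: each country lies inside exactly one continent
  nest <- table(reg$country, reg$continent)
  expect_true(all(rowSums(nest > 0) == 1))
  # union of a continent's countries is the continent
  for (cl in unique(reg$continent)) {
    cont_cells <- sort(reg$cell[reg$continent == cl])
    ctry_cells <- sort(reg$cell[reg$country %in%
                                  unique(reg$country[reg$continent == cl])])
    expect_identical(cont_cells, ctry_cells)
  }
  # contiguity of every region on rook adjacency (graph traversal oracle)
  for (cl in unique(reg$continent))
    expect_true(oracle_connected(reg$cell[reg$continent == cl], 10, 10))
  for (ct in unique(reg$country))
    expect_true(oracle_connected(reg$cell[reg$country == ct], 10, 10))
})

test_that("simulate_protection: bounds, mean, skew", {
  g <- endem_grid(10, 10)
  expect_error(simulate_protection(g, mean_coverage = 1.5), "mean_coverage")
  expect_identical(unname(simulate_protection(g, 0)), rep(0, 100))
  expect_identical(unname(simulate_protection(g, 1)), rep(1, 100))

  p <- simulate_protection(g, mean_coverage = 0.15, seed = 9)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p), 0.10)
  expect_lt(mean(p), 0.20)
  expect_lt(median(p), mean(p))  # right-skewed: most cells near zero
})

test_that("simulate_world: closure invariants, determinism, range-size skew", {
  w <- simulate_world(seed = 7, n_trees = 3)
  expect_true(validate_world(w))
  w2 <- simulate_world(seed = 7, n_trees = 3)
  expect_identical(w$ranges, w2$ranges)
  expect_identical(vapply(w$trees, write_newick, ""),
                   vapply(w2$trees, write_newick, ""))
  expect_identical(w$protection, w2$protection)
  expect_identical(w$env$values, w2$env$values)
  w3 <- simulate_world(seed = 8, n_trees = 3)
  expect_false(identical(w$ranges, w3$ranges))

  # right-skewed range-size law over >= 200 taxa at default parameters
  big <- simulate_world(n_rows = 20, n_cols = 20, n_taxa = 250, n_trees = 1,
                        seed = 12)
  sizes <- lengths(big$ranges)
  expect_lt(median(sizes), mean(sizes))
})

test_that("world round-trips through its directory format", {
  w <- simulate_world(seed = 31, n_taxa = 12, n_trees = 2, n_rows = 5,
                      n_cols = 6)
  dir <- tempfile("world")
  write_world(w, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "trees.nwk", "ranges.csv", "environment.csv", "regions.csv",
    "protection.csv", "manifest.json")))))
  w2 <- read_world(dir)
  expect_true(validate_world(w2))
  expect_setequal(names(w2$ranges), names(w$ranges))
  for (nm in names(w$ranges))
    expect_setequal(w2$ranges[[nm]], w$ranges[[nm]])
  expect_equal(unname(w2$protection[names(w$protection)]),
               unname(w$protection), tolerance = 1e-12)
  expect_identical(vapply(w2$trees, write_newick, ""),
                   vapply(w$trees, write_newick, ""))
  expect_equal(w2$grid$grain, w$grid$grain)
  unlink(dir, recursive = TRUE)
})
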