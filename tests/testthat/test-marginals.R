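test_that("empirical tables are exactly normalised point masses on uniform grids", {
  rg <- build_region_graph(c(6, 6), 3, explicit = FALSE)
  m0 <- empirical_marginals(make_grid(6, 6), rg)
  for (nm in names(m0$tables)) {
    tbl <- m0$tables[[nm]]
    expect_equal(sum(tbl), 1, tolerance = 1e-12)
    expect_equal(unname(tbl[1]), 1)          # all-0 configuration
    expect_true(all(tbl[-1] == 0))
  }
  m1 <- empirical_marginals(make_grid(6, 6, fill = 1L), rg)
  for (nm in names(m1$tables)) {
    tbl <- m1$tables[[nm]]
    expect_equal(unname(tbl[length(tbl)]), 1) # all-1 configuration
  }
})

test_that("tables are normalised within 1e-12 for random grids", {
  set.seed(401)
  for (rep in 1:10) {
    g <- random_grid(5 + rep %% 3, 6, 0.4)
    m <- empirical_marginals(g, build_region_graph(dim(g), 3, explicit = FALSE))
    for (tbl in m$tables) {
      expect_equal(sum(tbl), 1, tolerance = 1e-12)
      expect_true(all(tbl >= 0 & tbl <= 1))
    }
  }
})

test_that("checkerboard horizontal pairs split evenly between 01 and 10", {
  g <- as_cell_grid(outer(1:8, 1:8, function(i, j) (i + j) %% 2L))
  m <- empirical_marginals(g, build_region_graph(c(8, 8), 2, explicit = FALSE))
  expect_equal(unname(m$tables$pair_h), c(0, 0.5, 0.5, 0))
  expect_equal(unname(m$tables$pair_v), c(0, 0.5, 0.5, 0))
})

test_that("a single cancer site leaves the expected all-healthy triangle mass", {
  g <- seed_grid(make_grid(128, 128), "single_center")
  m <- empirical_marginals(g, build_region_graph(c(128, 128), 3, explicit = FALSE))
  n_tri <- 127^2
  covering <- 3   # interior site: three upper-left triangles cover it
  expect_equal(unname(m$tables$tri_ul[["000"]]), 1 - covering / n_tri,
               tolerance = 1e-12)
  expect_equal(unname(m$tables$tri_lr[["000"]]), 1 - covering / n_tri,
               tolerance = 1e-12)
})

test_that("triangle tables marginalise to the matching pair tables on shared support", {
  set.seed(402)
  g <- random_grid(9, 8, 0.35)
  H <- nrow(g)
  m <- empirical_marginals(g, build_region_graph(dim(g), 3, explicit = FALSE))
  ## upper-left triangles are anchored on rows 1..H-1; dropping the third
  ## site ((i+1, j)) leaves the horizontal pairs of those rows
  sub <- as_cell_grid(unclass(g)[1:(H - 1), , drop = FALSE])
  m_sub <- empirical_marginals(sub, build_region_graph(dim(sub), 2,
                                                       explicit = FALSE))
  expect_equal(unname(marginalize_config_table(m$tables$tri_ul, drop = 3)),
               unname(m_sub$tables$pair_h), tolerance = 1e-12)
  ## dropping the second site ((i, j+1)) leaves the vertical pairs of
  ## columns 1..W-1
  W <- ncol(g)
  subv <- as_cell_grid(unclass(g)[, 1:(W - 1), drop = FALSE])
  mv <- empirical_marginals(subv, build_region_graph(dim(subv), 2,
                                                     explicit = FALSE))
  expect_equal(unname(marginalize_config_table(m$tables$tri_ul, drop = 2)),
               unname(mv$tables$pair_v), tolerance = 1e-12)
})

test_that("transposing the grid swaps horizontal and vertical pair tables", {
  set.seed(403)
  g <- random_grid(7, 11, 0.3)
  gt <- as_cell_grid(t(unclass(g)))
  m <- empirical_marginals(g, build_region_graph(dim(g), 2, explicit = FALSE))
  mt <- empirical_marginals(gt, build_region_graph(dim(gt), 2, explicit = FALSE))
  expect_equal(m$tables$pair_h, mt$tables$pair_v, tolerance = 1e-12)
  expect_equal(m$tables$pair_v, mt$tables$pair_h, tolerance = 1e-12)
  expect_equal(m$tables$site, mt$tables$site, tolerance = 1e-12)
})

test_that("mean-field site marginal equals the cancer fraction", {
  expect_equal(unname(meanfield_marginal(make_grid(4, 4))), c(1, 0))
  half <- as_cell_grid(matrix(rep(c(0L, 1L), 8), 4, 4))
  expect_equal(unname(meanfield_marginal(half)), c(0.5, 0.5))
  g41 <- seed_grid(make_grid(128, 128), "blob", count = 41)
  expect_equal(unname(meanfield_marginal(g41)[["1"]]), 41 / 16384,
               tolerance = 1e-12)
})

test_that("constructor rejects malformed tables and pseudo-counts smooth zeros", {
  expect_error(cluster_marginals(list(site = c(0.5, 0.6)), c(4, 4), 1),
               "probability")
  expect_error(cluster_marginals(list(site = c(0.5, 0.25, 0.25)), c(4, 4), 1),
               "power of 2")
  g <- make_grid(5, 5)
  m <- empirical_marginals(g, build_region_graph(c(5, 5), 2, explicit = FALSE),
                           pseudo_count = 1)
  expect_true(all(m$tables$pair_h > 0))
  expect_equal(sum(m$tables$pair_h), 1, tolerance = 1e-12)
})
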