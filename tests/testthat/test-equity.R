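test_that("accessibility distances follow hand geometry", {
  g <- equity_grid(population = matrix(1, 1, 3),
                   green = matrix(c(TRUE, FALSE, FALSE), 1, 3),
                   cell_size = 200)
  expect_equal(as.numeric(accessibility(g)), c(0, 200, 400))

  gall <- equity_grid(matrix(1, 2, 2), matrix(TRUE, 2, 2))
  expect_true(all(accessibility(gall) == 0))
  expect_equal(gini_lorenz(accessibility(gall), gall$population)$gini, 0)

  gnone <- equity_grid(matrix(1, 2, 2), matrix(FALSE, 2, 2))
  expect_error(accessibility(gnone), "no green cells")
})

test_that("distance transform is exact against brute force on random grids", {
  for (case in 1:8) {
    withr::with_seed(case, {
      green <- matrix(runif(9 * 7) < 0.2, 9, 7)
    })
    if (!any(green)) green[5, 4] <- TRUE
    expect_equal(greengov:::distance_transform(green), distances_naive(green),
                 tolerance = 1e-12)
  }
})

test_that("Gini matches hand values and the pairwise-formula oracle", {
  # equal population on 4 cells, distances (0,0,0,d): pairwise sum 6d,
  # denominator 2*16*(d/4) -> 0.75
  expect_equal(gini_lorenz(c(0, 0, 0, 5), rep(1, 4))$gini, 0.75)
  expect_equal(gini_lorenz(rep(3, 6), runif(6) + 1)$gini, 0)

  for (case in 1:6) {
    withr::with_seed(case, {
      d <- rexp(50); p <- rgamma(50, 2)
    })
    expect_equal(gini_lorenz(d, p)$gini, gini_naive(d, p), tolerance = 1e-10)
    # scale invariance
    expect_equal(gini_lorenz(3.7 * d, p)$gini, gini_lorenz(d, p)$gini,
                 tolerance = 1e-12)
  }
})

test_that("Lorenz curve is anchored, nondecreasing and convex", {
  withr::with_seed(5, {
    d <- rexp(30); p <- rgamma(30, 2)
  })
  lz <- gini_lorenz(d, p)$lorenz
  expect_equal(lz$pop_share[1], 0)
  expect_equal(lz$burden_share[1], 0)
  expect_equal(lz$pop_share[nrow(lz)], 1)
  expect_equal(lz$burden_share[nrow(lz)], 1)
  expect_true(all(diff(lz$burden_share) >= -1e-12))
  slopes <- diff(lz$burden_share) / diff(lz$pop_share)
  expect_true(all(diff(slopes) >= -1e-9))       # sorted by distance => convex
})

test_that("group gaps behave at the symmetric and extreme cases", {
  # identical spatial distribution for both groups: interleave labels across
  # columns of a 1-D gradient so the two groups see the same distances
  green <- matrix(FALSE, 2, 6); green[, 1] <- TRUE
  grp <- matrix(rep(c("a", "b"), 6), 2, 6)
  g <- equity_grid(matrix(1, 2, 6), green, group = grp)
  gg <- group_gaps(g, "a", "b")
  expect_equal(gg$group_ratio, 1)
  expect_equal(gg$coverage_gap_pct, 100 / 6 - 100 / 6)

  # group b entirely green, group a not at all: gap = +100 points
  grp2 <- matrix("a", 2, 6); grp2[, 1] <- "b"
  g2 <- equity_grid(matrix(1, 2, 6), green, group = grp2)
  expect_equal(group_gaps(g2, "a", "b")$coverage_gap_pct, 100)
  expect_error(group_gaps(g2, "a", "zzz"), "zzz")
})

test_that("equity grid validation catches degenerate inputs", {
  expect_error(equity_grid(matrix(0, 2, 2), matrix(TRUE, 2, 2)),
               "total population")
  expect_error(equity_grid(matrix(-1, 2, 2), matrix(TRUE, 2, 2)),
               "nonnegative")
  expect_error(equity_grid(matrix(1, 2, 2), matrix(TRUE, 3, 2)), "dimension")
  expect_error(gini_lorenz(c(1, 2), c(-1, 1)), "nonnegative")
})

test_that("generated equity grids plant a recoverable group-distance ratio", {
  ratios <- vapply(1:50, function(i) {
    g <- gen_equity_grid(15, 15, "uniform", "edge", seed = 900 + i)
    group_gaps(g, "far", "near")$group_ratio
  }, numeric(1))
  expect_lt(abs(median(ratios) - 2), 0.1)

  g1 <- gen_equity_grid(10, 10, "clustered", "scattered", seed = 4)
  g2 <- gen_equity_grid(10, 10, "clustered", "scattered", seed = 4)
  expect_identical(g1, g2)
  truth <- attr(g1, "truth")
  expect_equal(truth$distances,
               greengov:::distance_transform(g1$green) * g1$cell_size)
})
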