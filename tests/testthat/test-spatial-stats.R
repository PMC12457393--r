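test_that("weights schemes produce the expected small-case matrices", {
  w2 <- build_weights(adjacency = matrix(c(0, 1, 1, 0), 2),
                      scheme = "binary_contiguity", row_standardize = FALSE)
  expect_equal(w2$w, matrix(c(0, 1, 1, 0), 2))

  rs <- row_standardize(matrix(c(0, 2, 2, 0), 2))
  expect_equal(rs$w, matrix(c(0, 1, 1, 0), 2))
  expect_true(rs$row_standardized)

  # 3 collinear equidistant points, knn k=1 with symmetrization: the middle
  # point ends up linked to both ends
  coords <- cbind(c(0, 1, 2), c(0, 0, 0))
  wk <- build_weights(coords = coords, scheme = "knn", k = 1, row_standardize = FALSE)
  expect_true(wk$w[2, 1] > 0 && wk$w[2, 3] > 0)
  expect_equal(wk$w[1, 3], 0)
  expect_equal(wk$w, t(wk$w))

  expect_error(build_weights(coords = rbind(c(0, 0), c(0, 0)),
                             scheme = "inverse_distance"),
               "duplicate coordinates")
})

test_that("weights CSV round-trips with ids and standardization detection", {
  w <- build_weights(coords = cbind(runif(5), runif(5)), scheme = "knn",
                     k = 2, ids = paste0("u", 1:5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_weights_csv(w, path)
  back <- read_weights_csv(path)
  expect_equal(back$w, w$w, tolerance = 1e-12)
  expect_equal(back$ids, w$ids)
  expect_true(back$row_standardized)
})

test_that("Moran's I matches hand values and the closed-form expectation", {
  w <- build_weights(adjacency = matrix(c(0, 1, 1, 0), 2),
                     scheme = "binary_contiguity", row_standardize = FALSE)
  m <- morans_i(c(1, -1), w, n_permutations = 99, seed = 1)
  expect_equal(m$statistic, -1)
  expect_equal(m$expectation, -1)               # -1/(n-1), n = 2

  w5 <- build_weights(coords = cbind(1:5, rep(0, 5)), scheme = "knn", k = 2)
  m5 <- morans_i(rnorm(5), w5, n_permutations = 99, seed = 1)
  expect_equal(m5$expectation, -0.25)

  expect_error(morans_i(rep(3, 5), w5), "degenerate variance")
})

test_that("Moran's I equals the literal double-sum on random instances", {
  for (case in 1:12) {
    withr::with_seed(case, {
      n <- sample(4:12, 1)
      coords <- cbind(runif(n), runif(n))
      w <- build_weights(coords = coords, scheme = "inverse_distance",
                         row_standardize = case %% 2 == 0)
      x <- rnorm(n)
      m <- morans_i(x, w, n_permutations = 9, seed = 1)
      expect_equal(m$statistic, moran_naive(x, w$w), tolerance = 1e-12)
    })
  }
})

test_that("Moran's I is invariant to affine rescaling of the attribute", {
  withr::with_seed(9, {
    coords <- cbind(runif(10), runif(10))
    x <- rnorm(10)
  })
  w <- build_weights(coords = coords, scheme = "knn", k = 3)
  m1 <- morans_i(x, w, n_permutations = 99, seed = 5)
  m2 <- morans_i(-2.5 * x + 7, w, n_permutations = 99, seed = 5)
  expect_equal(m1$statistic, m2$statistic, tolerance = 1e-12)
  expect_equal(m1$p_value_perm, m2$p_value_perm)
})

test_that("permutation p-values are reproducible and in (0, 1]", {
  w <- build_weights(coords = cbind(runif(8), runif(8)), scheme = "knn", k = 2)
  x <- rnorm(8)
  m1 <- morans_i(x, w, n_permutations = 199, seed = 42)
  m2 <- morans_i(x, w, n_permutations = 199, seed = 42)
  expect_identical(m1$p_value_perm, m2$p_value_perm)
  expect_true(m1$p_value_perm > 0 && m1$p_value_perm <= 1)
})
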