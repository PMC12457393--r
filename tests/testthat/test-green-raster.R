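# Helper: build a scene whose NDVI equals a prescribed matrix, using a fixed
# red band (ndvi = (nir - red)/(nir + red) inverts to nir = red(1+v)/(1-v)).
scene_from_ndvi <- function(v, mask = NULL) {
  red <- matrix(0.2, nrow(v), ncol(v))
  nir <- red * (1 + v) / (1 - v)
  raster_scene(nir = nir, red = red, nodata_mask = mask)
}

test_that("NDVI follows the band-ratio definition with invalid cells flagged", {
  nir <- matrix(c(0.4, 0.5, 0.0, 0.2), 2)
  red <- matrix(c(0.4, 0.3, 0.0, 0.0), 2)
  sc <- raster_scene(nir, red)
  v <- compute_ndvi(sc)
  expect_equal(v[1, 1], 0)                       # NIR = Red
  expect_equal(v[2, 1], 0.25)                    # (0.5-0.3)/(0.5+0.3)
  expect_true(is.na(v[1, 2]))                    # zero band sum: no information
  expect_equal(v[2, 2], 1)                       # Red = 0
  expect_true(all(abs(v[!is.na(v)]) <= 1))

  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  vm <- compute_ndvi(raster_scene(nir, red, nodata_mask = mask))
  expect_true(is.na(vm[1, 1]))
  expect_error(raster_scene(nir, red[1, , drop = FALSE]), "dimension")
})

test_that("coverage counts green cells among valid cells", {
  v <- matrix(c(0.4, 0.4, 0.1, 0.1), 2)
  s <- summarize_green(scene_from_ndvi(v), ndvi_green_threshold = 0.3)
  expect_equal(s$coverage, 0.5)
  expect_equal(s$mean_ndvi, 0.25)
  expect_equal(sum(s$patch_areas), sum(s$green_mask))

  mask <- matrix(TRUE, 2, 2)
  expect_error(summarize_green(scene_from_ndvi(v, mask)), "empty input")
  expect_error(summarize_green(scene_from_ndvi(v), ndvi_green_threshold = 1.5),
               "ndvi_green_threshold")
})

test_that("coverage is monotone nonincreasing in the NDVI threshold", {
  withr::with_seed(4, {
    v <- matrix(runif(100, -0.5, 0.9), 10)
  })
  sc <- scene_from_ndvi(v)
  cov <- vapply(seq(-0.5, 0.9, by = 0.1),
                function(th) summarize_green(sc, th)$coverage, numeric(1))
  expect_true(all(diff(cov) <= 0))
})

test_that("fragmentation is 0 iff a single patch and 1 - 1/n for n singletons", {
  v <- matrix(-0.2, 6, 6)
  v[2:4, 2:5] <- 0.6                              # one rectangular patch
  s <- summarize_green(scene_from_ndvi(v))
  expect_equal(s$fragmentation, 0)
  expect_equal(length(s$patch_areas), 1L)

  v2 <- matrix(-0.2, 5, 5)
  v2[cbind(c(1, 3, 5, 1, 5), c(1, 3, 5, 5, 1))] <- 0.6  # 5 isolated cells
  s2 <- summarize_green(scene_from_ndvi(v2))
  expect_equal(length(s2$patch_areas), 5L)
  expect_equal(s2$fragmentation, 1 - 1 / 5)

  # translation invariance of the green mask
  v3 <- matrix(-0.2, 6, 6)
  v3[1:3, 1:4] <- 0.6
  expect_equal(summarize_green(scene_from_ndvi(v3))$fragmentation,
               summarize_green(scene_from_ndvi(v))$fragmentation)

  # no green cells: fragmentation undefined
  s4 <- summarize_green(scene_from_ndvi(matrix(-0.2, 3, 3)))
  expect_true(is.na(s4$fragmentation))
  expect_equal(s4$coverage, 0)
})

test_that("patch labelling distinguishes 4- from 8-connectivity", {
  m <- matrix(FALSE, 3, 3)
  m[1, 1] <- m[2, 2] <- TRUE                     # diagonal touch
  l4 <- greengov:::label_patches(m, 4)
  l8 <- greengov:::label_patches(m, 8)
  expect_equal(max(l4), 2L)
  expect_equal(max(l8), 1L)
})
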