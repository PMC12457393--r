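#' Generate a synthetic reflectance scene with a known green layout
#'
#' Lays out `n_patches` mutually non-adjacent 4-connected green patches whose
#' total area matches `green_fraction` of the grid (to the nearest cell),
#' then synthesizes near-infrared and red reflectances so that
#' NDVI-thresholding at the conventional 0.3 cut recovers the layout exactly:
#' green cells get NDVI in (0.45, 0.75), background in (-0.05, 0.15).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param green_fraction target green share in `[0, 1]`.
#' @param n_patches number of separate green patches (>= 1).
#' @param seed random seed.
#' @param cell_size metres per cell (default 30).
#' @return A [raster_scene()] with attribute `truth`: list with `green_mask`,
#'   `patch_areas`, `coverage` (realized green fraction).
#' @export
gen_raster <- function(n_rows, n_cols, green_fraction, n_patches = 1, seed = 1,
                       cell_size = 30) {
  if (!is_count(n_rows) || !is_count(n_cols)) config_error("n_rows/n_cols", "must be positive counts")
  if (!is_prob(green_fraction)) config_error("green_fraction", "must lie in [0, 1]")
  if (!is_count(n_patches)) config_error("n_patches", "must be a count >= 1")
  n_cells <- n_rows * n_cols
  total <- round(green_fraction * n_cells)
  if (total > 0 && n_patches > total) {
    stop(sprintf("generation error: %d patches requested but only %d green cells",
                 n_patches, total), call. = FALSE)
  }

  with_rng(seed, {
    green <- matrix(FALSE, n_rows, n_cols)
    areas <- integer(0)
    if (total > 0) {
      sizes <- rep(total %/% n_patches, n_patches)
      extra <- total %% n_patches
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

      neighbours <- function(idx) {
        r <- (idx - 1L) %% n_rows + 1L
        c <- (idx - 1L) %/% n_rows + 1L
        nb <- c(
          if (r > 1) idx - 1L, if (r < n_rows) idx + 1L,
          if (c > 1) idx - n_rows, if (c < n_cols) idx + n_rows
        )
        nb
      }
      # forbidden = green or touching green (keeps patches disjoint)
      forbidden <- function() {
        f <- green
        idx <- which(green)
        for (i in idx) f[neighbours(i)] <- TRUE
        f
      }
      for (p in seq_along(sizes)) {
        placed <- FALSE
        for (attempt in seq_len(500L)) {
          f <- forbidden()
          free <- which(!f)
          if (!length(free)) break
          cells <- sample(free, 1L)
          ok <- TRUE
          while (length(cells) < sizes[p]) {
            front <- setdiff(unique(unlist(lapply(cells, neighbours))), cells)
            front <- front[!f[front]]
            if (!length(front)) { ok <- FALSE; break }
            cells <- c(cells, if (length(front) == 1L) front else sample(front, 1L))
          }
          if (ok) {
            green[cells] <- TRUE
            areas <- c(areas, length(cells))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("generation error: could not place the requested patch layout", call. = FALSE)
        }
      }
    }

    ndvi <- matrix(stats::runif(n_cells, -0.05, 0.15), n_rows, n_cols)
    ndvi[green] <- stats::runif(sum(green), 0.45, 0.75)
    red <- matrix(stats::runif(n_cells, 0.08, 0.25), n_rows, n_cols)
    nir <- red * (1 + ndvi) / (1 - ndvi)
    scene <- raster_scene(nir = nir, red = red, cell_size = cell_size)
    attr(scene, "truth") <- list(
      green_mask = green,
      patch_areas = areas,
      coverage = sum(green) / n_cells
    )
    scene
  })
}
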