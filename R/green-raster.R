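#' Construct a raster scene of paired reflectance bands
#'
#' A scene holds co-registered near-infrared and red reflectance grids plus a
#' nodata mask; it is the input for NDVI-based green-space extraction.
#'
#' @param nir,red numeric matrices of reflectance (unitless, >= 0 where valid).
#' @param nodata_mask logical matrix, `TRUE` = cell carries no data. Cells that
#'   are `NA` in either band are masked automatically.
#' @param cell_size cell edge in metres (default 30, the Landsat 8 pixel).
#' @return An object of class `raster_scene`.
#' @export
raster_scene <- function(nir, red, nodata_mask = NULL, cell_size = 30) {
  if (!is.matrix(nir) || !is.matrix(red)) stop_dimension("nir and red must be matrices")
  if (!all(dim(nir) == dim(red))) stop_dimension("nir and red must share dimensions")
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nrow(nir), ncol(nir))
  if (!all(dim(nodata_mask) == dim(nir))) stop_dimension("nodata_mask must share band dimensions")
  nodata_mask <- nodata_mask | is.na(nir) | is.na(red)
  valid <- !nodata_mask
  if (any(valid & (nir < 0 | red < 0), na.rm = TRUE)) {
    stop("reflectances must be nonnegative on unmasked cells", call. = FALSE)
  }
  if (any(valid & (!is.finite(nir) | !is.finite(red)))) {
    stop("reflectances must be finite on unmasked cells", call. = FALSE)
  }
  structure(
    list(nir = nir, red = red, nodata_mask = nodata_mask, cell_size = cell_size),
    class = "raster_scene"
  )
}

#' Normalized difference vegetation index
#'
#' Per cell, `NDVI = (NIR - Red) / (NIR + Red)`. Cells that are masked, or
#' whose band sum is zero (no spectral information), are returned as `NA` and
#' excluded from every downstream summary.
#'
#' @param scene a [raster_scene()].
#' @return numeric matrix of NDVI in `[-1, 1]` with `NA` for invalid cells.
#' @export
compute_ndvi <- function(scene) {
  stopifnot(inherits(scene, "raster_scene"))
  denom <- scene$nir + scene$red
  ndvi <- (scene$nir - scene$red) / denom
  ndvi[scene$nodata_mask | denom == 0] <- NA_real_
  ndvi
}

# 4- or 8-connected component labelling of a logical mask by iterative
# minimum-label propagation (vectorised; converges in O(patch diameter)).
label_patches <- function(mask, connectivity = 4) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  big <- sum(mask) + 1L
  l <- matrix(big, nr, nc)
  l[mask] <- lab[mask]
  shift <- function(m, dr, dc) {
    out <- matrix(big, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c], drop = FALSE]
    out
  }
  offsets <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8) {
    offsets <- c(offsets, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  repeat {
    nxt <- l
    for (o in offsets) nxt <- pmin(nxt, shift(l, o[1], o[2]))
    nxt[!mask] <- big
    if (identical(nxt, l)) break
    l <- nxt
  }
  l[!mask] <- 0L
  # compact labels to 1..K
  ids <- sort(unique(l[l > 0L]))
  if (length(ids)) l[l > 0L] <- match(l[l > 0L], ids)
  l
}

#' Summarize green space in a scene
#'
#' Thresholds NDVI into a green mask, then reports coverage (green cells /
#' valid cells), mean NDVI over valid cells, the sizes of connected green
#' patches, and a fragmentation index
#' \deqn{F = 1 - \sum_k a_k^2 / A^2}
#' where \eqn{a_k} are patch areas (cells) and \eqn{A} the total green area.
#' \eqn{F} is 0 for a single patch and approaches 1 as green space splinters
#' into many small patches; with no green cells it is `NA`.
#'
#' @param scene a [raster_scene()].
#' @param ndvi_green_threshold cells with NDVI at or above this value count as
#'   green. Default 0.3, the conventional vegetated-surface cut.
#' @param connectivity patch connectivity, 4 (default; the stricter landscape
#'   convention) or 8.
#' @return A list of class `green_summary`: `ndvi`, `green_mask`, `coverage`,
#'   `mean_ndvi`, `fragmentation`, `patch_areas`, `n_valid`.
#' @export
summarize_green <- function(scene, ndvi_green_threshold = 0.3, connectivity = 4) {
  stopifnot(inherits(scene, "raster_scene"))
  if (!is.numeric(ndvi_green_threshold) || length(ndvi_green_threshold) != 1L ||
      ndvi_green_threshold <= -1 || ndvi_green_threshold >= 1) {
    config_error("ndvi_green_threshold", "must lie in (-1, 1)")
  }
  ndvi <- compute_ndvi(scene)
  valid <- !is.na(ndvi)
  if (!any(valid)) stop("empty input: every cell is masked or spectrally void", call. = FALSE)
  green <- valid & ndvi >= ndvi_green_threshold
  lab <- label_patches(green, connectivity)
  areas <- if (any(green)) as.numeric(tabulate(lab[lab > 0L])) else numeric(0)
  A <- sum(areas)
  frag <- if (A > 0) 1 - sum(areas^2) / A^2 else NA_real_
  structure(
    list(
      ndvi = ndvi,
      green_mask = green,
      coverage = sum(green) / sum(valid),
      mean_ndvi = mean(ndvi[valid]),
      fragmentation = frag,
      patch_areas = areas,
      n_valid = sum(valid)
    ),
    class = "green_summary"
  )
}

#' @export
print.green_summary <- function(x, ...) {
  cat("Green-space summary\n")
  cat(sprintf("  valid cells : %d\n", x$n_valid))
  cat(sprintf("  coverage    : %.4f\n", x$coverage))
  cat(sprintf("  mean NDVI   : %.4f\n", x$mean_ndvi))
  cat(sprintf("  patches     : %d\n", length(x$patch_areas)))
  cat(sprintf("  fragmentation: %s\n",
               if (is.na(x$fragmentation)) "NA (no green cells)" else sprintf("%.4f", x$fragmentation)))
  invisible(x)
}
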