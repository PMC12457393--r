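#' Construct a co-registered population / green-space equity grid
#'
#' @param population nonnegative numeric matrix (persons per cell).
#' @param green logical matrix, `TRUE` = the cell contains green space.
#' @param group optional matrix of group labels (e.g. income stratum) per
#'   cell; `NA` = unlabelled.
#' @param cell_size cell edge in metres (default 200).
#' @return Object of class `equity_grid`.
#' @export
equity_grid <- function(population, green, group = NULL, cell_size = 200) {
  if (!is.matrix(population) || !is.matrix(green)) stop_dimension("population and green must be matrices")
  if (!all(dim(population) == dim(green))) stop_dimension("population and green must share dimensions")
  if (!is.null(group) && !all(dim(group) == dim(population))) {
    stop_dimension("group must share grid dimensions")
  }
  if (any(!is.finite(population)) || any(population < 0)) {
    stop("validation error: population must be finite and nonnegative", call. = FALSE)
  }
  if (sum(population) <= 0) stop("validation error: total population must be positive", call. = FALSE)
  structure(
    list(population = population, green = green != 0 & !is.na(green),
         group = group, cell_size = cell_size),
    class = "equity_grid"
  )
}

# Exact Euclidean distance transform (cell units): a vertical sweep per
# column gives the nearest green row offset within each column, then a
# per-row lower-envelope over columns completes the 2-D minimization. Exact,
# O(rows * cols^2), ample at grid scale.
distance_transform <- function(green) {
  nr <- nrow(green); nc <- ncol(green)
  big <- nr + nc + 1
  v <- matrix(big, nr, nc)
  v[green] <- 0
  if (nr > 1) {
    for (r in 2:nr) v[r, ] <- pmin(v[r, ], v[r - 1, ] + 1)
    for (r in (nr - 1):1) v[r, ] <- pmin(v[r, ], v[r + 1, ] + 1)
  }
  v2 <- v^2
  coloff2 <- outer(seq_len(nc), seq_len(nc), function(a, b) (a - b)^2)
  d2 <- t(apply(v2, 1L, function(row) {
    apply(coloff2 + matrix(row, nc, nc, byrow = FALSE), 2L, min)
  }))
  sqrt(d2)
}

#' Distance to the nearest green cell
#'
#' Per-cell Euclidean centroid distance (metres) to the nearest green cell;
#' green cells get 0. This straight-line metric stands in for walking
#' distance on a street network.
#'
#' @param grid an [equity_grid()].
#' @return numeric matrix of distances in metres.
#' @export
accessibility <- function(grid) {
  stopifnot(inherits(grid, "equity_grid"))
  if (!any(grid$green)) stop("no green cells: accessibility undefined", call. = FALSE)
  distance_transform(grid$green) * grid$cell_size
}

# Population-weighted Gini of a nonnegative quantity via the sorted
# O(n log n) identity; equals the pairwise mean-absolute-difference formula
#   G = sum_ij p_i p_j |d_i - d_j| / (2 P^2 dbar).
weighted_gini <- function(d, p) {
  keep <- p > 0
  d <- d[keep]; p <- p[keep]
  P <- sum(p)
  dbar <- sum(p * d) / P
  if (dbar == 0) return(0)  # perfect equality convention
  o <- order(d)
  d <- d[o]; p <- p[o]
  cp <- cumsum(p)
  # sum_ij p_i p_j |d_i-d_j| = 2 * sum_i p_i d_i * (cp_{i-1}) - 2 * sum_i p_i * cd_{i-1}
  cd <- cumsum(p * d)
  s <- 2 * sum(p * d * (cp - p)) - 2 * sum(p * (cd - p * d))
  s / (2 * P^2 * dbar)
}

#' Lorenz curve and Gini coefficient of accessibility burden
#'
#' Treats distance-to-green as a burden distributed over the population:
#' cells are sorted by distance, and the Lorenz curve plots cumulative
#' population share against cumulative share of population-weighted
#' distance. The Gini coefficient is the population-weighted
#' mean-absolute-difference statistic
#' \deqn{G = \frac{\sum_i\sum_j p_i p_j |d_i-d_j|}{2 (\sum_i p_i)^2 \bar d}.}
#' Higher G means green access is less equally shared. All-zero distances
#' give G = 0 by convention.
#'
#' @param distances numeric matrix or vector of per-cell distances (m).
#' @param population matching nonnegative population weights.
#' @return Object of class `equity_result`: `gini`, `lorenz` (data.frame
#'   `pop_share`, `burden_share`, starting at (0,0) and ending at (1,1)),
#'   `mean_distance` (population weighted).
#' @export
gini_lorenz <- function(distances, population) {
  d <- as.numeric(distances); p <- as.numeric(population)
  if (length(d) != length(p)) stop_dimension("distances and population must have equal length")
  if (any(!is.finite(p)) || any(p < 0)) stop("validation error: population must be nonnegative", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0)) stop("validation error: distances must be nonnegative", call. = FALSE)
  if (sum(p) <= 0) stop("validation error: some population must be positive", call. = FALSE)
  keep <- p > 0
  dk <- d[keep]; pk <- p[keep]
  o <- order(dk)
  dk <- dk[o]; pk <- pk[o]
  P <- sum(pk); tot <- sum(pk * dk)
  lorenz <- data.frame(
    pop_share = c(0, cumsum(pk) / P),
    burden_share = if (tot > 0) c(0, cumsum(pk * dk) / tot) else c(0, cumsum(pk) / P)
  )
  structure(
    list(
      gini = weighted_gini(d, p),
      lorenz = lorenz,
      mean_distance = tot / P
    ),
    class = "equity_result"
  )
}

#' Accessibility gaps between population groups
#'
#' Compares two labelled groups on an equity grid: the ratio of
#' population-weighted mean distances (`group_a : group_b`) and the green
#' coverage gap, i.e. the percentage of green cells among `group_b` cells
#' minus that among `group_a` cells, in percentage points. A negative gap
#' means `group_b` (e.g. a minority or low-income stratum) has less green
#' coverage than `group_a`.
#'
#' @param grid an [equity_grid()] with a `group` layer.
#' @param group_a,group_b labels present in the group layer.
#' @return list with `group_ratio` and `coverage_gap_pct`.
#' @export
group_gaps <- function(grid, group_a, group_b) {
  stopifnot(inherits(grid, "equity_grid"))
  if (is.null(grid$group)) stop("grid has no group layer", call. = FALSE)
  dist <- accessibility(grid)
  for (g in c(group_a, group_b)) {
    sel <- grid$group == g & !is.na(grid$group)
    if (!any(sel) || sum(grid$population[sel]) <= 0) {
      stop(sprintf("empty group: '%s' has no populated cells", g), call. = FALSE)
    }
  }
  sel_a <- grid$group == group_a & !is.na(grid$group)
  sel_b <- grid$group == group_b & !is.na(grid$group)
  mean_d <- function(sel) {
    sum(grid$population[sel] * dist[sel]) / sum(grid$population[sel])
  }
  cov_pct <- function(sel) 100 * mean(grid$green[sel])
  list(
    group_ratio = mean_d(sel_a) / mean_d(sel_b),
    coverage_gap_pct = cov_pct(sel_b) - cov_pct(sel_a)
  )
}

#' @export
print.equity_result <- function(x, ...) {
  cat(sprintf("Accessibility equity: Gini = %.4f, mean distance = %.1f m\n",
              x$gini, x$mean_distance))
  invisible(x)
}
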