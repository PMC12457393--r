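#' Construct a spatial weights matrix
#'
#' Builds the n-by-n nonnegative proximity matrix `W` used by Moran's I and
#' the spatial Durbin model. Three schemes are supported:
#' \describe{
#'   \item{`knn`}{k nearest neighbours by Euclidean distance, made symmetric
#'     by `max(W, t(W))` so neighbourhood is mutual.}
#'   \item{`inverse_distance`}{`w_ij = 1 / d_ij`; duplicate coordinates are
#'     rejected (infinite weight).}
#'   \item{`binary_contiguity`}{binarized from a supplied adjacency matrix.}
#' }
#' The diagonal is always zero. Row standardization rescales each nonzero row
#' to sum to one, the convention the spatial Durbin estimator requires.
#'
#' @param coords n x 2 matrix of unit coordinates (`knn`, `inverse_distance`).
#' @param adjacency n x n matrix, nonzero = neighbour (`binary_contiguity`).
#' @param scheme one of `"knn"`, `"inverse_distance"`, `"binary_contiguity"`.
#' @param k neighbours per unit for `knn` (default 4).
#' @param row_standardize rescale rows to sum to 1 (default `TRUE`).
#' @param ids optional unit labels.
#' @return Object of class `spatial_weights`: list with `w`, `ids`,
#'   `row_standardized`.
#' @export
build_weights <- function(coords = NULL, adjacency = NULL,
                          scheme = c("knn", "inverse_distance", "binary_contiguity"),
                          k = 4, row_standardize = TRUE, ids = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "binary_contiguity") {
    if (is.null(adjacency)) config_error("adjacency", "is required for binary_contiguity")
    w <- (as.matrix(adjacency) != 0) * 1
    w <- pmax(w, t(w))  # contiguity is mutual
  } else {
    if (is.null(coords)) config_error("coords", sprintf("is required for %s", scheme))
    coords <- as.matrix(coords)
    n <- nrow(coords)
    if (n < 2L) config_error("coords", "needs at least 2 units")
    d <- as.matrix(stats::dist(coords))
    if (scheme == "inverse_distance") {
      dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
      if (nrow(dup)) {
        stop(sprintf("duplicate coordinates for units %d and %d: inverse distance undefined",
                     dup[1, 1], dup[1, 2]), call. = FALSE)
      }
      w <- 1 / d
      diag(w) <- 0
    } else {
      if (!is_count(k) || k >= n) config_error("k", "must be a positive count below n")
      w <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(d[i, -i])[seq_len(k)]
        nb <- seq_len(n)[-i][nb]
        w[i, nb] <- 1
      }
      w <- pmax(w, t(w))  # symmetrize: keep a link if either end nominates it
    }
  }
  diag(w) <- 0
  n <- nrow(w)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- structure(
    list(w = w, ids = ids, row_standardized = FALSE),
    class = "spatial_weights"
  )
  if (row_standardize) out <- row_standardize(out)
  validate_weights(out)
  out
}

#' Row-standardize a spatial weights object
#'
#' @param weights a `spatial_weights` object or bare matrix.
#' @return `spatial_weights` whose nonzero rows sum to one.
#' @export
row_standardize <- function(weights) {
  w <- if (inherits(weights, "spatial_weights")) weights$w else as.matrix(weights)
  rs <- rowSums(w)
  nz <- rs > 0
  w[nz, ] <- w[nz, , drop = FALSE] / rs[nz]
  ids <- if (inherits(weights, "spatial_weights")) weights$ids else as.character(seq_len(nrow(w)))
  structure(list(w = w, ids = ids, row_standardized = TRUE), class = "spatial_weights")
}

validate_weights <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  w <- weights$w
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop_dimension("weights matrix must be square")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and nonnegative", call. = FALSE)
  if (any(diag(w) != 0)) stop("weights diagonal must be zero", call. = FALSE)
  if (all(w == 0)) stop("weights must contain at least one positive entry", call. = FALSE)
  if (isTRUE(weights$row_standardized)) {
    rs <- rowSums(w)
    if (any(abs(rs[rs > 0] - 1) > 1e-10)) {
      stop("row-standardized weights must have nonzero rows summing to 1", call. = FALSE)
    }
  }
  invisible(weights)
}

#' Write / read a dense weights matrix as CSV
#'
#' The CSV carries a header row of unit ids; row order matches the header.
#' @param weights a `spatial_weights` object.
#' @param path file path.
#' @return `path` invisibly / a `spatial_weights` object.
#' @export
write_weights_csv <- function(weights, path) {
  validate_weights(weights)
  df <- as.data.frame(weights$w)
  names(df) <- weights$ids
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @param row_standardized flag to set on the object read back (checked).
#' @export
read_weights_csv <- function(path, row_standardized = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  w <- as.matrix(df)
  dimnames(w) <- NULL
  out <- structure(
    list(w = w, ids = names(df), row_standardized = FALSE),
    class = "spatial_weights"
  )
  rs <- rowSums(w)
  looks_std <- all(abs(rs[rs > 0] - 1) <= 1e-10)
  out$row_standardized <- if (is.null(row_standardized)) looks_std else isTRUE(row_standardized)
  validate_weights(out)
  out
}
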