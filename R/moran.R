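#' Global Moran's I with permutation inference
#'
#' Computes
#' \deqn{I = \frac{n}{\sum_i \sum_j w_{ij}} \cdot
#'       \frac{\sum_i \sum_j w_{ij} (x_i-\bar x)(x_j-\bar x)}
#'            {\sum_i (x_i-\bar x)^2}}
#' and a two-sided permutation p-value obtained by randomly relabelling `x`
#' over the units: `p = (1 + #{|I_perm - E| >= |I_obs - E|}) / (1 + n_perm)`,
#' where `E = -1/(n-1)` is the null expectation. The add-one convention keeps
#' p strictly positive. A z-score under the classical normality approximation
#' is reported alongside.
#'
#' @param x numeric attribute vector, one value per unit; must vary.
#' @param weights a `spatial_weights` object (see [build_weights()]).
#' @param n_permutations number of random relabellings (default 999).
#' @param seed integer seed for the permutation stream.
#' @return Object of class `moran_result`: `statistic`, `expectation`
#'   (`-1/(n-1)` exactly), `p_value_perm`, `n_permutations`, `z_score`.
#' @export
morans_i <- function(x, weights, n_permutations = 999, seed = 1) {
  validate_weights(weights)
  w <- weights$w
  n <- nrow(w)
  x <- as.numeric(x)
  if (length(x) != n) stop_dimension("length(x) must equal the number of units in weights")
  if (!all(is.finite(x))) stop("x must be finite", call. = FALSE)
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop("degenerate variance: x is constant, Moran's I undefined", call. = FALSE)
  if (!is_count(n_permutations)) config_error("n_permutations", "must be a positive count")
  s0 <- sum(w)
  istat <- (n / s0) * sum(z * (w %*% z)) / ss
  expectation <- -1 / (n - 1)

  # Normality-assumption variance (Cliff & Ord): needs S1, S2.
  s1 <- sum((w + t(w))^2) / 2
  s2 <- sum((rowSums(w) + colSums(w))^2)
  var_norm <- (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - expectation^2
  zscore <- (istat - expectation) / sqrt(var_norm)

  iperm <- with_rng(seed, {
    vapply(seq_len(n_permutations), function(b) {
      zp <- z[sample.int(n)]
      (n / s0) * sum(zp * (w %*% zp)) / ss
    }, numeric(1))
  })
  p <- (1 + sum(abs(iperm - expectation) >= abs(istat - expectation))) / (1 + n_permutations)

  structure(
    list(
      statistic = istat,
      expectation = expectation,
      p_value_perm = p,
      n_permutations = n_permutations,
      z_score = zscore
    ),
    class = "moran_result"
  )
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Moran's I permutation test\n")
  cat(sprintf("  I = %.4f  (E[I] = %.4f)\n", x$statistic, x$expectation))
  cat(sprintf("  z = %.3f, permutation p = %.4f (%d permutations)\n",
              x$z_score, x$p_value_perm, x$n_permutations))
  invisible(x)
}
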