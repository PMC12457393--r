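#' Generate a cross-sectional spatial Durbin field with known parameters
#'
#' Draws unit sites uniformly, builds row-standardized k-nearest-neighbour
#' weights, and simulates
#' \deqn{y = (I - \rho W)^{-1} (\iota\beta_0 + X\beta + WX\theta + \varepsilon)}
#' with standard-normal regressors and Gaussian noise. Used to validate the
#' spatial Durbin estimator by recovery of the planted spatial lag and the
#' effects decomposition.
#'
#' @param n number of units.
#' @param rho planted spatial lag coefficient, in (-1, 1).
#' @param beta own-regressor coefficients (length sets the regressor count).
#' @param theta spatially-lagged regressor coefficients (same length).
#' @param intercept planted intercept (default 0).
#' @param sigma noise standard deviation (default 1).
#' @param k neighbours for the weights graph (default 4).
#' @param seed random seed.
#' @param weights optional pre-built row-standardized `spatial_weights` to
#'   reuse across replicates (its dimension must be `n`).
#' @return list with `y`, `X`, `weights`, `truth` (all planted values).
#' @export
gen_sdm_field <- function(n = 400, rho = 0.49, beta = c(-0.6, 0.3),
                          theta = c(-0.2, 0.1), intercept = 0, sigma = 1,
                          k = 4, seed = 1, weights = NULL) {
  if (!is.numeric(rho) || abs(rho) >= 1) config_error("rho", "must lie in (-1, 1)")
  if (length(beta) != length(theta)) config_error("theta", "must match beta in length")
  p <- length(beta)
  with_rng(seed, {
    if (is.null(weights)) {
      coords <- cbind(stats::runif(n, 0, 100), stats::runif(n, 0, 100))
      weights <- build_weights(coords = coords, scheme = "knn", k = k,
                               row_standardize = TRUE)
    } else {
      validate_weights(weights)
      if (nrow(weights$w) != n) stop_dimension("weights dimension must equal n")
      if (!isTRUE(weights$row_standardized)) {
        stop("contract error: weights must be row-standardized", call. = FALSE)
      }
    }
    X <- matrix(stats::rnorm(n * p), n, p)
    colnames(X) <- paste0("x", seq_len(p))
    W <- weights$w
    rhs <- intercept + X %*% beta + (W %*% X) %*% theta + stats::rnorm(n, 0, sigma)
    y <- as.numeric(solve(diag(n) - rho * W, rhs))
    list(
      y = y, X = X, weights = weights,
      truth = list(rho = rho, beta = beta, theta = theta,
                   intercept = intercept, sigma = sigma, seed = seed)
    )
  })
}
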