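# Panel containers are plain long-format data.frames with columns `unit`,
# `year`, the outcome, the coverage variable and any controls; validated here.

check_panel <- function(panel, vars) {
  stopifnot(is.data.frame(panel))
  need <- c("unit", "year", vars)
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    stop(sprintf("panel is missing column(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(panel[c("unit", "year")])) {
    stop("panel has duplicated (unit, year) pairs", call. = FALSE)
  }
  for (v in vars) {
    if (!all(is.finite(panel[[v]]))) stop(sprintf("column '%s' must be finite", v), call. = FALSE)
  }
  invisible(panel)
}

# Demean columns within unit (the within transform).
within_demean <- function(m, unit) {
  m <- as.matrix(m)
  for (j in seq_len(ncol(m))) m[, j] <- m[, j] - ave(m[, j], unit)
  m
}

#' Fixed-effects (within) panel estimator
#'
#' Estimates `y_it = alpha_i + x_it' beta + e_it` by unit-demeaning, with
#' cluster-robust standard errors by unit (CR1 small-sample correction) and
#' the within R-squared. Unit fixed effects absorb any time-invariant city
#' characteristic, so only within-city variation identifies `beta`.
#'
#' @param panel data.frame with `unit`, `year`, outcome and regressor columns.
#' @param outcome name of the outcome column.
#' @param regressors character vector of regressor column names; each must
#'   vary within at least one unit.
#' @return Object of class `fe_fit`: `beta` (named coefficients; the first
#'   regressor's coefficient is also exposed as `beta_g`), `se`
#'   (cluster-robust), `r2_within`, `n_obs`, `n_units`, `residuals`,
#'   `fitted_within`.
#' @export
fit_fe <- function(panel, outcome, regressors) {
  check_panel(panel, c(outcome, regressors))
  unit <- as.factor(panel$unit)
  y <- within_demean(panel[[outcome]], unit)
  X <- within_demean(panel[, regressors, drop = FALSE], unit)
  colnames(X) <- regressors
  for (j in seq_along(regressors)) {
    if (all(abs(X[, j]) < 1e-12)) {
      stop(sprintf("collinearity: regressor '%s' is constant within every unit", regressors[j]),
           call. = FALSE)
    }
  }
  n <- nrow(X); k <- ncol(X); g <- nlevels(unit)
  if (n < 2L * g || g < 2L) stop("need at least 2 periods for at least 2 units", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < k) stop("collinearity: within-transformed design is rank deficient", call. = FALSE)
  beta <- qr.coef(qx, y)[, 1]
  res <- y - X %*% beta
  xtx_inv <- chol2inv(qr.R(qx))

  # CR1 cluster-robust covariance: sum over units of X_g' e_g e_g' X_g.
  meat <- matrix(0, k, k)
  for (u in levels(unit)) {
    idx <- unit == u
    s <- crossprod(X[idx, , drop = FALSE], res[idx])
    meat <- meat + tcrossprod(s)
  }
  dfc <- (g / (g - 1)) * ((n - 1) / (n - g - k))
  vc <- dfc * xtx_inv %*% meat %*% xtx_inv
  se <- sqrt(diag(vc))
  names(beta) <- names(se) <- regressors

  structure(
    list(
      beta = beta,
      beta_g = beta[[1]],
      se = se,
      vcov = vc,
      r2_within = 1 - sum(res^2) / sum(y^2),
      n_obs = n,
      n_units = g,
      residuals = as.numeric(res),
      fitted_within = as.numeric(X %*% beta)
    ),
    class = "fe_fit"
  )
}

#' @export
print.fe_fit <- function(x, ...) {
  cat(sprintf("Within (fixed-effects) fit: %d obs, %d units, within R^2 = %.3f\n",
              x$n_obs, x$n_units, x$r2_within))
  print(data.frame(estimate = x$beta, cluster_se = x$se))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R_j^2)` where `R_j^2` comes from regressing regressor j
#' on the remaining regressors (with intercept). Values near 1 indicate no
#' multicollinearity; the screening rule used for panel controls is an
#' average VIF below 3.5.
#'
#' @param panel data.frame holding the regressors.
#' @param regressors character vector of at least two column names.
#' @return list with `vif` (named vector; `Inf` for perfectly collinear
#'   regressors, with `collinear` flag), `mean_vif`, `collinear`.
#' @export
vif <- function(panel, regressors) {
  if (length(regressors) < 2L) config_error("regressors", "needs at least 2 entries")
  check_panel(panel, regressors)
  X <- as.matrix(panel[, regressors, drop = FALSE])
  out <- vapply(seq_along(regressors), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    if (tot == 0) return(Inf)
    r2 <- 1 - sum(r^2) / tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- regressors
  if (any(!is.finite(out))) {
    warning("perfect collinearity detected: infinite VIF reported", call. = FALSE)
  }
  list(vif = out, mean_vif = mean(out), collinear = !is.finite(out))
}
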