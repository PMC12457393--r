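# Exact quantile regression.
#
# The check-loss minimization is a linear program whose optimum is attained
# at a "vertex": a coefficient vector that interpolates p observations
# (p = number of columns of the design). rq_exact() runs a specialized
# long-step simplex directly over such zero-residual bases: at each basis it
# tests the directional derivative of the objective along the p edge
# directions (each of which releases one basis observation), and if some
# direction descends, walks along it accumulating the derivative jumps at
# residual sign changes until the objective stops decreasing; the
# observation at that breakpoint enters the basis. The returned solution is
# an exact vertex minimizer of the check loss.

check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

rq_exact <- function(X, y, tau, max_iter = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    config_error("tau", "must lie strictly in (0, 1)")
  }
  if (n <= p) stop("rank error: need more observations than coefficients", call. = FALSE)
  if (qr(X)$rank < p) stop("rank error: design matrix is rank deficient", call. = FALSE)

  if (is.null(max_iter)) max_iter <- 50L * n
  ztol <- 1e-9 * (1 + max(abs(y)))

  # Initial basis: p linearly independent observations via pivoted QR of X'.
  h <- sort(qr(t(X))$pivot[seq_len(p)])

  rate <- function(v) tau * pmax(-v, 0) + (1 - tau) * pmax(v, 0)

  for (iter in seq_len(max_iter)) {
    Xh <- X[h, , drop = FALSE]
    beta <- solve(Xh, y[h])
    r <- as.numeric(y - X %*% beta)
    r[h] <- 0
    S <- X %*% solve(Xh)            # S[, j] = X %*% Xh^{-1} e_j
    zero <- abs(r) <= ztol          # includes the basis rows
    psi <- tau - (r < 0)

    # Directional derivatives for both orientations of each edge.
    zm <- matrix(zero, n, p)
    contrib_plus <- ifelse(zm, rate(S), -psi * S)
    contrib_minus <- ifelse(zm, rate(-S), psi * S)
    Dplus <- colSums(contrib_plus)
    Dminus <- colSums(contrib_minus)
    worst <- min(c(Dplus, Dminus))
    if (worst >= -1e-9) break

    if (min(Dplus) <= min(Dminus)) {
      j <- which.min(Dplus); sigma <- 1
    } else {
      j <- which.min(Dminus); sigma <- -1
    }
    s <- sigma * S[, j]
    D <- if (sigma == 1) Dplus[j] else Dminus[j]

    # Breakpoints where a nonzero residual hits zero along the edge.
    cand <- which(!zero & abs(s) > 1e-12)
    tvals <- r[cand] / s[cand]
    pos <- tvals > 0
    cand <- cand[pos]; tvals <- tvals[pos]
    if (!length(cand)) stop("estimation error: quantile objective unbounded along an edge", call. = FALSE)
    ord <- order(tvals)
    enter <- NA_integer_
    for (m in ord) {
      D <- D + abs(s[cand[m]])
      if (D >= 0) { enter <- cand[m]; break }
    }
    if (is.na(enter)) stop("estimation error: quantile objective unbounded along an edge", call. = FALSE)
    h[j] <- enter
    h <- sort(h)
  }

  Xh <- X[h, , drop = FALSE]
  beta <- solve(Xh, y[h])
  r <- as.numeric(y - X %*% beta)
  list(beta = beta, objective = check_loss(r, tau), basis = h, residuals = r,
       iterations = iter)
}

#' Quantile regression by exact linear programming
#'
#' Minimizes the check loss \eqn{\sum_i \rho_\tau(y_i - x_i'\beta)} with
#' \eqn{\rho_\tau(u) = u(\tau - 1\{u<0\})} exactly, returning a vertex
#' solution (one that interpolates as many observations as there are
#' coefficients). At \eqn{\tau = 0.25} the fitted line tracks the lower
#' quartile of the conditional outcome distribution — for a distress-style
#' mental-health score, the high-risk stratum.
#'
#' @param panel data.frame holding the outcome and regressors.
#' @param outcome outcome column name.
#' @param regressors character vector of regressor column names.
#' @param tau quantile level in (0, 1).
#' @param intercept include an intercept (default `TRUE`).
#' @return Object of class `quantile_fit`: `tau`, `beta` (named), `objective`
#'   (attained check loss), `basis` (row indices interpolated), `residuals`.
#' @export
fit_quantile <- function(panel, outcome, regressors, tau, intercept = TRUE) {
  check_panel_cols <- c(outcome, regressors)
  stopifnot(is.data.frame(panel))
  missing <- setdiff(check_panel_cols, names(panel))
  if (length(missing)) {
    stop(sprintf("panel is missing column(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(panel[, regressors, drop = FALSE])
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  y <- panel[[outcome]]
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("outcome and regressors must be finite", call. = FALSE)
  sol <- rq_exact(X, y, tau)
  names(sol$beta) <- colnames(X)
  structure(
    list(tau = tau, beta = sol$beta, objective = sol$objective,
         basis = sol$basis, residuals = sol$residuals),
    class = "quantile_fit"
  )
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile regression (tau = %.2f), check loss %.6g\n", x$tau, x$objective))
  print(x$beta)
  invisible(x)
}
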