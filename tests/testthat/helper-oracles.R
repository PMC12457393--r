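# Independent brute-force oracles used to validate the estimators. Each is a
# literal transcription of the defining formula, kept free of the package's
# own computational shortcuts.

# Moran's I as an explicit double sum.
moran_naive <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Population-weighted Gini as the explicit pairwise mean absolute difference.
gini_naive <- function(d, p) {
  n <- length(d)
  P <- sum(p)
  dbar <- sum(p * d) / P
  if (dbar == 0) return(0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + p[i] * p[j] * abs(d[i] - d[j])
  s / (2 * P^2 * dbar)
}

check_loss_naive <- function(r, tau) sum(r * (tau - (r < 0)))

# Global minimum of the quantile check loss over all "vertex" fits, i.e.
# coefficient vectors interpolating p observations. By LP theory the optimum
# of the full problem is attained at one of these.
rq_vertex_enum <- function(X, y, tau) {
  n <- nrow(X); p <- ncol(X)
  best <- Inf
  combs <- utils::combn(n, p)
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    Xh <- X[idx, , drop = FALSE]
    if (abs(det(Xh)) < 1e-10) next
    beta <- solve(Xh, y[idx])
    obj <- check_loss_naive(y - X %*% beta, tau)
    if (obj < best) best <- obj
  }
  best
}

# Mean local clustering coefficient by explicit triangle counting over an
# adjacency matrix (degree < 2 nodes contribute 0).
clustering_naive <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
  mean(vals)
}

# Distance to nearest green cell by exhaustive search.
distances_naive <- function(green) {
  nr <- nrow(green); nc <- ncol(green)
  gidx <- which(green, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    out[r, c] <- sqrt(min((gidx[, 1] - r)^2 + (gidx[, 2] - c)^2))
  }
  out
}

# Small random panel for estimator cross-checks.
random_small_panel <- function(n_units, n_periods, seed) {
  withr::with_seed(seed, {
    data.frame(
      unit = rep(letters[seq_len(n_units)], each = n_periods),
      year = rep(seq_len(n_periods), n_units),
      y = rnorm(n_units * n_periods),
      g = runif(n_units * n_periods),
      x1 = rnorm(n_units * n_periods)
    )
  })
}
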