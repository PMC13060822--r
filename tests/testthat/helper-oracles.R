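# Independent oracles used across the suite.  Everything here is written
# against the mathematical definitions, never by calling the package code
# under test.

# exhaustive sliding-window scan: best mean of log(1+x) over all contiguous
# windows of `width` minutes in one 1440-minute day
brute_window_mean <- function(day, width, maximize = TRUE) {
  lv <- log1p(day)
  means <- vapply(seq_len(length(lv) - width + 1L), function(s)
    mean(lv[s:(s + width - 1L)]), 0)
  if (maximize) max(means) else min(means)
}

# canonical correlations as singular values of the whitened cross-covariance,
# computed with plain solve() + eigen() (dense, no pseudo-inverse path)
brute_cca_rho <- function(X, Y) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc) / (n - 1)
  Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  isq <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*% t(e$vectors)
  }
  K <- isq(Sxx) %*% Sxy %*% isq(Syy)
  sort(svd(K)$d, decreasing = TRUE)[seq_len(min(ncol(X), ncol(Y)))]
}

# first canonical correlation by direct numerical maximization of
# corr(Xw, Yv): alternating least squares, which increases the objective at
# every half-step and converges to the global maximum for this bilinear
# problem; started from several random points for safety
brute_cca_rho1 <- function(X, Y, n_starts = 3L, iters = 200L) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  best <- 0
  for (s in seq_len(n_starts)) {
    v <- rnorm(ncol(Y))
    for (it in seq_len(iters)) {
      u_t <- Yc %*% v
      w <- qr.coef(qr(Xc), u_t)       # maximizes corr(Xw, Yv) over w
      w <- w / sqrt(sum(w^2))         # scale is irrelevant to correlation
      u_s <- Xc %*% w
      v <- qr.coef(qr(Yc), u_s)       # maximizes corr(Xw, Yv) over v
      v <- v / sqrt(sum(v^2))
    }
    r <- abs(as.numeric(cor(Xc %*% w, Yc %*% v)))
    if (!is.na(r) && r > best) best <- r
  }
  best
}

# Benjamini-Hochberg selection straight from the step-up definition:
# k* = max { i : p_(i) <= i * alpha / m }, select all p <= p_(k*)
brute_bh_select <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (!length(ok)) return(integer(0))
  sort(which(p <= ps[max(ok)]))
}

# Bernoulli log-likelihood from probabilities
brute_bernoulli_ll <- function(p, y) sum(y * log(p) + (1 - y) * log(1 - p))

# small residualized test blocks with a planted association
make_blocks <- function(n = 200, p = 4, q = 6, rho = 0, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * q), n, q)
  if (rho > 0) {
    c_ <- sqrt(rho / (1 - rho))
    X[, 1] <- X[, 1] + c_ * z
    Y[, 1] <- Y[, 1] + c_ * z
  }
  list(X = X, Y = Y)
}

# compact cohort config used by many tests
tiny_cohort <- function(n = 300, seed = 1, ...) {
  generate_cohort(cohort_config(n, n_fc_nodes = 8, n_gmv = 5, seed = seed, ...))
}
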