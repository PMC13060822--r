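#' Canonical correlation analysis of two centered blocks
#'
#' Estimates canonical correlations, coefficient vectors and unit-variance
#' canonical variates for two row-aligned data blocks.  The fit whitens
#' each within-block sample covariance through a spectral pseudo-inverse
#' square root (eigenvalues below a relative tolerance of 1e-10 are
#' truncated, so near-singular blocks degrade to their numerical rank
#' instead of exploding) and takes the singular value decomposition of the
#' whitened cross-covariance.  Mode signs are fixed so that each mode's
#' largest-magnitude X-side loading is positive; canonical signs are
#' otherwise arbitrary and a fixed orientation is required to interpret
#' loadings.
#'
#' @param X numeric matrix n x p (rows = participants).  Columns are
#'   centered internally.
#' @param Y numeric matrix n x q, same rows.
#' @return object of class `cca_fit`: list with `rho` (descending
#'   canonical correlations, length `min(p, q)` padded with zeros past the
#'   numerical rank), `a_coeffs` (p x k), `b_coeffs` (q x k), `U`, `V`
#'   (n x k unit-variance variates), `loadings_x`, `loadings_y`
#'   (variable-variate correlations), `n`, `p`, `q`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(600), 100, 6)
#' Y <- X[, 1:3] + matrix(rnorm(300), 100, 3)
#' fit <- fit_cca(X, Y)
#' fit$rho
#' @export
fit_cca <- function(X, Y) {
  X <- as_numeric_matrix(X)
  Y <- as_numeric_matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows", call. = FALSE)
  p <- ncol(X); q <- ncol(Y)
  if (n <= max(p, q)) {
    stop("need more rows than the larger block width", call. = FALSE)
  }
  if (any(apply(X, 2L, sd) == 0) || any(apply(Y, 2L, sd) == 0)) {
    stop("zero-variance column in an input block", call. = FALSE)
  }
  Xc <- center_cols(X)
  Yc <- center_cols(Y)
  Sxx <- crossprod(Xc) / (n - 1)
  Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)

  Wx <- pinv_sqrt(Sxx)
  Wy <- pinv_sqrt(Syy)
  K <- crossprod(Wx$half, Sxy %*% Wy$half)
  sv <- svd(K)
  k_eff <- min(Wx$rank, Wy$rank)
  k <- min(p, q)

  rho <- pmin(pmax(sv$d[seq_len(k_eff)], 0), 1)
  A <- Wx$half %*% sv$u[, seq_len(k_eff), drop = FALSE]
  B <- Wy$half %*% sv$v[, seq_len(k_eff), drop = FALSE]

  U <- Xc %*% A
  V <- Yc %*% B
  # whitening already gives unit population-scale variance; rescale to exact
  # unit sample variance for downstream variance-explained arithmetic
  su <- apply(U, 2L, sd); sv_ <- apply(V, 2L, sd)
  U <- sweep(U, 2L, su, "/"); A <- sweep(A, 2L, su, "/")
  V <- sweep(V, 2L, sv_, "/"); B <- sweep(B, 2L, sv_, "/")

  # sign convention: largest |X-side loading| positive per mode
  Lx <- suppressWarnings(cor(Xc, U))
  for (j in seq_len(k_eff)) {
    s <- sign(Lx[which.max(abs(Lx[, j])), j])
    if (is.na(s) || s == 0) s <- 1
    A[, j] <- s * A[, j]; U[, j] <- s * U[, j]
    B[, j] <- s * B[, j]; V[, j] <- s * V[, j]
    Lx[, j] <- s * Lx[, j]
  }

  pad <- function(M, kk) {
    if (ncol(M) >= kk) M[, seq_len(kk), drop = FALSE] else
      cbind(M, matrix(0, nrow(M), kk - ncol(M)))
  }
  structure(
    list(rho = c(rho, rep(0, k - k_eff)),
         a_coeffs = pad(A, k), b_coeffs = pad(B, k),
         U = pad(U, k), V = pad(V, k),
         loadings_x = pad(Lx, k),
         loadings_y = pad(suppressWarnings(cor(Yc, V)), k),
         n = n, p = p, q = q, rank = k_eff),
    class = "cca_fit"
  )
}

#' Bipartial canonical correlation analysis
#'
#' The full first-stage analysis: each block is residualized on its own
#' confounder set (intercept always included), optionally standardized to
#' correlation scale, and passed to [fit_cca()]; mode significance is then
#' assessed by the Bartlett chi-square approximation and, when `n_perm >
#' 0`, by permutation of the residualized X block.  Per-mode within-block
#' variance explained and cross-loadings of the X variables on the Y
#' variates (and vice versa) are attached.
#'
#' Because residualization can break the exchangeability that permutation
#' inference relies on for modes beyond the first, modes past the primary
#' one are flagged as caveated: they are computed and reported, but
#' interpretation should rest on the first mode.
#'
#' @param X n x p block (e.g. the 11 PA features).
#' @param Y n x q block (e.g. 1485 Fisher-z FC edges or 139 volumes).
#' @param confounders_x,confounders_y confounder matrices for each block
#'   (`NULL` = intercept only).
#' @param standardize scale residualized columns to unit SD before the fit
#'   (correlation-scale CCA, the default) or leave them on covariance
#'   scale.
#' @param n_perm number of permutations for the permutation test (0 skips
#'   it; at least 99 otherwise).
#' @param seed seed for the permutation draws.
#' @return object of class `bcca` extending `cca_fit` with `p_approx`,
#'   `p_perm`, `varexp_x`, `varexp_y`, `cross_loadings_x` (cor of X
#'   columns with V), `cross_loadings_y`, `n_perm`, `seed`, and the
#'   residualization records.
#' @examples
#' coh <- generate_cohort(cohort_config(300, n_fc_nodes = 8, n_gmv = 5, seed = 7))
#' fit <- bipartial_cca(coh$pa, coh$fc_edges,
#'                      confounders_x = coh$confounders,
#'                      confounders_y = coh$confounders,
#'                      n_perm = 99, seed = 1)
#' summary(fit)
#' @export
bipartial_cca <- function(X, Y, confounders_x = NULL, confounders_y = NULL,
                          standardize = TRUE, n_perm = 0L, seed = 1L) {
  X <- as_numeric_matrix(X)
  Y <- as_numeric_matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop("blocks are not row-aligned: X and Y differ in row count", call. = FALSE)
  }
  chk_rows <- function(G, nm) {
    if (!is.null(G) && nrow(as_numeric_matrix(G)) != nrow(X)) {
      stop(sprintf("blocks are not row-aligned: %s differs in row count", nm),
           call. = FALSE)
    }
  }
  chk_rows(confounders_x, "confounders_x")
  chk_rows(confounders_y, "confounders_y")

  rx <- residualize_block(X, confounders_x)
  ry <- residualize_block(Y, confounders_y)
  Xr <- rx$residuals
  Yr <- ry$residuals
  if (standardize) {
    Xr <- standardize_cols(Xr)
    Yr <- standardize_cols(Yr)
  }
  fit <- fit_cca(Xr, Yr)
  fit$p_approx <- approximation_test(fit$rho, fit$n, fit$p, fit$q)$p_value
  if (n_perm > 0L) {
    pt <- permutation_test(Xr, Yr, n_perm = n_perm, seed = seed)
    fit$p_perm <- pt$p_value
    fit$n_perm <- pt$n_perm
  } else {
    fit$p_perm <- rep(NA_real_, length(fit$rho))
    fit$n_perm <- 0L
  }
  fit$varexp_x <- variance_explained(Xr, fit$U)
  fit$varexp_y <- variance_explained(Yr, fit$V)
  fit$cross_loadings_x <- cross_loadings(Xr, fit$V[, 1L])
  fit$cross_loadings_y <- cross_loadings(Yr, fit$U[, 1L])
  fit$Xres <- Xr
  fit$Yres <- Yr
  fit$confounders_x <- rx$confounders
  fit$confounders_y <- ry$confounders
  fit$standardize <- standardize
  fit$seed <- as.integer(seed)
  class(fit) <- c("bcca", "cca_fit")
  fit
}

#' Bartlett approximation test for canonical modes
#'
#' For mode index s, tests the null that modes s, s+1, ... are all zero
#' via Wilks' Lambda_s = prod_{j >= s} (1 - rho_j^2), using Bartlett's
#' chi-square approximation: the statistic
#' `-(n - 1 - (p + q + 1)/2) * log(Lambda_s)` is referred to a chi-square
#' with `(p - s + 1)(q - s + 1)` degrees of freedom.
#'
#' For `method = "rao"`, Rao's F approximation of the same Wilks statistic
#' is used instead; it is exact in the single-pair case (p = q = 1, where
#' it reduces to the regression F-test) and slightly more accurate at
#' moderate n, at the cost of fractional denominator degrees of freedom.
#'
#' @param rho canonical correlations (descending), all strictly below 1.
#' @param n,p,q sample size and block widths; requires `n > p + q`.
#' @param method `"bartlett"` (chi-square, default) or `"rao"` (F).
#' @return list of class `cca_mode_test` with `method = "approximation"`,
#'   `statistic`, `df` (and `df2` for Rao), `p_value` (one entry per mode).
#' @export
approximation_test <- function(rho, n, p, q, method = c("bartlett", "rao")) {
  method <- match.arg(method)
  if (any(rho >= 1)) stop("degenerate canonical correlation of 1", call. = FALSE)
  if (n <= p + q) stop("approximation test needs n > p + q", call. = FALSE)
  k <- length(rho)
  stat <- df <- df2 <- pv <- numeric(k)
  for (s in seq_len(k)) {
    lam <- prod(1 - rho[s:k]^2)
    ps <- p - s + 1; qs <- q - s + 1
    df[s] <- ps * qs
    if (method == "bartlett") {
      mult <- n - 1 - (p + q + 1) / 2
      stat[s] <- -mult * log(lam)
      pv[s] <- pchisq(stat[s], df[s], lower.tail = FALSE)
    } else {
      tt <- if (ps^2 + qs^2 - 5 > 0) sqrt((ps^2 * qs^2 - 4) / (ps^2 + qs^2 - 5)) else 1
      mm <- (n - s + 1) - 1 - (ps + qs + 1) / 2
      df2[s] <- mm * tt - ps * qs / 2 + 1
      lam_t <- lam^(1 / tt)
      stat[s] <- (1 - lam_t) / lam_t * df2[s] / df[s]
      pv[s] <- pf(stat[s], df[s], df2[s], lower.tail = FALSE)
    }
  }
  out <- list(method = "approximation", approximation = method,
              statistic = stat, df = df, p_value = pv, n = n, p = p, q = q)
  if (method == "rao") out$df2 <- df2
  structure(out, class = "cca_mode_test")
}

#' Permutation test for canonical modes
#'
#' Permutes the rows of the (residualized) X block uniformly at random,
#' refits the CCA each draw, and reports per mode j the p-value
#' `(1 + #\{rho*_j >= rho_hat_j\}) / (n_perm + 1)`.  The X side is
#' permuted because it is the smaller block in the intended analyses.
#' Note that after residualization the permutation null is only exact for
#' the primary mode; higher modes carry an exchangeability caveat and a
#' warning is attached when they are reported.
#'
#' @param Xres,Yres residualized (and optionally standardized) blocks.
#' @param n_perm number of permutations, at least 99.
#' @param seed integer seed.
#' @return list of class `cca_mode_test` with `method = "permutation"`,
#'   `observed` rho, `p_value`, `n_perm`, `seed`, and the permutation null
#'   matrix `null_rho` (n_perm x k).
#' @export
permutation_test <- function(Xres, Yres, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) {
    stop("n_perm must be at least 99 for usable p-value resolution", call. = FALSE)
  }
  Xres <- as_numeric_matrix(Xres)
  Yres <- as_numeric_matrix(Yres)
  obs <- fit_cca(Xres, Yres)$rho
  k <- length(obs)
  n <- nrow(Xres)
  # permuting rows of X leaves both within-block covariances (hence the
  # whitening operators) unchanged; only the cross-covariance is refit
  Xc <- center_cols(Xres)
  Yc <- center_cols(Yres)
  Wx <- pinv_sqrt(crossprod(Xc) / (n - 1))$half
  Wy <- pinv_sqrt(crossprod(Yc) / (n - 1))$half
  XW <- Xc %*% Wx
  YW <- Yc %*% Wy
  k_eff <- min(ncol(XW), ncol(YW))
  null_rho <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      d <- svd(crossprod(XW[sample.int(n), , drop = FALSE], YW) / (n - 1),
               nu = 0, nv = 0)$d
      c(pmin(pmax(d[seq_len(k_eff)], 0), 1), rep(0, k - k_eff))
    }, numeric(k)))
  })
  pv <- (1 + colSums(null_rho >= rep(obs, each = n_perm))) / (n_perm + 1)
  structure(list(method = "permutation", observed = obs, p_value = pv,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 null_rho = null_rho),
            class = "cca_mode_test")
}

#' Per-mode within-block variance explained
#'
#' Proportion of a block's total variance carried by each canonical
#' variate: mode j explains
#' `sum_l cor(col_l, variate_j)^2 var(col_l) / sum_l var(col_l)`,
#' which reduces to the mean squared loading when the block is
#' standardized.  Summed over all modes of a block's own side the
#' proportions reach 1 (the variates span the column space).
#'
#' @param block residualized n x q matrix.
#' @param variates n x k matrix of unit-variance, mutually uncorrelated
#'   canonical variates.
#' @param tol tolerance for the orthonormality check.
#' @return numeric vector of k proportions.
#' @export
variance_explained <- function(block, variates, tol = 1e-6) {
  block <- as_numeric_matrix(block)
  variates <- as_numeric_matrix(variates)
  live <- apply(variates, 2L, sd) > 0   # zero-padded modes past the rank
  if (any(live)) {
    Vl <- variates[, live, drop = FALSE]
    cc <- crossprod(scale(Vl)) / (nrow(Vl) - 1)
    if (max(abs(cc - diag(ncol(Vl)))) > tol) {
      stop("variates must be unit-variance and mutually uncorrelated", call. = FALSE)
    }
  }
  v <- apply(block, 2L, var)
  out <- numeric(ncol(variates))
  for (j in which(live)) {
    r2 <- suppressWarnings(cor(block, variates[, j]))^2
    out[j] <- sum(r2 * v, na.rm = TRUE) / sum(v)
  }
  out
}

#' Cross-loadings of block variables on a canonical variate
#'
#' Pearson correlation of every column of a (residualized) block with one
#' canonical variate — e.g. each PA variable against the primary imaging
#' variate.  Zero-variance columns yield `NA` with a warning.
#'
#' @param block n x q matrix.
#' @param variate length-n vector.
#' @return named numeric vector of correlations.
#' @export
cross_loadings <- function(block, variate) {
  block <- as_numeric_matrix(block)
  if (length(variate) != nrow(block)) {
    stop("variate length must match block rows", call. = FALSE)
  }
  s <- apply(block, 2L, sd)
  if (any(s == 0)) warning("zero-variance column(s); loading reported as NA")
  out <- suppressWarnings(as.vector(cor(block, variate)))
  out[s == 0] <- NA_real_
  names(out) <- colnames(block)
  out
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("CCA fit: n=%d, p=%d, q=%d (rank %d)\n", x$n, x$p, x$q, x$rank))
  cat("Canonical correlations:\n")
  print(round(x$rho, 4))
  invisible(x)
}

#' @export
print.bcca <- function(x, ...) {
  cat(sprintf("Bipartial CCA: n=%d, p=%d, q=%d (%s scale)\n",
              x$n, x$p, x$q, if (x$standardize) "correlation" else "covariance"))
  cat(sprintf("Primary mode: rho = %.3f, approximation p = %.3g, permutation p = %s\n",
              x$rho[1L], x$p_approx[1L],
              if (x$n_perm > 0) format(x$p_perm[1L], digits = 3) else "not run"))
  invisible(x)
}

#' @export
summary.bcca <- function(object, ...) {
  k <- length(object$rho)
  tab <- data.frame(
    mode = seq_len(k),
    rho = object$rho,
    p_approx = object$p_approx,
    p_perm = object$p_perm,
    varexp_x = object$varexp_x,
    varexp_y = object$varexp_y
  )
  structure(list(table = tab, n = object$n, p = object$p, q = object$q,
                 n_perm = object$n_perm,
                 cross_loadings_x = object$cross_loadings_x),
            class = "summary.bcca")
}

#' @export
print.summary.bcca <- function(x, ...) {
  cat(sprintf("Bipartial CCA (n = %d, p = %d, q = %d)\n", x$n, x$p, x$q))
  print(format(x$table, digits = 3), row.names = FALSE)
  if (nrow(x$table) > 1L) {
    cat("Note: permutation inference past the primary mode may violate\n")
    cat("exchangeability after residualization; interpret mode 1 only.\n")
  }
  cat("\nCross-loadings of X variables on the primary Y variate:\n")
  print(round(x$cross_loadings_x, 3))
  invisible(x)
}

#' @export
coef.cca_fit <- function(object, side = c("x", "y"), ...) {
  side <- match.arg(side)
  if (side == "x") object$a_coeffs else object$b_coeffs
}

#' Scree-style plot of a bipartial CCA fit
#'
#' Left panel: canonical correlations by mode; right panel: per-mode
#' within-block variance explained for both sides.
#'
#' @param x a `bcca` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bcca <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  k <- length(x$rho)
  plot(seq_len(k), x$rho, type = "b", xlab = "mode",
       ylab = "canonical correlation", ylim = c(0, 1), ...)
  plot(seq_len(k), 100 * x$varexp_x, type = "b", xlab = "mode",
       ylab = "variance explained (%)", col = 2,
       ylim = c(0, 100 * max(x$varexp_x, x$varexp_y)))
  graphics::lines(seq_len(k), 100 * x$varexp_y, type = "b", col = 4)
  graphics::legend("topright", legend = c("X block", "Y block"),
                   col = c(2, 4), lty = 1, bty = "n")
  invisible(x)
}
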