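test_that("degenerate CCA cases have closed-form answers", {
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4)
  # Y identical to X: every mode correlates perfectly
  expect_equal(fit_cca(X, X)$rho, rep(1, 4), tolerance = 1e-8)
  # scalar blocks: the absolute Pearson correlation
  x <- rnorm(60); y <- 0.3 * x + rnorm(60)
  expect_equal(fit_cca(x, y)$rho, abs(cor(x, y)), tolerance = 1e-10)
  expect_error(fit_cca(matrix(rnorm(20), 4, 5), matrix(rnorm(8), 4, 2)),
               "more rows")
  Xz <- X; Xz[, 2] <- 7
  expect_error(fit_cca(Xz, X), "zero-variance")
})

test_that("canonical correlations match the dense whitened-SVD oracle and direct maximization", {
  for (s in 1:5) {
    b <- make_blocks(n = 200, p = 4, q = 6, rho = if (s %% 2) 0.5 else 0, seed = s)
    fit <- fit_cca(b$X, b$Y)
    expect_equal(fit$rho, brute_cca_rho(b$X, b$Y), tolerance = 1e-8)
    set.seed(s + 100)
    expect_equal(fit$rho[1], brute_cca_rho1(b$X, b$Y), tolerance = 1e-6)
  }
})

test_that("canonical correlations agree with stats::cancor", {
  b <- make_blocks(n = 150, p = 5, q = 7, rho = 0.4, seed = 9)
  expect_equal(fit_cca(b$X, b$Y)$rho, stats::cancor(b$X, b$Y)$cor,
               tolerance = 1e-8)
})

test_that("the fit is invariant to invertible within-block re-parameterization", {
  set.seed(12)
  b <- make_blocks(n = 300, p = 5, q = 5, rho = 0.5, seed = 12)
  A <- matrix(rnorm(25), 5, 5) + diag(5)          # invertible mixing
  B <- matrix(rnorm(25), 5, 5) + diag(5)
  f1 <- fit_cca(b$X, b$Y)
  f2 <- fit_cca(b$X %*% A, b$Y %*% B)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-6)
})

test_that("variates satisfy their defining identities", {
  b <- make_blocks(n = 250, p = 4, q = 6, rho = 0.5, seed = 3)
  fit <- fit_cca(b$X, b$Y)
  k <- length(fit$rho)
  for (j in seq_len(k)) {
    expect_equal(cor(fit$U[, j], fit$V[, j]), fit$rho[j], tolerance = 1e-8)
  }
  # unit variance, mutual uncorrelatedness within each side
  expect_equal(cov(fit$U), diag(k), tolerance = 1e-8)
  expect_equal(cov(fit$V), diag(k), tolerance = 1e-8)
  # sign convention: dominant X-side loading positive in every mode
  for (j in seq_len(k)) {
    lx <- fit$loadings_x[, j]
    expect_gte(lx[which.max(abs(lx))], 0)
  }
})

test_that("bipartial CCA with intercept-only confounders equals plain CCA", {
  b <- make_blocks(n = 150, p = 4, q = 5, rho = 0.5, seed = 6)
  fit0 <- fit_cca(standardize_cols(b$X), standardize_cols(b$Y))
  fitb <- bipartial_cca(b$X, b$Y)
  expect_equal(fitb$rho, fit0$rho, tolerance = 1e-10)
})

test_that("purely confounder-driven association vanishes after residualization", {
  set.seed(30)
  n <- 500
  G <- cbind(rnorm(n), rnorm(n))
  X <- G %*% matrix(rnorm(8), 2, 4) + matrix(rnorm(n * 4), n, 4)
  Y <- G %*% matrix(rnorm(12), 2, 6) + matrix(rnorm(n * 6), n, 6)
  naive <- fit_cca(X, Y)$rho[1]
  fitb <- bipartial_cca(X, Y, confounders_x = G, confounders_y = G)
  # naive CCA finds the confounder-induced association; bipartial kills it
  expect_gt(naive, 0.5)
  null_q95 <- quantile(replicate(50, {
    fit_cca(matrix(rnorm(n * 4), n, 4), matrix(rnorm(n * 6), n, 6))$rho[1]
  }), 0.95)
  expect_lt(fitb$rho[1], null_q95 + 0.05)
})

test_that("canonical variates are orthogonal to every confounder", {
  coh <- tiny_cohort(n = 400, seed = 8)
  G <- as.matrix(coh$confounders)
  fit <- bipartial_cca(coh$pa, coh$fc_edges, confounders_x = G, confounders_y = G)
  expect_lt(max(abs(cor(fit$U, G))), 1e-8)
  expect_lt(max(abs(cor(fit$V, G))), 1e-8)
  expect_lt(max(abs(cor(fit$Xres, G))), 1e-10)
  expect_lt(max(abs(cor(fit$Yres, G))), 1e-10)
})

test_that("Bartlett approximation test matches its arithmetic definition", {
  # all rho zero: Lambda = 1, statistic 0, p = 1
  t0 <- approximation_test(rep(0, 3), n = 100, p = 3, q = 5)
  expect_equal(t0$statistic, rep(0, 3))
  expect_equal(t0$p_value, rep(1, 3))

  rho <- c(0.6, 0.3, 0.1)
  tt <- approximation_test(rho, n = 200, p = 3, q = 7)
  mult <- 200 - 1 - (3 + 7 + 1) / 2
  for (s in 1:3) {
    lam_log <- sum(log1p(-rho[s:3]^2))            # independent log-sum
    expect_equal(tt$statistic[s], -mult * lam_log, tolerance = 1e-10)
    expect_equal(tt$df[s], (3 - s + 1) * (7 - s + 1))
    expect_equal(tt$p_value[s],
                 pchisq(-mult * lam_log, tt$df[s], lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(approximation_test(c(1, 0.2), 100, 2, 3), "degenerate")
  expect_error(approximation_test(c(0.5), 8, 4, 5), "n > p \\+ q")
})

test_that("Rao's F variant is exact in the scalar case and agrees with Bartlett asymptotically", {
  # p = q = 1: Rao reduces to the regression F-test of y on x
  set.seed(44)
  n <- 40
  x <- rnorm(n); y <- 0.4 * x + rnorm(n)
  r <- abs(cor(x, y))
  tr <- approximation_test(r, n, 1, 1, method = "rao")
  f_exact <- summary(lm(y ~ x))$fstatistic
  expect_equal(tr$statistic, unname(f_exact[1]), tolerance = 1e-10)
  expect_equal(tr$df2, n - 2)
  expect_equal(tr$p_value,
               pf(f_exact[1], 1, n - 2, lower.tail = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
  # large n: the two approximations give near-identical p-values
  rho <- c(0.25, 0.1)
  pb <- approximation_test(rho, 5000, 2, 6)$p_value
  pr <- approximation_test(rho, 5000, 2, 6, method = "rao")$p_value
  expect_equal(pb, pr, tolerance = 1e-3)
})

test_that("permutation test separates planted signal from null and is seeded", {
  b <- make_blocks(n = 2000, p = 4, q = 6, rho = 0.5, seed = 14)
  Xr <- residualize_block(b$X)$residuals
  Yr <- residualize_block(b$Y)$residuals
  pt <- permutation_test(Xr, Yr, n_perm = 999, seed = 5)
  expect_equal(pt$p_value[1], 1 / 1000)           # minimum attainable
  expect_true(all(pt$p_value >= 1 / 1000))
  pt2 <- permutation_test(Xr, Yr, n_perm = 999, seed = 5)
  expect_identical(pt$p_value, pt2$p_value)
  expect_error(permutation_test(Xr, Yr, n_perm = 50), "at least 99")
})

test_that("variance explained matches per-column regression and completes to one", {
  set.seed(21)
  # single-column block: proportion is the squared correlation
  y1 <- matrix(rnorm(100), 100, 1)
  u <- matrix(scale(y1 + rnorm(100)), 100, 1)
  expect_equal(variance_explained(y1, u), cor(y1, u)[1]^2, tolerance = 1e-10)

  b <- make_blocks(n = 20, p = 5, q = 5, rho = 0, seed = 22)
  fit <- fit_cca(b$X, b$Y)
  ve <- variance_explained(b$X, fit$U)
  # brute force: per-column R2 of the regression on variate j, aggregated
  # with variance weights
  v <- apply(b$X, 2, var)
  for (j in 1:5) {
    r2 <- vapply(1:5, function(l) summary(lm(b$X[, l] ~ fit$U[, j]))$r.squared, 0)
    expect_equal(ve[j], sum(r2 * v) / sum(v), tolerance = 1e-8)
  }
  # own-side modes span the block: cumulative variance explained is 1
  expect_equal(sum(ve), 1, tolerance = 1e-8)
  # non-orthogonal variates are rejected
  expect_error(variance_explained(b$X, cbind(fit$U[, 1], fit$U[, 1] + 0.5 * fit$U[, 2])),
               "uncorrelated")
})

test_that("cross-loadings are plain Pearson correlations with NA for dead columns", {
  set.seed(25)
  B <- matrix(rnorm(200), 50, 4)
  v <- B[, 2]
  cl <- cross_loadings(B, v)
  expect_equal(cl[2], 1, ignore_attr = TRUE)
  expect_equal(unname(cl), as.vector(cor(B, v)), tolerance = 1e-12)
  # orthogonal variate: loadings near zero
  vo <- residualize_block(matrix(rnorm(50), 50, 1), B)$residuals
  expect_lt(max(abs(cross_loadings(B, vo))), 1e-8)
  Bz <- B; Bz[, 3] <- 1
  expect_warning(clz <- cross_loadings(Bz, v), "zero-variance")
  expect_true(is.na(clz[3]))
  expect_error(cross_loadings(B, v[1:10]), "length")
})

test_that("bipartial_cca enforces row alignment and records the analysis", {
  coh <- tiny_cohort(n = 200, seed = 2)
  expect_error(bipartial_cca(coh$pa[1:100, ], coh$fc_edges), "row-aligned")
  expect_error(bipartial_cca(coh$pa, coh$fc_edges,
                             confounders_x = coh$confounders[1:50, ]),
               "row-aligned")
  fit <- bipartial_cca(coh$pa, coh$fc_edges, coh$confounders, coh$confounders,
                       n_perm = 99, seed = 4)
  expect_s3_class(fit, "bcca")
  expect_length(fit$p_perm, 11)
  expect_length(fit$p_approx, 11)
  s <- summary(fit)
  expect_s3_class(s, "summary.bcca")
  expect_output(print(s), "exchangeability")
  expect_equal(dim(coef(fit, "x")), c(11L, 11L))
})
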