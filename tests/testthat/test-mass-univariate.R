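test_that("BH selection follows the step-up definition on a worked example", {
  p <- c(0.001, 0.013, 0.9)
  expect_equal(brute_bh_select(p, 0.05), c(1L, 2L))
  expect_equal(which(p.adjust(p, "BH") <= 0.05), c(1L, 2L))
})

test_that("partial F screening matches an independent two-model RSS computation", {
  set.seed(5)
  n <- 150
  G <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  H <- matrix(rnorm(n * 4), n, 4)
  Y <- cbind(H %*% c(1, 0.5, 0, 0) + rnorm(n),        # PA-driven
             G %*% c(2, 1) + rnorm(n),                # confounder-driven only
             rnorm(n))                                # pure noise
  scr <- screen_responses(Y, G, H)
  # oracle: explicit lm fits and anova partial F per response
  for (l in 1:3) {
    full <- lm(Y[, l] ~ G + H)
    red <- lm(Y[, l] ~ G)
    a <- anova(red, full)
    expect_equal(scr$p_value[l], a$`Pr(>F)`[2], tolerance = 1e-10)
    expect_equal(scr$f_statistic[l], a$F[2], tolerance = 1e-10)
  }
  expect_equal(p.adjust(scr$p_value, "BH"), scr$p_adjusted)
  expect_true(1 %in% scr$selected)        # planted response found
  expect_false(2 %in% scr$selected)       # confounder-only response excluded
})

test_that("a response that is an exact function of the PA block floors its p-value", {
  set.seed(6)
  n <- 100
  G <- matrix(rnorm(n), n, 1)
  H <- matrix(rnorm(n * 3), n, 3)
  Y <- cbind(H %*% c(1, -1, 2), rnorm(n))
  scr <- screen_responses(Y, G, H)
  expect_lt(scr$p_adjusted[1], 1e-20)
  expect_true(1 %in% scr$selected)
})

test_that("null PA blocks keep the selection rate at the FDR level", {
  set.seed(7)
  n <- 200; q <- 40
  G <- matrix(rnorm(n * 2), n, 2)
  H <- matrix(rnorm(n * 5), n, 5)
  Y <- G %*% matrix(rnorm(2 * q), 2, q) + matrix(rnorm(n * q), n, q)
  scr <- screen_responses(Y, G, H)
  expect_lt(length(scr$selected), 4)       # BH controls false discoveries
  # raw p-values roughly uniform
  expect_gt(ks.test(scr$p_value, "punif")$p.value, 0.01)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  set.seed(8)
  G <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("g1", "g2")))
  H <- cbind(a = rnorm(30), b = rnorm(30))
  H <- cbind(H, dup = H[, "a"])
  expect_error(screen_responses(matrix(rnorm(30), 30, 1), G, H),
               "rank deficient.*dup")
  expect_error(importance_ttest(matrix(rnorm(30), 30, 1), G, H),
               "rank deficient")
})

test_that("CV predictive correlation recovers signal, vanishes on noise, and is seeded", {
  set.seed(9)
  n <- 1000
  X <- matrix(rnorm(n * 3), n, 3)
  y_signal <- X %*% c(1, 2, 1)                     # noiseless linear response
  r_sig <- cv_predictive_correlation(y_signal, X, n_reps = 3, seed = 1)
  expect_gt(r_sig$mean, 0.999)
  y_noise <- rnorm(n)
  r_noise <- cv_predictive_correlation(y_noise, X, n_reps = 5, seed = 2)
  expect_lt(abs(r_noise$mean), 0.05)
  r_again <- cv_predictive_correlation(y_noise, X, n_reps = 5, seed = 2)
  expect_identical(r_noise$per_rep, r_again$per_rep)
  expect_error(cv_predictive_correlation(y_noise[1:15], X[1:15, ]), "n_folds")
})

test_that("t-test importance scores single out a planted PA variable", {
  set.seed(10)
  n <- 500
  G <- matrix(rnorm(n * 2), n, 2)
  H <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("pa", 1:6)))
  Y <- cbind(2 * H[, 3] + rnorm(n), 2 * H[, 3] + rnorm(n))
  it <- importance_ttest(Y, G, H)
  expect_equal(it$method, "ttest")
  for (l in 1:2) expect_equal(which.max(it$scores[l, ]), c(pa3 = 3L))
  # null scores stay modest while the planted one dominates
  expect_gt(min(it$scores[, 3]), max(it$scores[, -3]))
})

test_that("stepwise BIC selects exactly the strong predictor and is deterministic", {
  set.seed(11)
  n <- 2000
  G <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "conf"))
  H <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("pa", 1:5)))
  y <- 0.5 * G[, 1] + 1 * H[, 2] + rnorm(n)
  ib <- importance_stepwise_bic(matrix(y), G, H)
  expect_equal(unname(ib$scores[1, ]), c(0, 1, 0, 0, 0))
  ib2 <- importance_stepwise_bic(matrix(y), G, H)
  expect_identical(ib$scores, ib2$scores)
  # null PA block at large n: BIC's consistency keeps the model empty
  y0 <- G[, 1] + rnorm(n)
  ib0 <- importance_stepwise_bic(matrix(y0), G, H)
  expect_equal(sum(ib0$scores), 0)
})

test_that("random-forest importance detects a nonlinear planted effect and is seeded", {
  set.seed(12)
  n <- 400
  G <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "conf"))
  H <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("pa", 1:5)))
  y <- H[, 4]^2 + 0.5 * rnorm(n)                   # quadratic: invisible to lm
  irf <- importance_random_forest(matrix(y), G, H, n_trees = 200, seed = 3)
  expect_equal(which.max(irf$scores[1, ]), c(pa4 = 4L))
  irf2 <- importance_random_forest(matrix(y), G, H, n_trees = 200, seed = 3)
  expect_identical(irf$scores, irf2$scores)
  expect_error(importance_random_forest(matrix(y), G, H, n_trees = 10),
               "at least 100")
  Yz <- cbind(y, 1)
  expect_warning(irfz <- importance_random_forest(Yz, G, H, n_trees = 100, seed = 1),
                 "zero variance")
  expect_true(all(is.na(irfz$scores[2, ])))
})

test_that("consensus ranking averages per-method ranks", {
  sc <- matrix(c(3, 2, 1), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  t1 <- pabrain:::new_importance_table(sc, "m1")
  t2 <- pabrain:::new_importance_table(sc, "m2")
  cons <- consensus_ranking(list(t1, t2))
  expect_equal(cons$variable, c("a", "b", "c"))    # identical tables keep order
  expect_equal(cons$mean_rank, c(1, 2, 3))
  # one method reversed: every variable lands mid-rank
  t3 <- pabrain:::new_importance_table(sc[, 3:1, drop = FALSE][, c("c","b","a")], "m3")
  t3$scores <- matrix(c(1, 2, 3), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  cons2 <- consensus_ranking(list(t1, t3))
  expect_equal(unique(cons2$mean_rank), 2)
  bad <- pabrain:::new_importance_table(matrix(1, 1, 2, dimnames = list(NULL, c("x", "y"))), "m4")
  expect_error(consensus_ranking(list(t1, bad)), "disagree")
  expect_error(consensus_ranking(list(t1)), "at least two")
})
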