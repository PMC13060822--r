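test_that("the empirical ROC has the required geometry and exact AUC", {
  set.seed(1)
  y <- rbinom(100, 1, 0.3)
  # probabilities equal to the labels: perfect separation
  expect_equal(roc_curve(y, y)$auc, 1)
  # all-tied scores: the diagonal, AUC 1/2
  r_tied <- roc_curve(rep(0.4, 100), y)
  expect_equal(r_tied$auc, 0.5)
  expect_equal(r_tied$fpr, c(0, 1))
  expect_equal(r_tied$tpr, c(0, 1))
  # geometry: starts (0,0), ends (1,1), TPR non-decreasing
  p <- runif(100)
  rc <- roc_curve(p, y)
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(rc$fpr[length(rc$fpr)], rc$tpr[length(rc$tpr)]), c(1, 1))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_true(all(diff(rc$fpr) >= 0))
  # AUC invariant under strictly increasing transforms, exactly
  expect_identical(rc$auc, roc_curve(qlogis(p), y)$auc)
  expect_identical(rc$auc, roc_curve(p^3, y)$auc)
  expect_error(roc_curve(p, rep(1, 100)), "both classes")
})

test_that("the empirical AUC agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(2)
  y <- rbinom(300, 1, 0.2)
  p <- plogis(y + rnorm(300))
  expect_equal(roc_curve(p, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("vertical ROC averaging integrates close to the mean of per-rep AUCs", {
  set.seed(3)
  n <- 500
  y <- rbinom(n, 1, 0.15)
  probs <- t(replicate(20, plogis(2 * y - 1 + rnorm(n))))
  mr <- mean_roc_auc(probs, y)
  expect_lt(abs(mr$auc - mean(mr$auc_per_rep)), 0.005)
  expect_true(all(diff(mr$tpr) >= 0))
  # single repetition: reduces to that repetition's (interpolated) curve
  m1 <- mean_roc_auc(probs[1, ], y)
  expect_equal(m1$auc, mr$auc_per_rep[1], tolerance = 0.005)
})

test_that("McFadden pseudo-R2 matches hand-computed likelihood arithmetic", {
  # toy 4-observation data: y = (1,0,1,1); null fit p0 = 3/4 each;
  # model probabilities chosen by hand
  y <- c(1, 0, 1, 1)
  p0 <- rep(3 / 4, 4)
  pm <- c(0.9, 0.2, 0.8, 0.7)
  expected <- 1 - brute_bernoulli_ll(pm, y) / brute_bernoulli_ll(p0, y)
  expect_equal(mcfadden_r2(pm, p0, y), expected, tolerance = 1e-10)
  # model equal to null: exactly zero
  expect_identical(mcfadden_r2(p0, p0, y), 0)
  # perfect probabilities: exactly one (correct-side boundaries contribute 0)
  expect_identical(mcfadden_r2(y, p0, y), 1)
  # an opposite-label boundary probability is clipped with a warning
  expect_warning(r2c <- mcfadden_r2(c(0, 0.2, 0.8, 0.7), p0, y), "clipped")
  expect_true(is.finite(r2c))
})

test_that("degenerate null likelihood is rejected", {
  y <- c(1, 1, 1, 0)
  # null probabilities exactly equal to the labels: l(M0) = 0
  expect_error(mcfadden_r2(c(.5, .5, .5, .5), c(1, 1, 1, 0), y), "degenerate")
})

test_that("full-data nested logistic fits honor nesting and detect separation", {
  set.seed(4)
  n <- 800
  conf <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("c1", "c2")))
  pa <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
  idp <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("i", 1:4)))
  # pure-noise outcome: slopes near zero, intercept = logit(prevalence)
  y0 <- rbinom(n, 1, 0.3)
  f0 <- fit_nested_logistic(y0, conf, pa, idp)
  m0 <- f0$fits$M0
  # null signal: slopes near zero, intercept near logit(prevalence)
  expect_lt(max(abs(coef(m0)[-1])), 0.2)
  expect_equal(unname(coef(m0)[1]), qlogis(mean(y0)), tolerance = 0.05)
  # training-data monotonicity of McFadden across nested models
  y <- rbinom(n, 1, plogis(-1 + pa %*% c(1, -1, 0)))
  f <- fit_nested_logistic(y, conf, pa, idp)
  expect_gte(f$r2_training[["M1"]], f$r2_training[["M2"]] - 1e-10)
  expect_gte(f$r2_training[["M1"]], f$r2_training[["M3"]] - 1e-10)
  expect_identical(f$r2_training[["M0"]], 0)
  # PA-driven outcome: the PA submodel dominates the imaging submodel
  expect_gt(f$r2_training[["M2"]], f$r2_training[["M3"]])
  # perfectly separable toy data raises the separation flag (with a warning)
  ys <- as.integer(conf[, 1] > 0)
  fs <- NULL
  ws <- capture_warnings(fs <- fit_nested_logistic(ys, conf, pa[, 1, drop = FALSE]))
  expect_true(any(grepl("separation", ws)))
  expect_true(fs$diagnostics$M0$separation || fs$diagnostics$M2$separation)
  expect_error(fit_nested_logistic(rep(1, 50), conf[1:50, ], pa[1:50, ]),
               "both classes")
})

test_that("repeated CV assigns one out-of-fold probability per participant and is seeded", {
  set.seed(5)
  coh <- tiny_cohort(n = 300, seed = 16)
  y <- coh$disease[, "cancer"]
  cv <- repeated_cv_risk(y, as.matrix(coh$confounders), coh$pa, coh$gmv,
                         n_reps = 2, seed = 9)
  expect_setequal(cv$models, c("M0", "M1", "M2", "M3"))
  for (m in cv$models) expect_false(anyNA(cv$prob[[m]]))
  # folds stratified: every fold contains both classes in training
  for (r in 1:2) {
    tab <- table(cv$folds[r, ], y)
    expect_true(all(rowSums(tab > 0) > 0))
  }
  cv2 <- repeated_cv_risk(y, as.matrix(coh$confounders), coh$pa, coh$gmv,
                          n_reps = 2, seed = 9)
  expect_identical(cv$prob, cv2$prob)
  # n_reps = 1 is plain 10-fold CV
  cv1 <- repeated_cv_risk(y, as.matrix(coh$confounders), coh$pa, NULL,
                          n_reps = 1, seed = 1)
  expect_equal(nrow(cv1$prob$M0), 1L)
})

test_that("nested_risk produces coherent AUCs, pseudo-R2 and ROC curves", {
  coh <- tiny_cohort(n = 500, seed = 18)
  nr <- nested_risk(coh$disease[, "cancer"], coh$confounders, coh$pa,
                    coh$gmv, n_reps = 3, seed = 2)
  expect_true(all(nr$auc >= 0 & nr$auc <= 1))
  expect_identical(unname(nr$r2_mcfadden["M0"]), 0)
  for (m in nr$models) {
    expect_true(all(diff(nr$roc[[m]]$tpr) >= -1e-12))
    expect_lt(abs(nr$auc[[m]] - mean(nr$auc_per_rep[[m]])), 0.005)
  }
  expect_output(print(nr), "Nested risk models")
})

test_that("the disease panel reproduces the planted PA-over-imaging ordering", {
  strong <- list(dz = list(prevalence = 0.12,
                           beta_conf = c(0.3, 0.3, 0),
                           beta_pa = c(-0.8, 0, -0.5, 0.5, 0, 0, 0.3, 0, -0.5, 0, 0),
                           beta_idp = 0))
  coh <- generate_cohort(cohort_config(900, n_fc_nodes = 8, n_gmv = 5,
                                       seed = 41, disease_spec = strong))
  panel <- run_disease_panel(coh, idp = "gmv", n_reps = 2, seed = 3)
  tab <- panel$table
  r2 <- setNames(tab$r2_mcfadden, tab$model)
  expect_gt(r2[["M2"]], r2[["M3"]])
  expect_output(print(panel), "risk panel")
  expect_error(run_disease_panel(coh, diseases = "nope"), "not present")
})
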