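#' Empirical ROC curve
#'
#' Builds the empirical ROC of a score vector against binary labels:
#' thresholds sweep the unique scores from high to low, ties share a
#' vertex (so the curve's trapezoidal area equals the Mann-Whitney AUC
#' with half-credit for ties).  The curve starts at (0,0) and ends at
#' (1,1) with TPR non-decreasing in FPR.
#'
#' @param prob numeric risk scores.
#' @param y 0/1 labels with both classes present.
#' @return object of class `roc_curve`: list with `fpr`, `tpr` (vertex
#'   coordinates) and `auc` (trapezoidal area).
#' @export
roc_curve <- function(prob, y) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L) {
    stop("y must be 0/1 with both classes present", call. = FALSE)
  }
  if (length(prob) != length(y)) stop("prob and y lengths differ", call. = FALSE)
  ord <- order(prob, decreasing = TRUE)
  ps <- prob[ord]; ys <- y[ord]
  # cumulative counts at each distinct threshold (ties collapse to one vertex)
  last <- c(ps[-1] != ps[-length(ps)], TRUE)
  tp <- cumsum(ys)[last]
  fp <- cumsum(1L - ys)[last]
  npos <- sum(y); nneg <- length(y) - npos
  fpr <- c(0, fp / nneg)
  tpr <- c(0, tp / npos)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d vertices, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

# TPR of a ROC curve at arbitrary FPR values, by linear interpolation of
# the vertex polyline (the same polyline the trapezoidal AUC integrates)
roc_interpolate <- function(roc, fpr_grid) {
  stats::approx(roc$fpr, roc$tpr, xout = fpr_grid, ties = max,
                yleft = 0, yright = 1)$y
}

#' Vertically averaged ROC and its AUC
#'
#' Given per-repetition risk scores (pooled out-of-fold probabilities
#' from repeated cross-validation), builds each repetition's empirical
#' ROC, averages the true-positive rates vertically on a fixed
#' false-positive-rate grid, and integrates the mean curve numerically
#' (trapezoid) for the reported AUC.  The per-repetition exact
#' (Mann-Whitney) AUCs are retained; averaging those is equivalent to the
#' mean-curve AUC up to grid interpolation error.
#'
#' @param prob_reps numeric matrix (repetitions x participants) of risk
#'   scores, or a vector for a single repetition.
#' @param y 0/1 labels.
#' @param fpr_grid grid for vertical averaging (default 1001 equally
#'   spaced points on [0, 1]).
#' @return list with `fpr` (the grid), `tpr` (mean curve), `auc`
#'   (integral of the mean curve), `auc_per_rep` (exact per-repetition
#'   AUCs) and `n_reps`.
#' @export
mean_roc_auc <- function(prob_reps, y, fpr_grid = seq(0, 1, length.out = 1001L)) {
  if (is.null(dim(prob_reps))) prob_reps <- matrix(prob_reps, nrow = 1L)
  n_reps <- nrow(prob_reps)
  tpr_sum <- numeric(length(fpr_grid))
  auc_rep <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    roc <- roc_curve(prob_reps[r, ], y)
    tpr_sum <- tpr_sum + roc_interpolate(roc, fpr_grid)
    auc_rep[r] <- roc$auc
  }
  tpr_mean <- tpr_sum / n_reps
  auc <- sum(diff(fpr_grid) * (head(tpr_mean, -1) + tpr_mean[-1]) / 2)
  list(fpr = fpr_grid, tpr = tpr_mean, auc = auc,
       auc_per_rep = auc_rep, n_reps = n_reps)
}

#' McFadden pseudo-R-squared from predicted probabilities
#'
#' `1 - l(M) / l(M0)` where `l` is the Bernoulli log-likelihood of the
#' labels under the model's and the confounders-only null's predicted
#' probabilities on the same evaluation data.  Probabilities are clipped
#' to `[1e-12, 1 - 1e-12]` (with a warning when clipping bites) so a
#' boundary prediction with the opposite label does not produce an
#' infinite likelihood.
#'
#' @param prob model predicted probabilities.
#' @param prob_null null-model predicted probabilities (confounders
#'   only), same evaluation rows.
#' @param y 0/1 labels.
#' @return scalar pseudo-R-squared; exactly 0 when `prob` equals
#'   `prob_null`.
#' @export
mcfadden_r2 <- function(prob, prob_null, y) {
  y <- as.integer(y)
  ll <- function(p) {
    # a boundary probability on the correct side contributes exactly 0;
    # only opposite-label boundary probabilities need clipping
    bad <- (p <= 0 & y == 1) | (p >= 1 & y == 0)
    if (any(bad)) {
      warning("boundary probabilities with opposite labels clipped to (1e-12, 1-1e-12)")
      p[bad] <- pmin(pmax(p[bad], 1e-12), 1 - 1e-12)
    }
    sum(ifelse(y == 1L, log(p), log1p(-p)))
  }
  l0 <- ll(prob_null)
  if (l0 == 0) stop("degenerate null model log-likelihood of 0", call. = FALSE)
  1 - ll(prob) / l0
}

# stratified fold labels: cases and controls are split into folds
# separately so every training set sees both classes
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

# principal-component reduction of the IDP block learned on training rows
# only: returns the training/test scores for components reaching
# `var_frac` of the training variance
fold_pca_reduce <- function(idp_train, idp_test, var_frac) {
  pc <- prcomp(idp_train, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- max(1L, which(cum >= var_frac)[1L])
  k <- min(k, max(1L, nrow(idp_train) - 2L))
  list(train = pc$x[, seq_len(k), drop = FALSE],
       test = scale(idp_test, center = pc$center, scale = FALSE) %*%
         pc$rotation[, seq_len(k), drop = FALSE],
       k = k)
}

# logistic fit + prediction used inside CV folds; returns test probabilities
glm_prob <- function(X_train, y_train, X_test) {
  df_tr <- data.frame(.y = y_train, X_train, check.names = FALSE)
  fit <- suppressWarnings(glm(.y ~ ., data = df_tr, family = binomial()))
  as.vector(predict(fit, newdata = data.frame(X_test, check.names = FALSE),
                    type = "response"))
}

#' Fit the nested logistic models on the full data
#'
#' M0: confounders only (null); M1: confounders + PA + imaging (full);
#' M2: confounders + PA; M3: confounders + imaging.  Fits are
#' maximum-likelihood [stats::glm()] fits; non-convergence and complete
#' or quasi-complete separation (fitted probabilities numerically at 0/1)
#' are detected and reported in the `diagnostics` element.  When the
#' imaging block is wider than `max(20, n/20)` columns it is reduced to
#' principal components retaining `pca_var` of its variance, keeping the
#' unpenalized fits well posed; M1 and M3 share the reduction so the
#' models stay nested.
#'
#' @param y 0/1 disease labels.
#' @param conf confounder matrix.
#' @param pa PA feature matrix.
#' @param idp imaging block (FC edges or volumes); `NULL` drops M1/M3.
#' @param pca_var variance fraction retained by the imaging reduction.
#' @return object of class `nested_logistic`: list of `glm` fits
#'   (`M0`, `M1`, `M2`, `M3`), training-data McFadden values
#'   `r2_training`, and `diagnostics`.
#' @export
fit_nested_logistic <- function(y, conf, pa, idp = NULL, pca_var = 0.9) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes", call. = FALSE)
  if (sum(y) < 10L) warning(sprintf("only %d events; fits may be unstable", sum(y)))
  conf <- as_numeric_matrix(conf)
  pa <- as_numeric_matrix(pa)
  n <- length(y)
  designs <- list(M0 = conf, M2 = cbind(conf, pa))
  if (!is.null(idp)) {
    idp <- as_numeric_matrix(idp)
    if (ncol(idp) > max(20L, n %/% 20L)) {
      red <- fold_pca_reduce(idp, idp, pca_var)
      idp <- red$train
      colnames(idp) <- paste0("IDPPC", seq_len(ncol(idp)))
    }
    designs$M3 <- cbind(conf, idp)
    designs$M1 <- cbind(conf, pa, idp)
  }
  fits <- list(); diag_ <- list()
  for (m in names(designs)) {
    df <- data.frame(.y = y, designs[[m]], check.names = FALSE)
    w <- NULL
    fit <- withCallingHandlers(
      glm(.y ~ ., data = df, family = binomial()),
      warning = function(cnd) {
        w <<- conditionMessage(cnd)
        invokeRestart("muffleWarning")
      })
    sep <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
    if (sep) {
      warning(sprintf("model %s shows (quasi-)complete separation; coefficients are unreliable", m))
    } else if (!fit$converged) {
      stop(sprintf("model %s did not converge", m), call. = FALSE)
    }
    diag_[[m]] <- list(converged = fit$converged, separation = sep, warning = w)
    fits[[m]] <- fit
  }
  p0 <- fits$M0$fitted.values
  r2 <- vapply(fits, function(f) mcfadden_r2(f$fitted.values, p0, y), 0)
  structure(list(fits = fits, r2_training = r2, diagnostics = diag_,
                 n = n, events = sum(y)),
            class = "nested_logistic")
}

#' @export
print.nested_logistic <- function(x, ...) {
  cat(sprintf("Nested logistic models: n = %d, events = %d\n", x$n, x$events))
  cat("Training-data McFadden pseudo-R2:\n")
  print(round(x$r2_training[order(names(x$r2_training))], 4))
  sep <- names(Filter(function(d) isTRUE(d$separation), x$diagnostics))
  if (length(sep)) cat("Separation detected in:", paste(sep, collapse = ", "), "\n")
  invisible(x)
}

#' Repeated cross-validated out-of-fold risk probabilities
#'
#' Runs `n_reps` repetitions of stratified `n_folds`-fold
#' cross-validation.  Within each repetition every participant receives
#' exactly one out-of-fold predicted probability per model; the split is
#' shared across M0-M3 so the models are compared on identical folds.
#' The imaging reduction (principal components to `pca_var` variance) is
#' re-learned inside each training fold, keeping the evaluation honest.
#'
#' @inheritParams fit_nested_logistic
#' @param n_folds folds per repetition (default 10).
#' @param n_reps repetitions (default 100).
#' @param seed integer seed for all splits.
#' @param reduce_idp force (TRUE) or suppress (FALSE) the PCA reduction;
#'   default `NULL` reduces only when the imaging block is wide.
#' @return list with `prob` — a named list of (n_reps x n) matrices per
#'   model — plus `models`, `folds` assignments, and the call settings.
#' @export
repeated_cv_risk <- function(y, conf, pa, idp = NULL, n_folds = 10L,
                             n_reps = 100L, seed = 1L, pca_var = 0.9,
                             reduce_idp = NULL) {
  y <- as.integer(y)
  n <- length(y)
  if (n < 2L * n_folds) stop("need n >= 2 * n_folds", call. = FALSE)
  if (min(sum(y), n - sum(y)) < n_folds) {
    stop("too few members of the rarer class for stratified folds", call. = FALSE)
  }
  conf <- as_numeric_matrix(conf)
  pa <- as_numeric_matrix(pa)
  has_idp <- !is.null(idp)
  if (has_idp) {
    idp <- as_numeric_matrix(idp)
    if (is.null(reduce_idp)) reduce_idp <- ncol(idp) > max(20L, n %/% 20L)
  }
  models <- if (has_idp) c("M0", "M1", "M2", "M3") else c("M0", "M2")
  prob <- lapply(setNames(models, models),
                 function(m) matrix(NA_real_, n_reps, n))
  folds <- matrix(0L, n_reps, n)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      fold <- stratified_folds(y, n_folds)
      folds[r, ] <- fold
      for (f in seq_len(n_folds)) {
        te <- fold == f
        tr <- !te
        blocks_tr <- list(conf = conf[tr, , drop = FALSE],
                          pa = pa[tr, , drop = FALSE])
        blocks_te <- list(conf = conf[te, , drop = FALSE],
                          pa = pa[te, , drop = FALSE])
        if (has_idp) {
          if (reduce_idp) {
            red <- fold_pca_reduce(idp[tr, , drop = FALSE],
                                   idp[te, , drop = FALSE], pca_var)
            blocks_tr$idp <- red$train; blocks_te$idp <- red$test
            colnames(blocks_tr$idp) <- colnames(blocks_te$idp) <-
              paste0("IDPPC", seq_len(ncol(red$train)))
          } else {
            blocks_tr$idp <- idp[tr, , drop = FALSE]
            blocks_te$idp <- idp[te, , drop = FALSE]
          }
        }
        parts <- list(M0 = "conf", M1 = c("conf", "pa", "idp"),
                      M2 = c("conf", "pa"), M3 = c("conf", "idp"))
        for (m in models) {
          Xtr <- do.call(cbind, blocks_tr[parts[[m]]])
          Xte <- do.call(cbind, blocks_te[parts[[m]]])
          prob[[m]][r, te] <- glm_prob(Xtr, y[tr], Xte)
        }
      }
    }
  })
  list(prob = prob, models = models, folds = folds, y = y,
       n_folds = as.integer(n_folds), n_reps = as.integer(n_reps),
       seed = as.integer(seed),
       pca_var = pca_var, reduced = if (has_idp) reduce_idp else FALSE)
}

#' Nested logistic disease-risk analysis for one outcome
#'
#' The full third-stage analysis for one disease: repeated stratified
#' 10-fold cross-validation of the nested logistic models M0 (confounders
#' only), M1 (confounders + PA + imaging), M2 (confounders + PA) and M3
#' (confounders + imaging); per model, the vertically averaged ROC curve
#' with its numerically integrated AUC, and the test-set McFadden
#' pseudo-R-squared per repetition (out-of-fold log-likelihoods against
#' the out-of-fold null), averaged across repetitions.
#'
#' @inheritParams repeated_cv_risk
#' @return object of class `nested_risk`: list with `roc` (per-model mean
#'   curves), `auc` (mean-curve AUC per model), `auc_per_rep`,
#'   `r2_mcfadden` (mean test-set value per model), `r2_per_rep`,
#'   `full_fit` (the full-data [fit_nested_logistic()]), and settings.
#' @examples
#' coh <- generate_cohort(cohort_config(400, n_fc_nodes = 8, n_gmv = 5, seed = 3))
#' nr <- nested_risk(coh$disease[, "cancer"], coh$confounders, coh$pa,
#'                   coh$fc_edges, n_reps = 2, seed = 1)
#' nr$auc
#' @export
nested_risk <- function(y, conf, pa, idp = NULL, n_folds = 10L,
                        n_reps = 100L, seed = 1L, pca_var = 0.9,
                        reduce_idp = NULL) {
  y <- as.integer(y)
  if (sum(y) < 20L) {
    warning(sprintf("only %d events for this outcome; estimates will be unstable", sum(y)))
  }
  cv <- repeated_cv_risk(y, conf, pa, idp, n_folds = n_folds,
                         n_reps = n_reps, seed = seed, pca_var = pca_var,
                         reduce_idp = reduce_idp)
  models <- cv$models
  roc <- list(); auc <- auc_sd <- numeric(0)
  auc_per_rep <- r2_per_rep <- list()
  for (m in models) {
    mr <- mean_roc_auc(cv$prob[[m]], y)
    roc[[m]] <- list(fpr = mr$fpr, tpr = mr$tpr)
    auc[m] <- mr$auc
    auc_per_rep[[m]] <- mr$auc_per_rep
    r2_per_rep[[m]] <- vapply(seq_len(cv$n_reps), function(r)
      mcfadden_r2(cv$prob[[m]][r, ], cv$prob[["M0"]][r, ], y), 0)
  }
  r2 <- vapply(r2_per_rep, mean, 0)
  full_fit <- fit_nested_logistic(y, conf, pa, idp, pca_var = pca_var)
  structure(
    list(roc = roc, auc = auc, auc_per_rep = auc_per_rep,
         r2_mcfadden = r2, r2_per_rep = r2_per_rep,
         full_fit = full_fit, models = models, y = y,
         n = length(y), events = sum(y),
         n_folds = cv$n_folds, n_reps = cv$n_reps, seed = cv$seed,
         pca_var = cv$pca_var, reduced = cv$reduced),
    class = "nested_risk"
  )
}

#' @export
print.nested_risk <- function(x, ...) {
  cat(sprintf("Nested risk models: n = %d, events = %d (%.1f%%), %d x %d-fold CV\n",
              x$n, x$events, 100 * x$events / x$n, x$n_reps, x$n_folds))
  tab <- data.frame(model = x$models,
                    AUC = round(x$auc[x$models], 3),
                    McFadden_R2 = round(x$r2_mcfadden[x$models], 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.nested_risk <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Plot mean ROC curves of a nested-risk fit
#'
#' @param x a `nested_risk` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nested_risk <- function(x, ...) {
  plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
       xlab = "false positive rate", ylab = "true positive rate", ...)
  cols <- setNames(seq_along(x$models) + 1L, x$models)
  for (m in x$models) {
    graphics::lines(x$roc[[m]]$fpr, x$roc[[m]]$tpr, col = cols[m])
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)", x$models, x$auc[x$models]),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Disease panel: nested risk models across outcomes
#'
#' Runs [nested_risk()] for each disease column of a cohort against one
#' imaging block, collecting mean-ROC AUCs and test-set McFadden values
#' into one report.
#'
#' @param cohort a `synthetic_cohort` (or any list with `confounders`,
#'   `pa`, `fc_edges`, `gmv`, `disease`).
#' @param diseases character vector of disease column names (default: all
#'   columns of `cohort$disease`).
#' @param idp which imaging block: `"fc"` or `"gmv"`.
#' @param ... passed to [nested_risk()] (`n_folds`, `n_reps`, `seed`, ...).
#' @return object of class `risk_panel`: named list of `nested_risk`
#'   fits plus a summary data.frame `table` (disease x model AUC and
#'   pseudo-R2).
#' @export
run_disease_panel <- function(cohort, diseases = NULL,
                              idp = c("fc", "gmv"), ...) {
  idp <- match.arg(idp)
  if (is.null(diseases)) diseases <- colnames(cohort$disease)
  missing_d <- setdiff(diseases, colnames(cohort$disease))
  if (length(missing_d)) {
    stop(sprintf("disease label(s) not present: %s", paste(missing_d, collapse = ", ")),
         call. = FALSE)
  }
  idp_block <- if (idp == "fc") cohort$fc_edges else cohort$gmv
  fits <- lapply(setNames(diseases, diseases), function(d) {
    nested_risk(cohort$disease[, d], cohort$confounders, cohort$pa,
                idp_block, ...)
  })
  rows <- do.call(rbind, lapply(diseases, function(d) {
    f <- fits[[d]]
    data.frame(disease = d, model = f$models,
               auc = unname(f$auc[f$models]),
               r2_mcfadden = unname(f$r2_mcfadden[f$models]),
               events = f$events, n = f$n)
  }))
  structure(list(fits = fits, table = rows, idp = idp),
            class = "risk_panel")
}

#' @export
print.risk_panel <- function(x, ...) {
  cat(sprintf("Disease risk panel (imaging block: %s)\n", toupper(x$idp)))
  tab <- x$table
  tab$auc <- round(tab$auc, 3)
  tab$r2_mcfadden <- round(tab$r2_mcfadden, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
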