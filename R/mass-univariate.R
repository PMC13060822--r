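#' Mass-univariate screening of responses on the PA block
#'
#' Fits, for every response column, the linear model with design
#' `[confounders, PA]` and tests the contribution of the PA block given
#' the confounders with a partial F-test (reduced model: confounders
#' only).  The q p-values are adjusted by Benjamini-Hochberg and the index
#' set of responses whose adjusted p-value is at or below `alpha` is
#' returned — the set "significantly related to the PA variables after
#' controlling for confounders".  An overall-model F (against the
#' intercept-only model) is available as an alternative.
#'
#' @param Y n x q response matrix (e.g. Fisher-z FC edges or volumes).
#' @param G n x p1 confounder matrix (intercept added internally).
#' @param H n x p2 predictor-of-interest matrix (the PA features).
#' @param alpha FDR level for selection (default 0.05).
#' @param test `"partial"` (PA given confounders, default) or
#'   `"overall"` (whole design against intercept).
#' @return object of class `mu_screen`: list with `p_value`, `p_adjusted`,
#'   `selected` (integer index set), `f_statistic`, `df`, `alpha`, `test`.
#' @export
screen_responses <- function(Y, G, H, alpha = 0.05,
                             test = c("partial", "overall")) {
  test <- match.arg(test)
  Y <- as_numeric_matrix(Y)
  G <- as_numeric_matrix(G)
  H <- as_numeric_matrix(H)
  n <- nrow(Y)
  if (nrow(G) != n || nrow(H) != n) stop("blocks are not row-aligned", call. = FALSE)
  Xfull <- cbind(1, G, H)
  qr_full <- qr(Xfull)
  if (qr_full$rank < ncol(Xfull)) {
    # identify which appended columns fail to add rank
    piv <- qr_full$pivot[seq_len(qr_full$rank)]
    bad <- setdiff(seq_len(ncol(Xfull)), piv)
    lbl <- c("(Intercept)",
             colnames(G) %||% paste0("G", seq_len(ncol(G))),
             colnames(H) %||% paste0("H", seq_len(ncol(H))))
    stop(sprintf("design matrix [confounders, PA] is rank deficient; collinear column(s): %s",
                 paste(lbl[bad], collapse = ", ")), call. = FALSE)
  }
  Xred <- if (test == "partial") cbind(1, G) else matrix(1, n, 1L)
  qr_red <- qr(Xred)

  rss_full <- colSums(qr.resid(qr_full, Y)^2)
  rss_red <- colSums(qr.resid(qr_red, Y)^2)
  df1 <- qr_full$rank - qr_red$rank
  df2 <- n - qr_full$rank
  fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  pv <- pf(fstat, df1, df2, lower.tail = FALSE)
  padj <- p.adjust(pv, method = "BH")
  structure(
    list(p_value = pv, p_adjusted = padj,
         selected = which(padj <= alpha),
         f_statistic = fstat, df = c(df1 = df1, df2 = df2),
         alpha = alpha, test = test, q = ncol(Y)),
    class = "mu_screen"
  )
}

#' @export
print.mu_screen <- function(x, ...) {
  cat(sprintf("Mass-univariate screen (%s F-test): %d of %d responses selected at BH alpha = %g (%.1f%%)\n",
              x$test, length(x$selected), x$q, x$alpha,
              100 * length(x$selected) / x$q))
  invisible(x)
}

#' Repeated cross-validated predictive correlation
#'
#' For one response, assembles out-of-fold linear-model predictions over a
#' k-fold split, correlates them with the observed response, and averages
#' the correlation over repeated random splits.
#'
#' @param y length-n response vector.
#' @param X n x p design matrix (typically `[confounders, PA]`).
#' @param n_folds folds per repetition (default 10).
#' @param n_reps number of repetitions (default 100).
#' @param seed integer seed governing all splits.
#' @return list with `mean` (average Pearson correlation), `per_rep`
#'   (length `n_reps`), `n_folds`, `n_reps`, `seed`.  A repetition with
#'   constant predictions is recorded as `NA` with a warning and excluded
#'   from the mean.
#' @export
cv_predictive_correlation <- function(y, X, n_folds = 10L, n_reps = 100L,
                                      seed = 1L) {
  y <- as.numeric(y)
  X <- as_numeric_matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("y and X are not row-aligned", call. = FALSE)
  if (n < 2L * n_folds) stop("need n >= 2 * n_folds", call. = FALSE)
  X1 <- cbind(1, X)
  per_rep <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      fold <- sample(rep_len(seq_len(n_folds), n))
      pred <- numeric(n)
      for (f in seq_len(n_folds)) {
        te <- fold == f
        beta <- qr.coef(qr(X1[!te, , drop = FALSE]), y[!te])
        beta[is.na(beta)] <- 0
        pred[te] <- X1[te, , drop = FALSE] %*% beta
      }
      if (sd(pred) == 0) return(NA_real_)
      cor(y, pred)
    }, 0)
  })
  if (anyNA(per_rep)) warning("constant predictions in some repetition(s); recorded as NA")
  list(mean = mean(per_rep, na.rm = TRUE), per_rep = per_rep,
       n_folds = as.integer(n_folds), n_reps = as.integer(n_reps),
       seed = as.integer(seed))
}

new_importance_table <- function(scores, method) {
  structure(list(scores = scores, method = method),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("PA variable importance (%s): %d response(s) x %d variables\n",
              x$method, nrow(x$scores), ncol(x$scores)))
  cat("Column means:\n")
  print(round(colMeans(x$scores), 3))
  invisible(x)
}

#' PA variable importance by per-coefficient t-tests
#'
#' Fits the full linear model `[confounders, PA]` for each response and
#' scores each PA variable by `-log10` of its coefficient's two-sided
#' t-test p-value (confounders always included).
#'
#' @inheritParams screen_responses
#' @return `importance_table` with a (responses x PA variables) matrix of
#'   `-log10 p` scores, method `"ttest"`.
#' @export
importance_ttest <- function(Y, G, H) {
  Y <- as_numeric_matrix(Y)
  G <- as_numeric_matrix(G)
  H <- as_numeric_matrix(H)
  n <- nrow(Y)
  X <- cbind(1, G, H)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix [confounders, PA] is rank deficient", call. = FALSE)
  }
  # diag of (X'X)^{-1} in original column order, respecting QR pivoting:
  # X P = Q R  =>  (X'X)^{-1} = P (R'R)^{-1} P'
  d_piv <- diag(chol2inv(qr.R(qrX)))
  d_xtx <- numeric(ncol(X))
  d_xtx[qrX$pivot] <- d_piv
  beta <- qr.coef(qrX, Y)                      # (1+p1+p2) x q
  resid <- qr.resid(qrX, Y)
  df <- n - ncol(X)
  sigma2 <- colSums(resid^2) / df
  h_idx <- (1L + ncol(G) + 1L):ncol(X)
  se <- sqrt(outer(d_xtx[h_idx], sigma2))      # p2 x q
  tval <- beta[h_idx, , drop = FALSE] / se
  pv <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  scores <- t(-log10(pmax(pv, .Machine$double.xmin)))
  colnames(scores) <- colnames(H) %||% paste0("H", seq_len(ncol(H)))
  rownames(scores) <- colnames(Y)
  new_importance_table(scores, "ttest")
}

#' PA variable selection by bidirectional stepwise BIC
#'
#' For each response, searches over PA variables with [stats::step()]
#' under the BIC penalty (`k = log(n)`), starting from the
#' confounders-only model; confounders are forced into every candidate
#' model through the scope's lower bound.  The score is a 0/1 selection
#' indicator per PA variable.  The search is deterministic given the
#' data; ties resolve by `step()`'s first-improvement rule in the fixed
#' column order.
#'
#' @inheritParams screen_responses
#' @return `importance_table` with a binary (responses x PA variables)
#'   matrix, method `"stepwise_bic"`.
#' @export
importance_stepwise_bic <- function(Y, G, H) {
  Y <- as_numeric_matrix(Y)
  G <- as_numeric_matrix(G)
  H <- as_numeric_matrix(H)
  n <- nrow(Y)
  gn <- colnames(G) %||% paste0("G", seq_len(ncol(G)))
  hn <- colnames(H) %||% paste0("H", seq_len(ncol(H)))
  colnames(G) <- gn; colnames(H) <- hn
  dat <- data.frame(G, H, check.names = FALSE)
  lower <- as.formula(paste(".y ~", paste(c("1", gn), collapse = " + ")))
  upper <- as.formula(paste(".y ~", paste(c("1", gn, hn), collapse = " + ")))
  scores <- matrix(0L, ncol(Y), ncol(H), dimnames = list(colnames(Y), hn))
  for (l in seq_len(ncol(Y))) {
    dat$.y <- Y[, l]
    fit0 <- lm(lower, data = dat)
    sel <- step(fit0, scope = list(lower = lower, upper = upper),
                direction = "both", k = log(n), trace = 0)
    scores[l, ] <- as.integer(hn %in% attr(stats::terms(sel), "term.labels"))
  }
  new_importance_table(scores, "stepwise_bic")
}

#' PA variable importance by random-forest permutation importance
#'
#' Fits a regression forest per response on `[confounders, PA]` and
#' reports the permutation importance (mean decrease in out-of-bag
#' accuracy, `%IncMSE`) of the PA columns only.  A degenerate
#' (zero-variance) response is skipped with a warning and scored `NA`.
#'
#' @inheritParams screen_responses
#' @param n_trees trees per forest, at least 100.
#' @param seed integer seed.
#' @param importance_type `"permutation"` (default) or `"impurity"`
#'   (IncNodePurity).
#' @return `importance_table` with a (responses x PA variables) score
#'   matrix, method `"random_forest"`.
#' @export
importance_random_forest <- function(Y, G, H, n_trees = 500L, seed = 1L,
                                     importance_type = c("permutation", "impurity")) {
  importance_type <- match.arg(importance_type)
  if (n_trees < 100L) stop("n_trees must be at least 100", call. = FALSE)
  Y <- as_numeric_matrix(Y)
  G <- as_numeric_matrix(G)
  H <- as_numeric_matrix(H)
  hn <- colnames(H) %||% paste0("H", seq_len(ncol(H)))
  X <- cbind(G, H)
  colnames(X) <- c(colnames(G) %||% paste0("G", seq_len(ncol(G))), hn)
  col <- if (importance_type == "permutation") "%IncMSE" else "IncNodePurity"
  scores <- with_seed(seed, {
    t(vapply(seq_len(ncol(Y)), function(l) {
      yl <- Y[, l]
      if (sd(yl) == 0) {
        warning(sprintf("response %d has zero variance; skipped", l))
        return(rep(NA_real_, length(hn)))
      }
      rf <- randomForest::randomForest(x = X, y = yl, ntree = n_trees,
                                       importance = TRUE)
      randomForest::importance(rf)[hn, col]
    }, numeric(length(hn))))
  })
  dimnames(scores) <- list(colnames(Y), hn)
  new_importance_table(scores, "random_forest")
}

#' Consensus ranking of PA variables across importance engines
#'
#' Aggregates two or more importance tables over the same PA columns:
#' each method's column-mean score is converted to ranks (1 = most
#' important), the ranks are averaged across methods, and the variables
#' are returned in consensus order with the per-method ranks attached.
#'
#' @param tables list of `importance_table` objects sharing column names.
#' @return data.frame ordered by consensus rank, with one rank column per
#'   method and `mean_rank`.
#' @export
consensus_ranking <- function(tables) {
  if (length(tables) < 2L) stop("need at least two importance tables", call. = FALSE)
  cols <- colnames(tables[[1L]]$scores)
  for (tb in tables) {
    if (!identical(colnames(tb$scores), cols)) {
      stop("importance tables disagree on PA columns", call. = FALSE)
    }
  }
  ranks <- vapply(tables, function(tb) {
    m <- colMeans(tb$scores, na.rm = TRUE)
    rank(-m, ties.method = "average")
  }, numeric(length(cols)))
  colnames(ranks) <- vapply(tables, `[[`, "", "method")
  mean_rank <- rowMeans(ranks)
  out <- data.frame(variable = cols, ranks, mean_rank = mean_rank,
                    check.names = FALSE)
  out[order(out$mean_rank), , drop = FALSE]
}
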