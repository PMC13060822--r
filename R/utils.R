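#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov sd var lm glm pf pchisq pnorm plogis qlogis
#'   binomial anova coef predict rnorm runif rbinom quantile p.adjust
#'   step as.formula setNames prcomp uniroot ks.test complete.cases
#' @importFrom utils head read.delim write.table modifyList
NULL

# stop() wrapper that names the offending field, used by config validators
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

# column-center a numeric matrix
center_cols <- function(X) {
  sweep(X, 2L, colMeans(X), "-")
}

# symmetric pseudo inverse square root with relative spectral truncation.
# Used to whiten within-block covariances in the CCA fit; eigenvalues below
# tol * max(eigenvalue) are dropped (treated as exact rank deficiency).
pinv_sqrt <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) stop("matrix is numerically zero; cannot whiten", call. = FALSE)
  V <- e$vectors[, keep, drop = FALSE]
  list(
    half = V %*% (t(V) / sqrt(e$values[keep])),
    rank = sum(keep)
  )
}

# draw a reproducible child seed (kept below 2^31) from the current RNG
child_seed <- function() {
  as.integer(floor(runif(1) * 2147483399)) + 1L
}

# run `expr` under a local RNG state seeded with `seed`; restores the caller's
# RNG afterwards so seeded subroutines do not perturb outer streams
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

as_numeric_matrix <- function(x, arg = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", arg), call. = FALSE)
  x
}
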