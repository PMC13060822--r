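#' Fisher z-transform of a correlation
#'
#' Variance-stabilizing transform `atanh(r)` applied element-wise to
#' (partial) correlations before linear modelling, as is standard for
#' functional-connectivity edges.
#'
#' @param r numeric vector of correlations, all strictly inside (-1, 1).
#' @return numeric vector of the same length, `atanh(r)`.
#' @examples
#' fisher_z(c(0, 0.5, -0.5))
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r)) stop("'r' must be numeric", call. = FALSE)
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z is defined only for |r| < 1", call. = FALSE)
  }
  atanh(r)
}

#' Inverse Fisher z-transform
#'
#' @param z numeric vector.
#' @return `tanh(z)`, correlations in (-1, 1).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Edge labels for netmat vectorization
#'
#' The vectorization convention is the strict lower triangle in row-major
#' node order: edge 1 is (node 2, node 1), edge 2 is (node 3, node 1),
#' edge 3 is (node 3, node 2), and so on.  This table makes the index ->
#' (node_i, node_j) map explicit and is the sidecar written next to edge
#' matrices.
#'
#' @param n_nodes number of network nodes (55 for the default parcellation).
#' @return data.frame with columns `edge`, `node_i`, `node_j` (`node_i >
#'   node_j`), one row per lower-triangle entry.
#' @export
netmat_edge_labels <- function(n_nodes) {
  idx <- which(lower.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])  # row-major within the lower triangle
  data.frame(
    edge = seq_len(nrow(idx)),
    node_i = idx[ord, 1L],
    node_j = idx[ord, 2L]
  )
}

#' Vectorize a symmetric netmat into Fisher-z edges
#'
#' Extracts the strict lower triangle of a node-by-node (partial)
#' correlation matrix in row-major node order and applies the element-wise
#' Fisher transform.  A 55-node netmat yields 55*54/2 = 1485 edges.
#'
#' @param netmat square symmetric numeric matrix; off-diagonal entries must
#'   lie strictly inside (-1, 1).
#' @param tol symmetry tolerance (max absolute difference).
#' @return numeric vector of length `n*(n-1)/2` of Fisher-z edge values.
#' @seealso [unvectorize_netmat()] for the exact inverse,
#'   [netmat_edge_labels()] for the index convention.
#' @export
vectorize_netmat <- function(netmat, tol = 1e-8) {
  netmat <- as_numeric_matrix(netmat)
  n <- nrow(netmat)
  if (ncol(netmat) != n) stop("netmat must be square", call. = FALSE)
  if (max(abs(netmat - t(netmat))) > tol) {
    stop("netmat is asymmetric beyond tolerance", call. = FALSE)
  }
  lab <- netmat_edge_labels(n)
  r <- netmat[cbind(lab$node_i, lab$node_j)]
  if (any(abs(r) >= 1)) {
    stop("off-diagonal netmat entries must lie strictly in (-1, 1)",
         call. = FALSE)
  }
  fisher_z(r)
}

#' Rebuild a netmat from a Fisher-z edge vector
#'
#' Exact inverse of [vectorize_netmat()]: edges are mapped back through
#' `tanh` into the lower triangle (row-major), mirrored, and the diagonal
#' set to 1.
#'
#' @param edges numeric vector of length `n*(n-1)/2`.
#' @param n_nodes number of nodes; inferred from `length(edges)` if missing.
#' @return symmetric `n_nodes` x `n_nodes` matrix with unit diagonal.
#' @export
unvectorize_netmat <- function(edges, n_nodes = NULL) {
  m <- length(edges)
  if (is.null(n_nodes)) {
    n_nodes <- (1 + sqrt(1 + 8 * m)) / 2
    if (n_nodes != round(n_nodes)) {
      stop("edge vector length is not n*(n-1)/2 for any integer n",
           call. = FALSE)
    }
    n_nodes <- as.integer(n_nodes)
  }
  if (m != n_nodes * (n_nodes - 1L) / 2L) {
    stop("edge vector length does not match n_nodes", call. = FALSE)
  }
  lab <- netmat_edge_labels(n_nodes)
  M <- diag(1, n_nodes)
  M[cbind(lab$node_i, lab$node_j)] <- fisher_z_inv(edges)
  M[cbind(lab$node_j, lab$node_i)] <- fisher_z_inv(edges)
  M
}

#' Residualize a data block on its confounders
#'
#' Regresses every column of `Y` on the confounder matrix `G` (an intercept
#' is appended if absent) and returns the residuals
#' `Y - G (G'G)^- G' Y`, computed through a rank-revealing QR solve so a
#' rank-deficient confounder matrix degrades gracefully to the
#' pseudoinverse projection (with a warning) instead of failing.
#' Residual columns are exactly orthogonal to the column space of `G`,
#' hence mean-zero and with zero sample correlation with every confounder.
#'
#' @param Y numeric matrix (participants x variables) or data.frame.
#' @param G confounder matrix (participants x confounders); `NULL` means
#'   intercept-only (plain column centering).
#' @return object of class `residualized_block`: a list with the residual
#'   matrix `residuals`, the confounder matrix `confounders` actually used
#'   (including intercept), and the projection `rank`.
#' @export
residualize_block <- function(Y, G = NULL) {
  Y <- as_numeric_matrix(Y)
  n <- nrow(Y)
  if (is.null(G)) {
    G <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    G <- as_numeric_matrix(G)
    if (nrow(G) != n) stop("Y and G must have the same number of rows", call. = FALSE)
    # append intercept unless some column is already constant non-zero
    has_intercept <- any(apply(G, 2L, function(g) sd(g) == 0 && g[1] != 0))
    if (!has_intercept) {
      G <- cbind("(Intercept)" = 1, G)
    }
  }
  if (n <= ncol(G)) {
    stop("need more rows than confounder columns to residualize", call. = FALSE)
  }
  qrG <- qr(G)
  if (qrG$rank < ncol(G)) {
    warning(sprintf(
      "confounder matrix is rank deficient (rank %d of %d columns); using pseudoinverse projection",
      qrG$rank, ncol(G)))
  }
  res <- qr.resid(qrG, Y)
  structure(
    list(residuals = res, confounders = G, rank = qrG$rank),
    class = "residualized_block"
  )
}

#' @export
print.residualized_block <- function(x, ...) {
  cat(sprintf(
    "Residualized block: %d x %d, %d confounder column(s) (projection rank %d)\n",
    nrow(x$residuals), ncol(x$residuals), ncol(x$confounders), x$rank))
  invisible(x)
}

#' Complete-case participant filter across analysis blocks
#'
#' Identifies the participants with no missing value in any column of any
#' supplied block — the analytic-sample rule for every stage of the
#' pipeline: a participant is dropped from an analysis if any variable of
#' that analysis is missing, before residualization.
#'
#' @param ... row-aligned matrices or data.frames (blocks of one
#'   analysis).
#' @return logical vector of length n, `TRUE` for complete cases; the
#'   number dropped is reported in a message when positive.
#' @export
complete_case_filter <- function(...) {
  blocks <- list(...)
  if (!length(blocks)) stop("no blocks supplied", call. = FALSE)
  n <- nrow(as_numeric_matrix(blocks[[1L]]))
  keep <- rep(TRUE, n)
  for (b in blocks) {
    b <- as_numeric_matrix(b)
    if (nrow(b) != n) stop("blocks are not row-aligned", call. = FALSE)
    keep <- keep & complete.cases(b)
  }
  if (any(!keep)) {
    message(sprintf("dropping %d of %d participants with incomplete data",
                    sum(!keep), n))
  }
  keep
}

#' Standardize columns to mean zero, unit sample SD
#'
#' @param X numeric matrix.
#' @return matrix with each column demeaned and scaled to sample standard
#'   deviation one.  Errors (naming the column) if any column is constant.
#' @export
standardize_cols <- function(X) {
  X <- as_numeric_matrix(X)
  s <- apply(X, 2L, sd)
  if (any(s == 0)) {
    bad <- colnames(X)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop(sprintf("zero-variance column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  scale(X, center = TRUE, scale = s)[, , drop = FALSE]
}
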