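#' Factors of one extracted signal
#'
#' Container for one signal's expanded SVD factors: `U` (P x d variable
#' loadings, orthonormal columns), `sigma` (d positive nonincreasing
#' singular values), `V` (N x d sample coordinates, orthonormal columns),
#' plus selection metadata when the signal came from a selection-expansion
#' step (`selection`, `threshold`, `score`, and `submatrix_sigma`, the
#' singular values of the selected submatrix).
#'
#' @param U,sigma,V SVD factors.
#' @param selection Optional `selection_map`.
#' @param threshold Optional standard-deviation cutoff used for selection.
#' @param score Optional projection-score value at the optimum.
#' @param submatrix_sigma Optional singular values of \eqn{S^T X}.
#' @param score_grid Optional `score_grid` diagnostic object.
#' @return Object of class `signal_factors`.
#' @export
signal_factors <- function(U, sigma, V, selection = NULL, threshold = NA_real_,
                           score = NA_real_, submatrix_sigma = NULL,
                           score_grid = NULL) {
  U <- as.matrix(U); V <- as.matrix(V)
  d <- length(sigma)
  if (ncol(U) != d || ncol(V) != d) stop("factor dimensions disagree")
  if (d > 0L) {
    if (any(sigma <= 0)) stop("singular values must be positive")
    if (is.unsorted(rev(sigma))) stop("singular values must be nonincreasing")
    if (max(abs(crossprod(U) - diag(d))) > 1e-8) stop("U columns not orthonormal")
    if (max(abs(crossprod(V) - diag(d))) > 1e-8) stop("V columns not orthonormal")
  }
  structure(list(U = U, sigma = as.numeric(sigma), V = V, d = d,
                 selection = selection, threshold = threshold, score = score,
                 submatrix_sigma = submatrix_sigma, score_grid = score_grid),
            class = "signal_factors")
}

#' @method print signal_factors
#' @export
print.signal_factors <- function(x, ...) {
  cat("signal_factors: d = ", x$d, ", P = ", nrow(x$U), ", N = ", nrow(x$V), "\n", sep = "")
  if (x$d > 0) cat("  sigma: ", paste(signif(x$sigma, 4), collapse = " "), "\n", sep = "")
  if (!is.null(x$selection))
    cat("  selection: ", selection_size(x$selection), " variables, threshold ",
        signif(x$threshold, 4), ", score ", signif(x$score, 4), "\n", sep = "")
  invisible(x)
}

#' SVD of a data matrix restricted to a subspace of sample space
#'
#' Computes the singular value decomposition of \eqn{X|_\Pi}, the linear map
#' X considered only on inputs in the d-dimensional subspace \eqn{\Pi}
#' spanned by the orthonormal columns of `basis`. The decomposition is
#' obtained from the thin SVD of the P x d matrix `X %*% basis` (never by
#' forming N x N or P x P projections), with the right factor rotated back:
#' `V = basis %*% W`. The returned factors satisfy `X %*% V == U %*% diag(sigma)`
#' and the columns of V span \eqn{\Pi} exactly.
#'
#' If \eqn{\Pi} is spanned by top right-singular vectors of X this is the
#' truncated SVD; for a general \eqn{\Pi} orthogonal to the null space of X
#' it retains the key SVD-like properties (orthonormal factors, deflation
#' identity, rank additivity) that the decomposition algorithm relies on.
#'
#' @param X P x N numeric matrix.
#' @param basis N x d matrix with orthonormal columns, \eqn{\Pi \perp \ker X}.
#' @return A [signal_factors] object.
#' @export
restricted_svd <- function(X, basis) {
  X <- as_data_matrix(X)
  basis <- check_subspace_basis(basis, ncol(X))
  d <- ncol(basis)
  B <- X %*% basis
  sv <- svd(B)
  # reference scale is ||X||_2, not sv$d[1]: for d = 1 the latter would
  # compare the only singular value against itself
  if (sv$d[d] <= 1e-12 * top_sv(X))
    stop("subspace intersects the null space of X (rank(X %*% basis) < d)")
  s <- fix_signs(sv$u, basis %*% sv$v)
  U <- s$U; V <- s$V
  rownames(U) <- rownames(X)
  rownames(V) <- colnames(X)
  signal_factors(U = U, sigma = sv$d, V = V)
}

#' Selection-expansion: SVD of the selected submatrix, expanded to all variables
#'
#' Computes the rank-d truncated SVD \eqn{\tilde U \tilde\Sigma \tilde V^T}
#' of the selected submatrix \eqn{S^T X}, takes \eqn{\Pi} to be the span of
#' \eqn{\tilde V}, and returns [restricted_svd] of X on \eqn{\Pi}. The
#' expansion leaves the selected variables intact
#' (\eqn{S^T U \Sigma V^T = \tilde U \tilde\Sigma \tilde V^T}), the sample
#' representation changes at most by rotation (V and \eqn{\tilde V} span the
#' same subspace), and for subset selections the expanded singular values
#' dominate: \eqn{\|\Sigma\|_F \ge \|\tilde\Sigma\|_F}.
#'
#' @param X P x N numeric matrix.
#' @param selection A `selection_map`.
#' @param d Signal rank; requires `rank(S^T X) >= d`.
#' @param threshold,score Optional metadata recorded on the result.
#' @param score_grid Optional `score_grid` recorded on the result.
#' @return A [signal_factors] object with `selection` and `submatrix_sigma` set.
#' @export
select_expand <- function(X, selection, d, threshold = NA_real_,
                          score = NA_real_, score_grid = NULL) {
  X <- as_data_matrix(X)
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1")
  Xs <- apply_selection(selection, X)
  if (nrow(Xs) == 0L) stop("empty selection")
  sv <- svd(Xs, nu = 0)
  if (length(sv$d) < d || sv$d[d] <= 1e-12 * sv$d[1])
    stop("insufficient submatrix rank: rank(S^T X) < ", d)
  Vt <- sv$v[, seq_len(d), drop = FALSE]
  out <- restricted_svd(X, Vt)
  signal_factors(U = out$U, sigma = out$sigma, V = out$V,
                 selection = selection, threshold = threshold, score = score,
                 submatrix_sigma = sv$d[seq_len(d)], score_grid = score_grid)
}

#' Deflate a signal from a data matrix
#'
#' The signal-removal step: returns \eqn{(I - U U^T) X}, projecting the data
#' onto the orthogonal complement of the extracted signal's variable-side
#' span. This reduces the rank by the signal's dimension and guarantees that
#' all later signals are orthogonal to this one (on both the variable and
#' sample sides, since \eqn{(I - UU^T)X = (I - UU^T)X(I - VV^T)}).
#'
#' @param X P x N numeric matrix.
#' @param factors A [signal_factors] object extracted from `X`.
#' @return The deflated matrix, same shape and dimnames as `X`.
#' @export
remove_signal <- function(X, factors) {
  stopifnot(inherits(factors, "signal_factors"))
  if (factors$d == 0L) return(X)
  if (nrow(factors$U) != nrow(X)) stop("factors have ", nrow(factors$U),
                                       " variables, matrix has ", nrow(X))
  X - factors$U %*% crossprod(factors$U, X)
}
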