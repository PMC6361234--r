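#' Configuration for the SMSSVD decomposition
#'
#' @param target_dim Total number of dimensions to extract, or `NULL` for
#'   library mode (iterate while the optimal projection score is positive).
#' @param n_randomizations Randomized copies per projection-score cell
#'   (default 10; very few are needed since the null informativeness has
#'   small variance).
#' @param seed Master seed for all randomization streams.
#' @param disable_selection If TRUE, skip variable selection entirely; the
#'   decomposition then coincides with the (truncated) SVD.
#' @param center_variables If TRUE, subtract each variable's mean first
#'   (PCA-style use; default off, pure SVD semantics).
#' @param threshold_grid_size Number of quantile levels in the
#'   variance-filter threshold grid (default 32).
#' @param d_max Largest candidate signal dimension per iteration (default 20).
#' @return An `smssvd_config` list.
#' @export
smssvd_config <- function(target_dim = NULL, n_randomizations = 10, seed = 1,
                          disable_selection = FALSE, center_variables = FALSE,
                          threshold_grid_size = 32, d_max = 20) {
  if (!is.null(target_dim) && target_dim < 1) stop("target_dim must be >= 1")
  if (n_randomizations < 1) stop("n_randomizations must be >= 1")
  if (threshold_grid_size < 2) stop("threshold_grid_size must be >= 2")
  if (d_max < 1) stop("d_max must be >= 1")
  structure(list(target_dim = if (is.null(target_dim)) NULL else as.integer(target_dim),
                 n_randomizations = as.integer(n_randomizations),
                 seed = as.integer(seed),
                 disable_selection = isTRUE(disable_selection),
                 center_variables = isTRUE(center_variables),
                 threshold_grid_size = as.integer(threshold_grid_size),
                 d_max = as.integer(d_max)),
            class = "smssvd_config")
}

#' SubMatrix Selection Singular Value Decomposition
#'
#' Iteratively decomposes a P x N variables-by-samples matrix into
#' orthogonal low-rank signals. Each iteration (1) optimizes the projection
#' score jointly over variance-filtering thresholds and dimensions to find
#' the most informative variable subset \eqn{S_k} and its dimension
#' \eqn{d_k}; (2) computes the rank-\eqn{d_k} truncated SVD of the selected
#' submatrix \eqn{S_k^T X_k}; (3) expands it back to all variables through
#' the SVD of \eqn{X_k} restricted to the selected right-singular subspace;
#' and (4) deflates, \eqn{X_{k+1} = (I - U_k U_k^T) X_k}. The concatenated
#' factors form an SVD-like decomposition \eqn{U \Sigma V^T} with
#' orthonormal U and V across all signals — a denoised, low-rank version of
#' X. With selection disabled the result coincides with the truncated SVD.
#'
#' Iteration stops when `target_dim` dimensions have been extracted (the
#' last signal is truncated to the remaining budget), when the residual is
#' numerically zero, or — in library mode (`target_dim = NULL`) — when the
#' optimal projection score is no longer positive.
#'
#' @param X P x N numeric matrix (variables in rows).
#' @param target_dim Total dimension to extract; overrides
#'   `config$target_dim`. `1 <= target_dim <= min(P, N)`.
#' @param config An [smssvd_config].
#' @return An object of class `smssvd`: list with `signals` (list of
#'   [signal_factors]), concatenated `U`, `sigma`, `V`, the final `residual`
#'   matrix, and `total_dim`.
#' @export
smssvd <- function(X, target_dim = config$target_dim, config = smssvd_config()) {
  X <- as_data_matrix(X)
  P <- nrow(X); N <- ncol(X)
  if (config$center_variables) X <- X - rowMeans(X)
  sv_max0 <- top_sv(X)
  if (sv_max0 <= 0) stop("zero input matrix")
  if (!is.null(target_dim)) {
    target_dim <- as.integer(target_dim)
    if (target_dim < 1L || target_dim > min(P, N))
      stop("target_dim must be in 1..min(P, N)")
  }

  signals <- list()
  Xk <- X
  used <- 0L
  k <- 0L
  repeat {
    if (!is.null(target_dim) && used >= target_dim) break
    k <- k + 1L
    sv_max <- top_sv(Xk)
    if (sv_max <= 1e-12 * sv_max0) {
      if (!is.null(target_dim))
        log_warn("target_dim (", target_dim, ") exceeds rank(X); returning ",
                 used, " dimensions")
      break
    }
    budget <- if (is.null(target_dim)) Inf else target_dim - used

    if (config$disable_selection) {
      sel <- selection_all(P)
      sv <- svd(Xk, nu = 0, nv = 0)$d
      d_k <- min(budget, numerical_rank(sv))
      fac <- select_expand(Xk, sel, d_k)
    } else {
      opt <- optimize_projection_score(Xk, config, d_max_cap = budget,
                                       seed = derive_seed(config$seed, 101L, k))
      if (is.null(target_dim) && (opt$fallback || opt$score <= 0)) {
        log_info("stopping: optimal projection score ",
                 if (opt$fallback) "undefined" else signif(opt$score, 4),
                 " at iteration ", k)
        break
      }
      fac <- select_expand(Xk, opt$selection, opt$d, threshold = opt$threshold,
                           score = opt$score, score_grid = opt$grid)
      if (fac$d > budget) fac <- truncate_factors(fac, budget)
      log_info("signal ", k, ": d = ", fac$d, ", threshold = ",
               signif(fac$threshold, 4), ", n_selected = ",
               selection_size(fac$selection), ", score = ", signif(fac$score, 4))
    }
    signals[[length(signals) + 1L]] <- fac
    Xk <- remove_signal(Xk, fac)
    used <- used + fac$d
    if (config$disable_selection && (is.null(target_dim) || used >= target_dim)) break
  }
  concatenate_signals(signals, Xk)
}

# Keep the leading `d` singular triplets of a signal (dimension-budget
# truncation of the final signal).
truncate_factors <- function(fac, d) {
  d <- as.integer(d)
  keep <- seq_len(d)
  signal_factors(U = fac$U[, keep, drop = FALSE], sigma = fac$sigma[keep],
                 V = fac$V[, keep, drop = FALSE], selection = fac$selection,
                 threshold = fac$threshold, score = fac$score,
                 submatrix_sigma = fac$submatrix_sigma[keep],
                 score_grid = fac$score_grid)
}

#' Concatenate extracted signals into one decomposition
#'
#' Block-concatenates the per-signal factors in signal order (within-signal
#' singular values stay in descending order; between signals the order
#' follows discovery and is not re-sorted). Cross-signal orthonormality of
#' the concatenated U and V columns is verified to 1e-6 — a violation means
#' the signals were not produced by proper deflation.
#'
#' @param signals List of [signal_factors] sharing P and N.
#' @param residual P x N residual matrix after the last deflation.
#' @return An `smssvd` object.
#' @export
concatenate_signals <- function(signals, residual) {
  residual <- as.matrix(residual)
  P <- nrow(residual); N <- ncol(residual)
  for (s in signals) {
    if (nrow(s$U) != P || nrow(s$V) != N) stop("signal dimensions disagree with residual")
  }
  U <- do.call(cbind, c(lapply(signals, `[[`, "U"), list(matrix(0, P, 0))))
  V <- do.call(cbind, c(lapply(signals, `[[`, "V"), list(matrix(0, N, 0))))
  sigma <- unlist(lapply(signals, `[[`, "sigma"), use.names = FALSE)
  if (is.null(sigma)) sigma <- numeric(0)
  D <- length(sigma)
  if (D > 0L) {
    if (max(abs(crossprod(U) - diag(D))) > 1e-6 ||
        max(abs(crossprod(V) - diag(D))) > 1e-6)
      stop("cross-signal orthogonality violated; signals were not produced by proper deflation")
    colnames(U) <- colnames(V) <-
      unlist(lapply(seq_along(signals), function(k)
        paste0("s", k, "c", seq_len(signals[[k]]$d))), use.names = FALSE)
    names(sigma) <- colnames(U)
  }
  structure(list(signals = signals, U = U, sigma = sigma, V = V,
                 residual = residual, total_dim = D),
            class = "smssvd")
}

#' Reconstruct the denoised matrix from a decomposition
#'
#' Returns \eqn{U \Sigma V^T}. In contrast to the SVD this is in general not
#' equal to X — the difference is the removed noise. Equality (to numerical
#' precision) holds only with selection disabled and `target_dim = rank(X)`.
#'
#' @param result An `smssvd` object.
#' @return P x N numeric matrix.
#' @export
reconstruct <- function(result) {
  stopifnot(inherits(result, "smssvd"))
  if (result$total_dim == 0L) {
    out <- matrix(0, nrow(result$residual), ncol(result$residual))
    dimnames(out) <- dimnames(result$residual)
    return(out)
  }
  out <- result$U %*% (result$sigma * t(result$V))
  rownames(out) <- rownames(result$U)
  colnames(out) <- rownames(result$V)
  out
}

#' @method print smssvd
#' @export
print.smssvd <- function(x, ...) {
  cat("smssvd decomposition: ", length(x$signals), " signal(s), total dimension ",
      x$total_dim, "\n", sep = "")
  for (k in seq_along(x$signals)) {
    s <- x$signals[[k]]
    cat("  signal ", k, ": d = ", s$d,
        if (!is.null(s$selection)) paste0(", ", selection_size(s$selection), " variables") else "",
        if (!is.na(s$threshold)) paste0(", threshold ", signif(s$threshold, 4)) else "",
        if (!is.na(s$score)) paste0(", score ", signif(s$score, 4)) else "",
        ", sigma = [", paste(signif(s$sigma, 4), collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}
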