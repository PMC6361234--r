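#' Variance filtering
#'
#' Subset-mode selection of the variables whose sample standard deviation
#' (denominator N-1) strictly exceeds `threshold`. Thresholds are expressed
#' on the standard-deviation scale throughout the package.
#'
#' @param X P x N numeric matrix.
#' @param threshold Nonnegative standard-deviation cutoff.
#' @return A `selection_map` (subset mode).
#' @export
variance_filter <- function(X, threshold) {
  X <- as_data_matrix(X)
  if (threshold < 0) stop("threshold must be >= 0")
  idx <- which(row_sds(X) > threshold)
  if (length(idx) == 0L)
    stop("empty selection: no variable has standard deviation above ", threshold)
  selection_subset(idx, nrow(X))
}

#' Informativeness of a rank-d representation
#'
#' The root fraction of squared singular mass captured by the top d
#' singular values:
#' \eqn{\tau_d = \sqrt{(\sigma_1^2 + \dots + \sigma_d^2) /
#'                     (\sigma_1^2 + \dots + \sigma_r^2)}}.
#' Ranges in (0, 1]; equals 1 when d reaches the rank.
#'
#' @param sigma Nonincreasing, nonnegative singular values (not all zero).
#' @param d Dimension, `1 <= d <= length(sigma)`.
#' @return The informativeness value.
#' @export
informativeness <- function(sigma, d) {
  if (length(sigma) < 1L || d < 1L || d > length(sigma)) stop("d out of range")
  if (any(sigma < 0) || is.unsorted(rev(sigma))) stop("sigma must be nonincreasing and nonnegative")
  tot <- sum(sigma^2)
  if (tot <= 0) stop("all singular values are zero")
  sqrt(sum(sigma[seq_len(d)]^2) / tot)
}

# Null tau for all dimensions 1..dmax at once: n_rand x dmax matrix of
# informativeness values of row-wise permuted copies of Xs. row_ids keys the
# permutation streams by original variable index.
null_tau_matrix <- function(Xs, dmax, n_randomizations, seed,
                            row_ids = seq_len(nrow(Xs))) {
  cpp_null_tau(Xs, as.integer(row_ids), as.integer(dmax),
               as.integer(n_randomizations), as.numeric(seed))
}

#' Permutation streams of the randomization null
#'
#' Returns the exact within-variable permutations that
#' [null_informativeness] applies, as a list of `n_randomizations` L x N
#' integer matrices of column indices (`permuted_row <- row[perm[r, ]]`).
#' Exposed so the null can be recomputed by an independent implementation.
#'
#' @param row_ids Original variable indices of the submatrix rows.
#' @param n Number of samples (columns).
#' @param n_randomizations Number of randomized copies.
#' @param seed Integer seed.
#' @return List of integer matrices.
#' @export
row_permutations <- function(row_ids, n, n_randomizations, seed) {
  cpp_row_permutations(as.integer(row_ids), as.integer(n),
                       as.integer(n_randomizations), as.numeric(seed))
}

#' Null informativeness under within-variable permutation
#'
#' Mean of [informativeness] at dimension `d` over `n_randomizations`
#' randomized copies of the submatrix, each obtained by independently
#' permuting the entries within every variable (row). This destroys
#' inter-variable correlation while preserving each variable's marginal
#' distribution. Every (copy, variable) pair draws from a dedicated stream
#' derived from `seed`, so the value is reproducible and independent of
#' evaluation order and of the order of the rows.
#'
#' @param Xs Selected submatrix (L x N).
#' @param d Dimension.
#' @param n_randomizations Number of randomized copies (>= 1).
#' @param seed Integer seed for the permutation streams.
#' @param row_ids Original variable indices of the rows of `Xs` (defaults to
#'   `1:L`); keys the permutation streams.
#' @return Mean null informativeness.
#' @export
null_informativeness <- function(Xs, d, n_randomizations = 10, seed = 1,
                                 row_ids = seq_len(nrow(Xs))) {
  Xs <- as.matrix(Xs)
  if (n_randomizations < 1L) stop("n_randomizations must be >= 1")
  tau <- null_tau_matrix(Xs, d, n_randomizations, seed, row_ids)
  mean(tau[, d])
}

#' Projection score of a variable subset
#'
#' Measures how informative a variable subset is for a rank-d representation:
#' the informativeness \eqn{\tau_d} of the selected submatrix minus its mean
#' under the within-variable permutation null. Positive values mean the
#' subset carries more low-rank structure than expected by chance.
#'
#' @param X P x N numeric matrix.
#' @param selection A `selection_map`.
#' @param d Dimension; requires `rank(S^T X) >= d`.
#' @param n_randomizations,seed Passed to [null_informativeness].
#' @return The projection score.
#' @export
projection_score <- function(X, selection, d, n_randomizations = 10, seed = 1) {
  X <- as_data_matrix(X)
  Xs <- apply_selection(selection, X)
  sv <- svd(Xs, nu = 0, nv = 0)$d
  if (length(sv) < d || sv[d] <= 1e-12 * sv[1])
    stop("insufficient submatrix rank: rank(S^T X) < ", d)
  tau <- informativeness(sv, d)
  tau - null_informativeness(Xs, d, n_randomizations, seed,
                             row_ids = selection_row_ids(selection))
}

#' Joint optimization of the projection score
#'
#' Sweeps a grid of variance-filtering thresholds (empirical quantiles of
#' the per-variable standard deviations, always including 0) crossed with
#' candidate dimensions `1..d_max`, scores every valid cell, and returns the
#' arg-max selection and dimension together with the full diagnostic grid.
#' Cells where fewer than `d + 1` variables survive, or where the submatrix
#' rank falls below `d`, are invalid and skipped. Ties at the arg-max prefer
#' the smaller dimension, then the larger threshold (fewer variables).
#'
#' @param X P x N numeric matrix.
#' @param config An [smssvd_config]; supplies the grid sizes,
#'   `n_randomizations` and default seed.
#' @param d_max_cap Optional extra cap on the candidate dimensions (used by
#'   [smssvd] to honor the remaining dimension budget).
#' @param seed Seed for the randomization streams (defaults to `config$seed`).
#' @return A list with elements `selection` (a `selection_map`), `d`,
#'   `threshold`, `score`, `grid` (a `score_grid`), and `fallback` (TRUE when
#'   no valid cell existed and the all-variables, d = 1 fallback was used).
#' @export
optimize_projection_score <- function(X, config = smssvd_config(),
                                      d_max_cap = Inf, seed = config$seed) {
  X <- as_data_matrix(X)
  P <- nrow(X); N <- ncol(X)
  sds <- row_sds(X)
  G <- config$threshold_grid_size
  qs <- quantile(sds, probs = seq_len(G - 1) / G, names = FALSE, type = 7)
  thresholds <- unique(c(0, qs[qs > 0]))
  d_max <- max(1L, min(config$d_max, N - 1L, d_max_cap))

  # Permutation streams are keyed by each variable's rank in the std
  # ordering, an intrinsic label, so the score grid is invariant under
  # reordering of the rows of X (up to ties in the stds).
  sd_rank <- integer(P)
  sd_rank[order(sds, decreasing = TRUE)] <- seq_len(P)

  n_thr <- length(thresholds)
  scores <- matrix(NA_real_, n_thr, d_max)
  n_selected <- integer(n_thr)
  for (t in seq_len(n_thr)) {
    idx <- which(sds > thresholds[t])
    n_selected[t] <- length(idx)
    if (length(idx) < 2L) next
    Xs <- X[idx, , drop = FALSE]
    sv <- gram_sv(Xs)
    if (sv[1] <= 0) next
    # Gram-based singular values: rank validity at 1e-7 relative (squaring
    # halves precision); the chosen cell is re-checked by select_expand.
    d_valid <- min(d_max, length(idx) - 1L, sum(sv > 1e-7 * sv[1]))
    if (d_valid < 1L) next
    tot <- sum(sv^2)
    tau_obs <- sqrt(cumsum(sv[seq_len(d_valid)]^2) / tot)
    tau_null <- null_tau_matrix(Xs, d_valid, config$n_randomizations,
                                derive_seed(seed, t), row_ids = sd_rank[idx])
    scores[t, seq_len(d_valid)] <- tau_obs - colMeans(tau_null)[seq_len(d_valid)]
  }

  grid <- structure(list(thresholds = thresholds, dims = seq_len(d_max),
                         scores = scores, n_selected = n_selected,
                         n_randomizations = config$n_randomizations,
                         seed = seed),
                    class = "score_grid")

  best <- NULL
  for (d in seq_len(d_max)) {        # d ascending: ties keep the smaller d
    for (t in seq_len(n_thr)) {      # threshold ascending
      sc <- scores[t, d]
      if (is.na(sc)) next
      if (is.null(best) || sc > best$score ||
          (sc == best$score && d == best$d && thresholds[t] > best$threshold)) {
        best <- list(threshold = thresholds[t], d = d, score = sc)
      }
    }
  }
  if (is.null(best)) {
    log_warn("no valid projection-score cell; falling back to all variables, d = 1")
    return(list(selection = selection_all(P), d = 1L, threshold = NA_real_,
                score = NA_real_, grid = grid, fallback = TRUE))
  }
  list(selection = selection_subset(which(sds > best$threshold), P),
       d = as.integer(best$d), threshold = best$threshold, score = best$score,
       grid = grid, fallback = FALSE)
}

#' @method print score_grid
#' @export
print.score_grid <- function(x, ...) {
  cat("score_grid: ", length(x$thresholds), " thresholds x ",
      length(x$dims), " dims, ", x$n_randomizations, " randomizations\n", sep = "")
  invisible(x)
}

#' Export a score grid as TSV
#'
#' One row per threshold: `threshold`, `n_selected`, then one score column
#' per dimension (`d1`, `d2`, ...). Invalid cells are left empty.
#'
#' @param grid A `score_grid`.
#' @param path Output file.
#' @export
write_score_grid <- function(grid, path) {
  stopifnot(inherits(grid, "score_grid"))
  df <- data.frame(threshold = fmt_num(grid$thresholds),
                   n_selected = grid$n_selected,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (d in grid$dims)
    df[[paste0("d", d)]] <- ifelse(is.na(grid$scores[, d]), "",
                                   fmt_num(grid$scores[, d]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
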