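#' Support-restricted reconstruction error
#'
#' `err(k) = || R_k^T (Y_k - Yhat_k) ||_F`: the Frobenius norm of the
#' reconstruction error restricted to the variables (rows) where the planted
#' signal has support. Entries outside the support are ignored.
#'
#' @param signal A `synthetic_signal` (with `Y` and `support`).
#' @param Y_hat Reconstructed P x N matrix.
#' @return The error value.
#' @export
reconstruction_error <- function(signal, Y_hat) {
  stopifnot(inherits(signal, "synthetic_signal"))
  if (!all(dim(Y_hat) == dim(signal$Y))) stop("shape mismatch")
  idx <- signal$support
  frob(signal$Y[idx, , drop = FALSE] - Y_hat[idx, , drop = FALSE])
}

#' Split a decomposition into rank-1 components
#'
#' @param result An `smssvd` object (or anything with `U`, `sigma`, `V`).
#' @return List of `list(u, sigma, v)` triplets, one per column.
#' @export
rank1_components <- function(result) {
  lapply(seq_along(result$sigma), function(j)
    list(u = result$U[, j], sigma = result$sigma[[j]], v = result$V[, j]))
}

#' Greedy matching of rank-1 components to planted signals
#'
#' Methods other than the generator do not label which component belongs to
#' which planted signal, so components are reordered by greedily matching
#' rank-1 matrices to signals: at every step, over all unassigned components
#' and all signals with remaining capacity (capacity = rank of the signal),
#' the pair whose addition to the signal's running reconstruction lowers the
#' total support-restricted error the most is committed. Exactly
#' `sum(rank(Y_k))` components end up assigned; surplus components stay
#' unassigned. Ties prefer the lowest component index, then the lowest
#' signal index.
#'
#' @param components List of rank-1 triplets (see [rank1_components]).
#' @param signals List of `synthetic_signal`s.
#' @return Object of class `component_assignment`: `assignment` (component
#'   index -> signal index or NA), `per_signal_error` (err(k)),
#'   `total_error`.
#' @export
greedy_match <- function(components, signals) {
  K <- length(signals)
  caps <- vapply(signals, function(s) length(s$sigma), integer(1))
  n_comp <- length(components)
  if (n_comp < sum(caps))
    stop("fewer components (", n_comp, ") than total signal rank (", sum(caps), ")")

  sup <- lapply(signals, `[[`, "support")
  Ysup <- lapply(signals, function(s) s$Y[s$support, , drop = FALSE])
  Yhat <- lapply(Ysup, function(y) array(0, dim(y)))
  cur_err <- vapply(Ysup, frob, numeric(1))
  # rank-1 component restricted to each signal's support rows
  comp_sup <- lapply(components, function(cm)
    lapply(seq_len(K), function(k)
      cm$sigma * tcrossprod(cm$u[sup[[k]]], cm$v)))

  assignment <- rep(NA_integer_, n_comp)
  remaining <- caps
  for (step in seq_len(sum(caps))) {
    best <- NULL
    for (ci in seq_len(n_comp)) {
      if (!is.na(assignment[ci])) next
      for (k in seq_len(K)) {
        if (remaining[k] == 0L) next
        delta <- frob(Ysup[[k]] - Yhat[[k]] - comp_sup[[ci]][[k]]) - cur_err[k]
        if (is.null(best) || delta < best$delta) best <- list(ci = ci, k = k, delta = delta)
      }
    }
    assignment[best$ci] <- best$k
    Yhat[[best$k]] <- Yhat[[best$k]] + comp_sup[[best$ci]][[best$k]]
    cur_err[best$k] <- cur_err[best$k] + best$delta
    remaining[best$k] <- remaining[best$k] - 1L
  }
  # recompute errors exactly (avoid accumulated delta rounding)
  per_signal <- vapply(seq_len(K), function(k) frob(Ysup[[k]] - Yhat[[k]]), numeric(1))
  structure(list(assignment = assignment, per_signal_error = per_signal,
                 total_error = sum(per_signal)),
            class = "component_assignment")
}

#' Benchmark sweep over synthetic conditions
#'
#' For every grid cell and replicate: generate a dataset, run each method to
#' total dimension `K * d`, split the output into rank-1 components, greedily
#' match them to the planted signals, and record the support-restricted
#' error err(k) together with the signal strength `||Y_k||_F`. Errors larger
#' than the signal strength are flagged (they indicate that a different
#' signal was found). Method failures are recorded as missing with a reason
#' and the sweep continues.
#'
#' @param param_grid Data frame with columns `P`, `L`, `d`, `sigma` and
#'   optionally `regime` (default `"all"`).
#' @param methods Subset of `c("truncated_svd", "smssvd")`.
#' @param n_replicates Replicates per cell.
#' @param seed Master seed.
#' @param N,K Fixed sample count and signal count (defaults 100 and 8).
#' @param n_randomizations Projection-score randomizations for smssvd.
#' @param disjoint_supports Passed to [synthetic_config]; noiseless
#'   recovery is exact for the selection-based method only when supports do
#'   not overlap.
#' @return Tidy long-format data frame: one row per
#'   (cell, replicate, method, signal).
#' @export
benchmark_sweep <- function(param_grid, methods = c("truncated_svd", "smssvd"),
                            n_replicates = 1, seed = 1, N = 100, K = 8,
                            n_randomizations = 10, disjoint_supports = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(all(c("P", "L", "d", "sigma") %in% names(param_grid)))
  if (is.null(param_grid$regime)) param_grid$regime <- "all"
  rows <- list()
  for (cell in seq_len(nrow(param_grid))) {
    g <- param_grid[cell, ]
    for (rep_i in seq_len(n_replicates)) {
      ds_seed <- derive_seed(seed, cell, rep_i)
      regime <- if (g$sigma == 0) "none" else as.character(g$regime)
      ds <- generate_dataset(synthetic_config(
        P = g$P, L = g$L, d = g$d, N = N, K = K, noise_sigma = g$sigma,
        noise_support = regime, disjoint_supports = disjoint_supports,
        seed = ds_seed))
      D <- K * g$d
      strength <- vapply(ds$signals, function(s) frob(s$sigma), numeric(1))
      for (m in methods) {
        res <- tryCatch({
          dec <- switch(m,
            truncated_svd = {
              sv <- svd(ds$X)
              list(U = sv$u[, seq_len(D), drop = FALSE],
                   sigma = sv$d[seq_len(D)],
                   V = sv$v[, seq_len(D), drop = FALSE])
            },
            smssvd = smssvd(ds$X, target_dim = D,
                            config = smssvd_config(
                              seed = derive_seed(ds_seed, match(m, methods)),
                              n_randomizations = n_randomizations)))
          gm <- greedy_match(rank1_components(dec), ds$signals)
          list(err = gm$per_signal_error, note = "")
        }, error = function(e)
          list(err = rep(NA_real_, K), note = conditionMessage(e)))
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_i, P = g$P, L = g$L, d = g$d, sigma = g$sigma,
          regime = regime, method = m, signal_index = seq_len(K),
          err = res$err, signal_strength = strength,
          flagged = !is.na(res$err) & res$err > strength,
          note = res$note, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Gaussian-mixture AIC score of a sample representation
#'
#' Fits one multivariate Gaussian per class (maximum-likelihood mean and
#' covariance from that class's rows) with class priors proportional to
#' class sizes, and scores how well the low-dimensional representation
#' explains the class labels: the log-likelihood is the conditional
#' (classification) likelihood of the labels given the coordinates by
#' Bayes' rule, `l = sum_i log P(label_i | coords_i)`, and
#' `AIC = 2 k - 2 l` with `k = C * (D + D (D + 1) / 2)` fitted parameters
#' (priors are determined by counts, not fitted).
#'
#' @param coords N x D matrix of sample coordinates.
#' @param labels N class labels.
#' @param ridge Optional diagonal regularization, `lambda * trace / D` added
#'   to each covariance diagonal (default 0, i.e. none).
#' @return Object of class `gmm_score`: `loglik`, `n_params`, `aic`,
#'   `per_class` (mean, covariance, prior per class).
#' @export
gmm_aic <- function(coords, labels, ridge = 0) {
  coords <- as.matrix(coords)
  N <- nrow(coords); D <- ncol(coords)
  if (D < 1L) stop("coords must have at least one dimension")
  labels <- as.factor(labels)
  if (length(labels) != N) stop("labels length must match nrow(coords)")
  classes <- levels(labels)
  C <- length(classes)
  counts <- table(labels)
  if (any(counts < D + 1L))
    stop("class '", names(counts)[which(counts < D + 1L)[1]],
         "' has fewer than D + 1 members; covariance is not estimable")

  per_class <- vector("list", C)
  names(per_class) <- classes
  logdens <- matrix(NA_real_, N, C)
  for (c in seq_len(C)) {
    rows <- which(labels == classes[c])
    xc <- coords[rows, , drop = FALSE]
    mu <- colMeans(xc)
    cen <- sweep(xc, 2, mu)
    S <- crossprod(cen) / length(rows)           # ML covariance
    if (ridge > 0) S <- S + diag(ridge * sum(diag(S)) / D, D)
    R <- tryCatch(chol(S), error = function(e)
      stop("singular covariance in class '", classes[c], "'", call. = FALSE))
    per_class[[c]] <- list(mean = mu, cov = S, prior = length(rows) / N)
    dev <- forwardsolve(t(R), t(sweep(coords, 2, mu)))
    logdens[, c] <- -0.5 * (D * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(dev^2))
  }
  logpost <- sweep(logdens, 2, log(vapply(per_class, `[[`, numeric(1), "prior")), `+`)
  m <- apply(logpost, 1, max)
  lse <- m + log(rowSums(exp(logpost - m)))
  l <- sum(logpost[cbind(seq_len(N), as.integer(labels))] - lse)
  k <- C * (D + D * (D + 1) / 2)
  structure(list(loglik = l, n_params = k, aic = 2 * k - 2 * l,
                 per_class = per_class),
            class = "gmm_score")
}

#' @method print gmm_score
#' @export
print.gmm_score <- function(x, ...) {
  cat("gmm_score: ", length(x$per_class), " classes, loglik = ",
      signif(x$loglik, 6), ", n_params = ", x$n_params,
      ", AIC = ", signif(x$aic, 6), "\n", sep = "")
  invisible(x)
}
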