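#' Configuration for the synthetic benchmark generator
#'
#' Describes a dataset of K mutually orthogonal low-rank signals with sparse
#' variable support plus Gaussian noise: `X = sum_k Y_k + eps`, with
#' `Y_k = U_k Sigma_k V_k^T`, `U_k` supported on L variables, singular values
#' following the geometric schedule [sigma_schedule], and
#' `eps_ij ~ N(0, sigma_ij)`.
#'
#' @param P Number of variables.
#' @param L Support size (variables per signal).
#' @param d Rank of each signal.
#' @param N Number of samples (default 100).
#' @param K Number of signals (default 8).
#' @param noise_sigma Noise standard deviation: scalar, length-P vector, or
#'   P x N matrix (default 0.1).
#' @param noise_support `"all"` (every entry), `"non_signal_only"` (noise
#'   zeroed on the union of signal supports), or `"none"`.
#' @param disjoint_supports If TRUE, signal supports are drawn without
#'   overlap (requires `K * L <= P`).
#' @param seed Master seed; every (signal, factor side, column) gets its own
#'   derived substream so changing K or d does not perturb earlier columns.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(P, L, d, N = 100, K = 8, noise_sigma = 0.1,
                             noise_support = c("all", "non_signal_only", "none"),
                             disjoint_supports = FALSE, seed = 1) {
  noise_support <- match.arg(noise_support)
  P <- as.integer(P); L <- as.integer(L); d <- as.integer(d)
  N <- as.integer(N); K <- as.integer(K)
  if (K * d > min(N, P)) stop("infeasible: K * d must be <= min(N, P)")
  if (L < d) stop("infeasible: support size L must be >= rank d")
  if (L > P) stop("L must be <= P")
  if (disjoint_supports && K * L > P)
    stop("infeasible: disjoint supports require K * L <= P")
  if (any(noise_sigma < 0)) stop("noise_sigma must be nonnegative")
  if (is.matrix(noise_sigma)) {
    if (nrow(noise_sigma) != P || ncol(noise_sigma) != N)
      stop("matrix noise_sigma must be P x N")
  } else if (length(noise_sigma) != 1L && length(noise_sigma) != P) {
    stop("noise_sigma must be a scalar, length-P vector, or P x N matrix")
  }
  structure(list(P = P, L = L, d = d, N = N, K = K, noise_sigma = noise_sigma,
                 noise_support = noise_support,
                 disjoint_supports = isTRUE(disjoint_supports),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Singular-value schedule of the planted signals
#'
#' The i-th singular value of signal k is `0.6^(k-1) * 0.9^(i-1)`: power
#' declines geometrically both between signals and within the components of
#' each signal.
#'
#' @param k Signal index (>= 1).
#' @param d Signal rank.
#' @return Vector of d singular values.
#' @export
sigma_schedule <- function(k, d) {
  if (k < 1 || d < 1) stop("k and d must be >= 1")
  0.6^(k - 1) * 0.9^(seq_len(d) - 1)
}

#' Draw one orthonormal column
#'
#' Samples a vector of i.i.d. standard Gaussians, projects it onto the
#' orthogonal complement of the span of the `forbidden` columns, and
#' normalizes. With `support` given, the draw and projection happen within
#' the support coordinates (against the forbidden columns restricted to the
#' support) and the result is expanded by inserting zeros elsewhere — which
#' still guarantees full-space orthogonality to the forbidden columns.
#' Draws from the current R RNG state.
#'
#' @param dim Length of the returned vector.
#' @param forbidden Matrix of previously used columns (or NULL).
#' @param support Optional index set outside which the column is zero.
#' @return Unit vector of length `dim`.
#' @export
orthonormal_column <- function(dim, forbidden = NULL, support = NULL) {
  coords <- if (is.null(support)) seq_len(dim) else as.integer(support)
  z <- rnorm(length(coords))
  if (!is.null(forbidden) && ncol(forbidden) > 0L) {
    B <- forbidden[coords, , drop = FALSE]
    qrB <- qr(B)
    r <- qrB$rank
    if (r >= length(coords))
      stop("orthogonal complement exhausted: no room for another column")
    if (r > 0L) {
      Q <- qr.Q(qrB)[, seq_len(r), drop = FALSE]
      z <- z - Q %*% crossprod(Q, z)
    }
  }
  nrm <- sqrt(sum(z^2))
  if (nrm < 1e-8) stop("orthogonal complement exhausted: projection left a zero vector")
  out <- numeric(dim)
  out[coords] <- z / nrm
  out
}

#' Generate a synthetic benchmark dataset
#'
#' Builds K mutually orthogonal signals `Y_k = U_k Sigma_k V_k^T`: each new
#' `V_k` column is drawn orthogonal to all previous V columns (in the current
#' and previous signals) in full sample space; each new `U_k` column is drawn
#' on the signal's L-variable support, orthogonal to all previous U columns,
#' and zero elsewhere. Singular values follow [sigma_schedule]. Gaussian
#' noise `eps_ij ~ N(0, sigma_ij)` is added according to `noise_support`,
#' and `X = sum_k Y_k + eps`.
#'
#' @param config A [synthetic_config].
#' @return An object of class `synthetic_dataset`: list with `signals`
#'   (each a `synthetic_signal` with `Y`, `U`, `sigma`, `V`, `support`),
#'   `noise`, `X`, and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  P <- config$P; N <- config$N; K <- config$K
  L <- config$L; d <- config$d
  master <- config$seed

  supports <- vector("list", K)
  if (config$disjoint_supports) {
    set.seed(derive_seed(master, 0L, 4L, 0L))
    perm <- sample.int(P)
    for (k in seq_len(K)) supports[[k]] <- sort(perm[((k - 1L) * L + 1L):(k * L)])
  } else {
    for (k in seq_len(K)) {
      set.seed(derive_seed(master, k, 0L, 0L))
      supports[[k]] <- sort(sample.int(P, L))
    }
  }

  Uall <- matrix(0, P, 0)
  Vall <- matrix(0, N, 0)
  signals <- vector("list", K)
  for (k in seq_len(K)) {
    sigma <- sigma_schedule(k, d)
    Uk <- matrix(0, P, d)
    Vk <- matrix(0, N, d)
    for (i in seq_len(d)) {
      set.seed(derive_seed(master, k, 2L, i))
      v <- orthonormal_column(N, forbidden = Vall)
      Vk[, i] <- v
      Vall <- cbind(Vall, v)
      set.seed(derive_seed(master, k, 1L, i))
      u <- tryCatch(orthonormal_column(P, forbidden = Uall, support = supports[[k]]),
                    error = function(e)
                      stop("signal ", k, ", column ", i, ": support capacity exhausted (",
                           conditionMessage(e), ")", call. = FALSE))
      Uk[, i] <- u
      Uall <- cbind(Uall, u)
    }
    Y <- Uk %*% (sigma * t(Vk))
    signals[[k]] <- structure(list(Y = Y, U = Uk, sigma = sigma, V = Vk,
                                   support = supports[[k]]),
                              class = "synthetic_signal")
  }

  if (config$noise_support == "none") {
    eps <- matrix(0, P, N)
  } else {
    set.seed(derive_seed(master, 0L, 3L, 0L))
    eps <- matrix(rnorm(P * N), P, N)
    eps <- if (is.matrix(config$noise_sigma)) eps * config$noise_sigma
           else eps * config$noise_sigma    # scalar or per-variable recycling by row
    if (config$noise_support == "non_signal_only") {
      sig_rows <- sort(unique(unlist(supports)))
      eps[sig_rows, ] <- 0
    }
  }

  X <- Reduce(`+`, lapply(signals, `[[`, "Y")) + eps
  rownames(X) <- paste0("var", seq_len(P))
  colnames(X) <- paste0("sample", seq_len(N))
  structure(list(signals = signals, noise = eps, X = X, config = config),
            class = "synthetic_dataset")
}

#' The two-signal partial-noise benchmark geometry
#'
#' Two 2-d signals with non-overlapping 64-variable supports in a 5000 x 32
#' matrix, under one of three noise regimes: no noise, noise on the
#' non-signal variables only, or noise everywhere.
#'
#' @param regime Noise regime.
#' @param seed Master seed.
#' @param noise_sigma Noise scale (ignored for `"none"`).
#' @return A `synthetic_dataset`.
#' @export
two_signal_fixture <- function(regime = c("none", "non_signal_only", "all"),
                            seed = 1, noise_sigma = 0.1) {
  regime <- match.arg(regime)
  generate_dataset(synthetic_config(P = 5000, L = 64, d = 2, N = 32, K = 2,
                                    noise_sigma = noise_sigma,
                                    noise_support = regime,
                                    disjoint_supports = TRUE, seed = seed))
}

#' @method print synthetic_dataset
#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat("synthetic_dataset: ", cfg$K, " signal(s) of rank ", cfg$d, ", P = ", cfg$P,
      ", N = ", cfg$N, ", L = ", cfg$L, ", noise = ", cfg$noise_support, "\n", sep = "")
  invisible(x)
}
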