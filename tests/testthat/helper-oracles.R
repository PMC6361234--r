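# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data.

rand_mat <- function(p, n, seed) {
  set.seed(seed)
  matrix(rnorm(p * n), p, n)
}

# Orthonormal basis of a random d-dimensional subspace of the row space of X
# (hence orthogonal to ker X): random rotation of the leading right singular
# vectors.
random_rowspace_basis <- function(X, d, seed) {
  sv <- svd(X, nu = 0)
  r <- sum(sv$d > 1e-12 * sv$d[1])
  stopifnot(d <= r)
  set.seed(seed)
  Vr <- sv$v[, seq_len(r), drop = FALSE]
  Q <- qr.Q(qr(matrix(rnorm(r * d), r, d)))
  Vr %*% Q
}

frob_ <- function(x) sqrt(sum(x^2))

# Independent null-informativeness oracle: consumes the same permutation
# streams as the package kernel but recomputes tau with base svd().
null_oracle <- function(Xs, d, n_rand, seed, row_ids = seq_len(nrow(Xs))) {
  perms <- row_permutations(row_ids, ncol(Xs), n_rand, seed)
  tot <- sum(Xs^2)
  taus <- vapply(perms, function(P) {
    M <- Xs
    for (r in seq_len(nrow(Xs))) M[r, ] <- Xs[r, P[r, ]]
    sv <- svd(M, nu = 0, nv = 0)$d
    sqrt(sum(sv[seq_len(d)]^2) / tot)
  }, numeric(1))
  mean(taus)
}

# Brute-force minimal total support-restricted error over all
# capacity-respecting assignments of components to signals (for small
# instances only).
brute_force_match <- function(components, signals) {
  K <- length(signals)
  caps <- vapply(signals, function(s) length(s$sigma), integer(1))
  n_comp <- length(components)
  Ysup <- lapply(signals, function(s) s$Y[s$support, , drop = FALSE])
  comp_sup <- lapply(components, function(cm)
    lapply(seq_len(K), function(k)
      cm$sigma * tcrossprod(cm$u[signals[[k]]$support], cm$v)))
  best <- Inf
  # total error of one assignment, given as a list of component-index sets
  assign_err <- function(sets) {
    tot <- 0
    for (k in seq_len(K)) {
      Yhat <- array(0, dim(Ysup[[k]]))
      for (ci in sets[[k]]) Yhat <- Yhat + comp_sup[[ci]][[k]]
      tot <- tot + frob_(Ysup[[k]] - Yhat)
    }
    tot
  }
  enumerate <- function(k, remaining, sets) {
    if (k > K) {
      e <- assign_err(sets)
      if (e < best) best <<- e
      return(invisible(NULL))
    }
    choices <- utils::combn(remaining, caps[k], simplify = FALSE)
    for (ch in choices) enumerate(k + 1L, setdiff(remaining, ch), c(sets, list(ch)))
  }
  enumerate(1L, seq_len(n_comp), list())
  best
}

# Quick access to a small planted dataset.
small_dataset <- function(seed = 1, P = 200, L = 30, d = 2, N = 30, K = 2,
                          noise_support = "none", noise_sigma = 0,
                          disjoint = TRUE) {
  generate_dataset(synthetic_config(P = P, L = L, d = d, N = N, K = K,
                                    noise_sigma = noise_sigma,
                                    noise_support = noise_support,
                                    disjoint_supports = disjoint, seed = seed))
}
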