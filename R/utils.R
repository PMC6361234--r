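# Internal numeric helpers shared across modules.

frob <- function(x) sqrt(sum(x^2))

#' Numerical rank from singular values
#'
#' Counts singular values above `tol_rel` times the largest one.
#'
#' @param sv Nonincreasing vector of singular values.
#' @param tol_rel Relative cutoff (default `1e-12`).
#' @return Integer rank.
#' @export
numerical_rank <- function(sv, tol_rel = 1e-12) {
  if (length(sv) == 0L || sv[1] <= 0) return(0L)
  sum(sv > tol_rel * sv[1])
}

# Singular values via the Gram matrix on the smaller side. Fast for
# P >> N submatrices; accuracy of small values is ~sqrt(eps) relative,
# callers that need 1e-12 rank decisions must use svd() instead.
gram_sv <- function(M) {
  if (length(M) == 0L) return(numeric(0))
  G <- if (nrow(M) <= ncol(M)) tcrossprod(M) else crossprod(M)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}

top_sv <- function(M) {
  sv <- gram_sv(M)
  if (length(sv) == 0L) 0 else sv[1]
}

# Deterministic sign convention: flip each singular triplet so that the
# largest-magnitude entry of the U column is positive (ties -> lowest index,
# which is what which.max returns).
fix_signs <- function(U, V) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  list(U = U, V = V)
}

# Derive reproducible integer sub-seeds (< 2^31) from a master seed and a
# sequence of integer tags. 69069 * 2^31 < 2^53 so the arithmetic is exact
# in doubles.
derive_seed <- function(master, ...) {
  s <- as.numeric(master) %% 2147483563
  for (x in c(...)) s <- (s * 69069 + as.numeric(x)) %% 2147483563
  as.integer(s)
}

row_sds <- function(X) {
  n <- ncol(X)
  if (n < 2L) return(rep(0, nrow(X)))
  m <- rowMeans(X)
  sqrt(pmax(rowSums((X - m)^2), 0) / (n - 1))
}

# 17 significant digits: round-trip exact for doubles.
fmt_num <- function(x) sprintf("%.17g", x)

log_info <- function(...) message("INFO  [smssvd] ", ...)
log_warn <- function(...) warning("[smssvd] ", ..., call. = FALSE)
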