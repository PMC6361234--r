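test_that("restricted_svd with the full row space reproduces the SVD", {
  X <- rand_mat(4, 3, seed = 11)
  f <- restricted_svd(X, diag(3))
  sv <- svd(X)
  expect_equal(f$sigma, sv$d, tolerance = 1e-12)
  expect_equal(abs(f$U), abs(sv$u), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(abs(f$V), abs(sv$v), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("restricted_svd on an axis-aligned restriction of a diagonal matrix", {
  X <- diag(c(3, 2))
  f <- restricted_svd(X, matrix(c(1, 0), 2, 1))
  expect_equal(f$sigma, 3)
  expect_equal(as.numeric(f$U), c(1, 0))
  expect_equal(as.numeric(f$V), c(1, 0))
})

test_that("restricted_svd on the top right-singular subspace equals the truncated SVD", {
  X <- rand_mat(6, 4, seed = 7)
  sv <- svd(X)
  f <- restricted_svd(X, sv$v[, 1:2])
  expect_equal(f$sigma, sv$d[1:2], tolerance = 1e-12)
  expect_lt(max(abs(X %*% f$V - f$U %*% diag(f$sigma))), 1e-10)
  expect_equal(abs(f$U), abs(sv$u[, 1:2]), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("restricted_svd rejects bad subspaces", {
  X <- rand_mat(6, 4, seed = 8)
  X[, 4] <- X[, 1] + X[, 2]           # rank 3, nontrivial kernel
  kern <- svd(X)$v[, 4, drop = FALSE]
  expect_error(restricted_svd(X, kern), "null space")
  expect_error(restricted_svd(rand_mat(5, 3, 1), diag(4)), "one row per sample")
  expect_error(restricted_svd(rand_mat(5, 3, 1), matrix(1, 3, 2)), "orthonormal")
})

test_that("decomposition identities hold for random restrictions", {
  # properties of the SVD of X restricted to a random subspace of the row
  # space: XV = U Sigma, orthonormal factors, deflation identity, rank
  # additivity, V and U orthogonal to kernel and cokernel
  for (case in list(list(p = 8, n = 5, d = 2, seed = 21),
                    list(p = 5, n = 5, d = 3, seed = 22),
                    list(p = 40, n = 7, d = 4, seed = 23))) {
    X <- rand_mat(case$p, case$n, case$seed)
    B <- random_rowspace_basis(X, case$d, case$seed + 100)
    f <- restricted_svd(X, B)
    expect_lt(max(abs(X %*% f$V - f$U %*% diag(f$sigma, case$d))), 1e-10)
    expect_lt(max(abs(crossprod(f$U) - diag(case$d))), 1e-10)
    expect_lt(max(abs(crossprod(f$V) - diag(case$d))), 1e-10)
    resid <- remove_signal(X, f)
    expect_lt(max(abs(resid %*% f$V)), 1e-10)             # (I-UU')X(I-VV') = (I-UU')X
    sv_r <- svd(resid, nu = 0, nv = 0)$d
    expect_equal(sum(sv_r > 1e-10 * max(svd(X)$d)),
                 min(case$p, case$n) - case$d)            # rank additivity
    # V spans exactly the requested subspace
    expect_lt(max(abs(tcrossprod(f$V) - tcrossprod(B))), 1e-10)
  }
})

test_that("select_expand with the identity selection is the truncated SVD", {
  X <- rand_mat(10, 6, seed = 31)
  f <- select_expand(X, selection_all(10), 2)
  sv <- svd(X)
  expect_equal(f$sigma, sv$d[1:2], tolerance = 1e-12)
  expect_equal(abs(f$U), abs(sv$u[, 1:2]), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(f$submatrix_sigma, sv$d[1:2], tolerance = 1e-12)
})

test_that("selection-expansion contract on a row subset", {
  X <- rand_mat(6, 4, seed = 41)
  sel <- selection_subset(c(1, 3, 5), 6)
  f <- select_expand(X, sel, 1)
  # variable selection inverts variable expansion: S'USV' = tilde(U S V')
  lowrank <- f$U %*% diag(f$sigma, 1) %*% t(f$V)
  sv_sub <- svd(X[c(1, 3, 5), ])
  tilde <- sv_sub$u[, 1, drop = FALSE] %*% diag(sv_sub$d[1], 1) %*% t(sv_sub$v[, 1, drop = FALSE])
  expect_lt(max(abs(lowrank[c(1, 3, 5), ] - tilde)), 1e-8)
  # norm inequality for orthonormal selections
  expect_gte(frob_(f$sigma), frob_(f$submatrix_sigma))
  # V spans the same subspace as tilde V
  expect_lt(max(abs(tcrossprod(f$V) - tcrossprod(sv_sub$v[, 1, drop = FALSE]))), 1e-8)
})

test_that("selection-expansion residual identity involves only unselected variables", {
  # U'X = Sigma V' + U'(I - SS')X(I - VV')
  X <- rand_mat(9, 5, seed = 43)
  idx <- c(2, 4, 5, 8)
  sel <- selection_subset(idx, 9)
  f <- select_expand(X, sel, 2)
  SSt <- diag(as.numeric(seq_len(9) %in% idx))
  lhs <- crossprod(f$U, X)
  rhs <- diag(f$sigma) %*% t(f$V) +
    crossprod(f$U, (diag(9) - SSt) %*% X %*% (diag(5) - tcrossprod(f$V)))
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("select_expand supports diagonal weighting", {
  X <- rand_mat(8, 5, seed = 47)
  w <- c(2, 0, 1, 0.5, 0, 3, 1, 0.25)
  sel <- selection_weights(w)
  f <- select_expand(X, sel, 2)
  sv_sub <- svd(w * X)
  # S' U Sigma V' = tilde(U) tilde(Sigma) tilde(V)'
  lowrank <- w * (f$U %*% diag(f$sigma) %*% t(f$V))
  tilde <- sv_sub$u[, 1:2] %*% diag(sv_sub$d[1:2]) %*% t(sv_sub$v[, 1:2])
  expect_lt(max(abs(lowrank - tilde)), 1e-8)
  # general norm inequality: ||Sigma||_F >= ||tilde Sigma||_F / ||S||_2
  expect_gte(frob_(f$sigma), frob_(f$submatrix_sigma) / max(w))
})

test_that("select_expand errors are informative", {
  X <- rand_mat(6, 4, seed = 51)
  X[2, ] <- X[1, ]
  expect_error(select_expand(X, selection_subset(c(1, 2), 6), 2),
               "insufficient submatrix rank")
  expect_error(selection_subset(integer(0), 6), "empty selection")
  expect_error(select_expand(X, selection_subset(1:6, 6), 0), "d must be >= 1")
})

test_that("remove_signal deflates exactly", {
  X <- rand_mat(6, 4, seed = 61)
  # removing a full-row-space signal leaves zero
  f <- restricted_svd(X, svd(X)$v)
  expect_lt(max(abs(remove_signal(X, f))), 1e-10)
  # d = 0 leaves X unchanged
  f0 <- signal_factors(matrix(0, 6, 0), numeric(0), matrix(0, 4, 0))
  expect_identical(remove_signal(X, f0), X)
  # removing a d = 2 signal from a rank-5 matrix leaves rank 3
  A <- rand_mat(10, 5, 62) %*% t(rand_mat(8, 5, 63))   # 10 x 8, rank 5
  fb <- restricted_svd(A, random_rowspace_basis(A, 2, 64))
  sv <- svd(remove_signal(A, fb), nu = 0, nv = 0)$d
  expect_equal(sum(sv > 1e-10 * svd(A)$d[1]), 3)
  # idempotence
  R1 <- remove_signal(A, fb)
  expect_equal(remove_signal(R1, fb), R1, tolerance = 1e-12)
  # shape mismatch
  expect_error(remove_signal(rand_mat(4, 8, 65), fb), "variables")
})

test_that("concatenate_signals and reconstruct are consistent", {
  ds <- small_dataset(seed = 5)
  res <- suppressMessages(smssvd(ds$X, target_dim = 4, config = smssvd_config(seed = 9)))
  D <- res$total_dim
  expect_lt(max(abs(crossprod(res$U) - diag(D))), 1e-8)
  expect_lt(max(abs(crossprod(res$V) - diag(D))), 1e-8)
  # reconstruction equals the naive per-signal outer-product sum
  naive <- Reduce(`+`, lapply(res$signals, function(s)
    s$U %*% diag(s$sigma, s$d) %*% t(s$V)))
  expect_equal(unname(reconstruct(res)), unname(naive), tolerance = 1e-12)
  # single signal round-trips unchanged
  one <- concatenate_signals(res$signals[1], res$residual)
  expect_identical(one$signals[[1]], res$signals[[1]])
  expect_equal(one$total_dim, res$signals[[1]]$d)
  # component naming follows s<k>c<i>
  expect_identical(colnames(res$U)[1:2], c("s1c1", "s1c2"))
  # empty result reconstructs to zero
  empty <- concatenate_signals(list(), ds$X)
  expect_true(all(reconstruct(empty) == 0))
  # signals not produced by deflation are rejected
  bad <- res$signals
  bad[[2]] <- bad[[1]]
  expect_error(concatenate_signals(bad, res$residual), "orthogonality")
})

test_that("smssvd with selection disabled equals the truncated SVD", {
  X <- rand_mat(20, 10, seed = 71)
  res <- suppressMessages(smssvd(X, target_dim = 4,
                                 config = smssvd_config(disable_selection = TRUE)))
  sv <- svd(X)
  expect_equal(unname(res$sigma), sv$d[1:4], tolerance = 1e-10)
  for (j in 1:4) {
    s <- sign(sum(res$U[, j] * sv$u[, j]))
    expect_lt(max(abs(res$U[, j] - s * sv$u[, j])), 1e-10)
    expect_lt(max(abs(res$V[, j] - s * sv$v[, j])), 1e-10)
  }
  # full-rank, no selection: reconstruction equals X
  full <- suppressMessages(smssvd(X, target_dim = 10,
                                  config = smssvd_config(disable_selection = TRUE)))
  expect_equal(unname(reconstruct(full)), X, tolerance = 1e-8)
})

test_that("smssvd recovers noiseless planted signals exactly", {
  ds <- small_dataset(seed = 13, P = 400, L = 50, d = 2, K = 2, N = 40)
  res <- suppressMessages(smssvd(ds$X, target_dim = 4, config = smssvd_config(seed = 3)))
  gm <- greedy_match(rank1_components(res), ds$signals)
  for (k in 1:2)
    expect_lt(gm$per_signal_error[k], 1e-8 * frob_(ds$signals[[k]]$sigma))
  # reconstruction equals the clean signal sum
  expect_equal(unname(reconstruct(res)), Reduce(`+`, lapply(ds$signals, `[[`, "Y")),
               tolerance = 1e-8)
})

test_that("smssvd handles rank deficiency and bad inputs", {
  A <- rand_mat(8, 3, 81) %*% t(rand_mat(6, 3, 82))    # 8 x 6, rank 3
  expect_warning(
    res <- smssvd(A, target_dim = 5,
                  config = smssvd_config(disable_selection = TRUE)),
    "exceeds rank")
  expect_equal(res$total_dim, 3L)
  expect_error(smssvd(matrix(0, 4, 4), target_dim = 2), "zero input")
  expect_error(suppressMessages(smssvd(rand_mat(5, 5, 1), target_dim = 9)), "target_dim")
})

test_that("smssvd is deterministic given input and seed", {
  ds <- small_dataset(seed = 17, noise_sigma = 0.01, noise_support = "all")
  r1 <- suppressMessages(smssvd(ds$X, target_dim = 4, config = smssvd_config(seed = 5)))
  r2 <- suppressMessages(smssvd(ds$X, target_dim = 4, config = smssvd_config(seed = 5)))
  expect_identical(r1$U, r2$U)
  expect_identical(r1$sigma, r2$sigma)
  expect_identical(r1$V, r2$V)
  expect_identical(r1$residual, r2$residual)
})

test_that("library mode stops at the true rank on noiseless data", {
  ds <- small_dataset(seed = 19, P = 120, L = 25, d = 2, K = 2, N = 20)
  res <- suppressMessages(smssvd(ds$X, config = smssvd_config(seed = 11)))
  expect_equal(res$total_dim, 4L)
  expect_lt(max(abs(res$residual)), 1e-8)
})
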