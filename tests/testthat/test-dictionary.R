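test_that("sav_offdiag sums off-diagonal Gram entries", {
  expect_equal(sav_offdiag(diag(4)), 0) # orthogonal columns
  v <- runif(6); v <- v / sqrt(sum(v^2))
  expect_equal(sav_offdiag(cbind(v, v)), 2) # identical unit columns
  set.seed(1)
  Phi <- matrix(abs(rnorm(18)), 6, 3)
  G <- crossprod(Phi)
  expect_equal(sav_offdiag(Phi), sum(G) - sum(diag(G))) # algebraic identity
})

test_that("dictionary objective matches term-by-term recomputation", {
  set.seed(2)
  N <- 7; Tn <- 9; M <- 3
  A <- matrix(abs(rnorm(N * M)), N, M)
  Phi <- matrix(abs(rnorm(Tn * M)), Tn, M)
  Phi_prev <- matrix(abs(rnorm(Tn * M)), Tn, M)
  Y <- matrix(rnorm(N * Tn), N, Tn)
  cfg <- dictionary_config(gamma1 = 0.3, gamma2 = 0.2, gamma3 = 0.15)
  got <- dictionary_objective(Y, A, Phi, Phi_prev, cfg)
  want <- sum((Y - A %*% t(Phi))^2) + 0.3 * sum(Phi^2) +
    0.2 * (sum(crossprod(Phi)) - sum(colSums(Phi^2))) +
    0.15 * sum((Phi - Phi_prev)^2)
  expect_equal(got, want)
  # perfect fit with zero gammas is exactly zero
  cfg0 <- dictionary_config(gamma1 = 0, gamma2 = 0, gamma3 = 0)
  expect_equal(dictionary_objective(A %*% t(Phi), A, Phi, Phi_prev, cfg0), 0)
  # Phi = Phi_prev removes the smoothness contribution
  expect_equal(dictionary_objective(Y, A, Phi, Phi, cfg) -
                 dictionary_objective(Y, A, Phi, Phi,
                                      dictionary_config(0.3, 0.2, 0)), 0)
  expect_error(dictionary_objective(Y, A, Phi[1:5, ], Phi_prev, cfg), "mismatch")
})

test_that("update with orthonormal A and no regularization is least squares", {
  set.seed(3)
  N <- 12; Tn <- 10; M <- 3
  A <- qr.Q(qr(matrix(rnorm(N * M), N, M)))
  Y <- matrix(rnorm(N * Tn), N, Tn)
  cfg <- dictionary_config(gamma1 = 0, gamma2 = 0, gamma3 = 0, nonneg = FALSE,
                           solver_tol = 1e-14)
  Phi <- update_dictionary(Y, A, matrix(0, Tn, M), cfg)
  expect_equal(unclass(Phi), crossprod(Y, A), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("huge smoothness keeps the previous dictionary", {
  set.seed(4)
  N <- 10; Tn <- 12; M <- 3
  A <- matrix(abs(rnorm(N * M)), N, M)
  Phi_prev <- matrix(abs(rnorm(Tn * M)), Tn, M)
  Y <- matrix(abs(rnorm(N * Tn)), N, Tn)
  Phi <- update_dictionary(Y, A, Phi_prev,
                           dictionary_config(gamma3 = 1e10))
  expect_equal(unclass(Phi), Phi_prev, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("nonnegative update reaches the projected-gradient optimum", {
  set.seed(5)
  N <- 15; Tn <- 20; M <- 3
  A <- matrix(rbinom(N * M, 1, 0.5) * runif(N * M), N, M)
  Ptrue <- matrix(abs(rnorm(Tn * M)), Tn, M)
  Y <- tcrossprod(A, Ptrue) + 0.05 * matrix(rnorm(N * Tn), N, Tn)
  Phi_prev <- matrix(abs(rnorm(Tn * M)), Tn, M)
  cfg <- dictionary_config(gamma1 = 0.2, gamma2 = 0.1, gamma3 = 0.1,
                           solver_tol = 1e-14, max_sweeps = 2000)
  Phi <- update_dictionary(Y, A, Phi_prev, cfg)
  # oracle: long-run projected gradient, independent implementation
  G <- crossprod(A); B <- crossprod(Y, A)
  L <- 2 * (norm(G, "2") + 0.2 + 0.1 + 0.1 * (M - 1))
  X <- Phi_prev
  off <- matrix(1, M, M) - diag(M)
  for (it in 1:20000) {
    gr <- 2 * (X %*% G - B) + 2 * 0.2 * X + 2 * 0.1 * (X %*% off) +
      2 * 0.1 * (X - Phi_prev)
    X <- pmax(X - gr / L, 0)
  }
  o_pkg <- dictionary_objective(Y, A, Phi, Phi_prev, cfg)
  o_orc <- dictionary_objective(Y, A, X, Phi_prev, cfg)
  expect_lt(abs(o_pkg - o_orc) / (1 + abs(o_orc)), 1e-5)
  expect_true(all(Phi >= 0))
})

test_that("update never increases the objective and handles dead columns", {
  set.seed(6)
  N <- 20; Tn <- 15; M <- 4
  A <- matrix(abs(rnorm(N * M)), N, M)
  A[, 3] <- 0 # dead component
  Y <- matrix(abs(rnorm(N * Tn)), N, Tn)
  Phi_prev <- matrix(abs(rnorm(Tn * M)), Tn, M)
  cfg <- dictionary_config()
  Phi <- update_dictionary(Y, A, Phi_prev, cfg)
  expect_lte(attr(Phi, "objective"), attr(Phi, "objective_before"))
  # dead column anchored to the smoothness term
  expect_equal(Phi[, 3], (0.1 / 0.3) * Phi_prev[, 3])
  expect_error(update_dictionary(Y, A * 0, Phi_prev, cfg), "zero")
})

test_that("with gamma2 = 0 the update decouples across time rows", {
  set.seed(7)
  N <- 12; Tn <- 8; M <- 3
  A <- matrix(abs(rnorm(N * M)), N, M)
  Y <- matrix(abs(rnorm(N * Tn)), N, Tn)
  Phi_prev <- matrix(abs(rnorm(Tn * M)), Tn, M)
  cfg <- dictionary_config(gamma1 = 0.2, gamma2 = 0, gamma3 = 0.1,
                           solver_tol = 1e-14, max_sweeps = 5000)
  Phi <- update_dictionary(Y, A, Phi_prev, cfg)
  # row-wise oracle: each time row solves an independent nonneg QP
  G <- crossprod(A)
  for (t in sample(Tn, 4)) {
    Q <- 2 * (G + diag(0.2 + 0.1, M))
    f <- -2 * drop(crossprod(A, Y[, t])) - 2 * 0.1 * Phi_prev[t, ]
    row_o <- nnqp_enum_oracle(Q, f)
    expect_equal(Phi[t, ], row_o, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("projected-gradient mode descends with the step schedule", {
  set.seed(8)
  N <- 10; Tn <- 12; M <- 3
  A <- matrix(abs(rnorm(N * M)), N, M)
  Y <- matrix(abs(rnorm(N * Tn)), N, Tn)
  Phi_prev <- matrix(abs(rnorm(Tn * M)), Tn, M)
  cfg <- dictionary_config(method = "projected_gradient", gd_iters = 5)
  Phi <- update_dictionary(Y, A, Phi_prev, cfg)
  expect_lte(attr(Phi, "objective"), attr(Phi, "objective_before"))
  expect_true(all(Phi >= 0))
})
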