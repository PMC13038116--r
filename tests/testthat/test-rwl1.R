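test_that("weighted nonneg lasso solves the per-pixel objective", {
  set.seed(1)
  Tn <- 30; M <- 5
  Phi <- matrix(abs(rnorm(Tn * M)), Tn, M)
  a0 <- c(1.2, 0, 0.7, 0, 0)
  y <- drop(Phi %*% a0) + 0.01 * rnorm(Tn)
  cfg <- rwl1_config(lambda0 = 0.5, noise_var = 0.5)
  lam <- runif(M, 0.5, 2)
  a <- weighted_nonneg_lasso(y, Phi, lam, cfg)
  # oracle: exhaustive support enumeration on the equivalent QP
  qp <- lasso_to_qp(y, Phi, cfg$noise_var * cfg$lambda0 * lam, nonneg = TRUE)
  ao <- nnqp_enum_oracle(qp$H, qp$f)
  expect_lt(max(abs(a - ao)), 1e-6)
  # objective at solution no worse than at 0
  expect_lte(graftdl:::rwl1_objective(y, Phi, a, lam, cfg),
             graftdl:::rwl1_objective(y, Phi, numeric(M), lam, cfg))
  # huge penalty drives everything to zero
  big <- weighted_nonneg_lasso(y, Phi, lam, rwl1_config(lambda0 = 1e6, noise_var = 1))
  expect_true(all(big == 0))
  # orthonormal design, no penalty: closed form max(Phi'y, 0)
  Q <- qr.Q(qr(matrix(rnorm(40 * 4), 40, 4)))
  yq <- rnorm(40)
  aq <- weighted_nonneg_lasso(yq, Q, rep(1, 4),
                              rwl1_config(lambda0 = 0, noise_var = 1))
  expect_equal(drop(aq), pmax(drop(crossprod(Q, yq)), 0), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("weight update implements the graph-filtered rule", {
  set.seed(2)
  N <- 12; M <- 3
  A <- matrix(abs(rnorm(N * M)), N, M); A[A < 0.5] <- 0
  W <- Matrix::sparseMatrix(i = rep(1:N, each = 2),
                            j = as.vector(vapply(1:N, function(i)
                              sample(setdiff(1:N, i), 2), integer(2))),
                            x = 1, dims = c(N, N))
  W <- (W + Matrix::t(W)) / 2
  K <- normalize_diffusion(W)$K
  cfg <- rwl1_config(xi = 1, beta = 0.09)
  L <- update_weights(A, K, cfg)
  # dense entrywise oracle
  Kd <- as.matrix(K)
  for (i in 1:N) for (k in 1:M)
    expect_equal(L[i, k], 1 / (0.09 + A[i, k] + abs(sum(Kd[i, ] * A[, k]))))
  expect_true(all(L > 0 & L <= 1 / 0.09 + 1e-12))
  # zero coefficient with zero neighbours gives xi / beta exactly
  A0 <- matrix(0, N, M)
  expect_equal(unique(as.vector(update_weights(A0, K, cfg))), 1 / 0.09)
})

test_that("rwl1gf recovers planted supports and respects graph blocks", {
  set.seed(3)
  Tn <- 80
  tr1 <- as.numeric(stats::filter(rbinom(Tn, 1, 0.08), 0.9, "recursive"))
  tr2 <- as.numeric(stats::filter(rbinom(Tn, 1, 0.08), 0.9, "recursive"))
  Phi <- cbind(tr1 / sqrt(sum(tr1^2)), tr2 / sqrt(sum(tr2^2)))
  # two disconnected 6-pixel blocks, each expressing one component
  A_true <- rbind(matrix(c(1, 0), 6, 2, byrow = TRUE) * runif(6, .8, 1.2),
                  matrix(c(0, 1), 6, 2, byrow = TRUE) * runif(6, .8, 1.2))
  Y <- tcrossprod(A_true, Phi)
  block <- function(n) {
    W <- matrix(1, n, n) - diag(n)
    W
  }
  W <- Matrix::bdiag(block(6), block(6))
  K <- normalize_diffusion(W)$K
  maps <- rwl1gf(Y, Phi, K, rwl1_config(lambda0 = 0.1, noise_var = 0.01))
  expect_s3_class(maps, "spatial_maps")
  expect_true(all(maps$A >= 0))
  mx <- max(maps$A)
  expect_lt(max(maps$A[1:6, 2]), 1e-3 * mx)   # no cross-block support
  expect_lt(max(maps$A[7:12, 1]), 1e-3 * mx)
  expect_gt(min(maps$A[1:6, 1]), 0.5 * min(A_true[1:6, 1]))
})

test_that("one inner iteration is a plain uniform-weight LASSO", {
  set.seed(4)
  Tn <- 40; M <- 3; N <- 6
  Phi <- matrix(abs(rnorm(Tn * M)), Tn, M)
  Y <- matrix(abs(rnorm(N * Tn)), N, Tn)
  K <- Matrix::Diagonal(N)
  cfg <- rwl1_config(lambda0 = 0.3, noise_var = 0.2, inner_iters = 1)
  maps <- rwl1gf(Y, Phi, K, cfg)
  for (i in 1:N) {
    ai <- weighted_nonneg_lasso(Y[i, ], Phi, rep(1, M), cfg)
    expect_equal(maps$A[i, ], drop(ai), tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("inner reweighting does not increase the per-pixel objective", {
  # objective of iterate l evaluated at the weights that produced it
  set.seed(5)
  Tn <- 60; M <- 4; N <- 10
  Phi <- matrix(abs(rnorm(Tn * M)), Tn, M)
  A0 <- matrix(rbinom(N * M, 1, 0.4) * runif(N * M, 0.5, 1.5), N, M)
  Y <- tcrossprod(A0, Phi) + 0.05 * matrix(rnorm(N * Tn), N, Tn)
  g <- build_graph(Y, graph_config(k_neighbors = 3, k_sigma = 2))
  cfg <- rwl1_config(lambda0 = 0.5, noise_var = 0.1)
  runs <- lapply(1:3, function(iters) {
    cfg$inner_iters <- iters
    rwl1gf(Y, Phi, g$K, cfg)
  })
  # each round's solve minimizes the objective at the weights produced by the
  # previous round, so it cannot do worse there than the previous iterate
  for (l in 1:2) {
    lam_l <- runs[[l]]$weights
    for (i in 1:N) {
      f_new <- graftdl:::rwl1_objective(Y[i, ], Phi, runs[[l + 1]]$A[i, ],
                                        lam_l[i, ], cfg)
      f_old <- graftdl:::rwl1_objective(Y[i, ], Phi, runs[[l]]$A[i, ],
                                        lam_l[i, ], cfg)
      expect_lte(f_new, f_old + 1e-8 * (1 + abs(f_old)))
    }
  }
  # weight bound holds throughout
  maps <- rwl1gf(Y, Phi, g$K, cfg)
  expect_true(all(maps$weights > 0 & maps$weights <= cfg$xi / cfg$beta + 1e-12))
})

test_that("with K = I the scheme matches a standalone reweighted-l1 oracle", {
  set.seed(6)
  Tn <- 50; M <- 3; N <- 5
  Phi <- matrix(abs(rnorm(Tn * M)), Tn, M)
  Y <- matrix(abs(rnorm(N * Tn)), N, Tn)
  K <- Matrix::Diagonal(N)
  cfg <- rwl1_config(lambda0 = 0.4, noise_var = 0.3, inner_iters = 3)
  maps <- rwl1gf(Y, Phi, K, cfg)
  # oracle: classical per-pixel RWL1 with the self term counted twice
  for (i in 1:N) {
    lam <- rep(1, M)
    for (l in 1:3) {
      qp <- lasso_to_qp(Y[i, ], Phi, cfg$noise_var * cfg$lambda0 * lam,
                        nonneg = TRUE)
      a <- nnqp_enum_oracle(qp$H, qp$f)
      lam <- cfg$xi / (cfg$beta + 2 * a)
    }
    expect_equal(maps$A[i, ], a, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("the weighted nonneg LASSO agrees with glmnet as external check", {
  skip_if_not_installed("glmnet")
  set.seed(9)
  for (s in 1:3) {
    Tn <- 40; M <- 6
    Phi <- matrix(abs(rnorm(Tn * M)), Tn, M)
    y <- drop(Phi %*% (rbinom(M, 1, 0.5) * runif(M, 0.5, 1.5))) + 0.05 * rnorm(Tn)
    w <- runif(M, 0.1, 1)
    # map absolute weights onto glmnet's normalized penalty factors
    fit <- glmnet::glmnet(Phi, y, standardize = FALSE, intercept = FALSE,
                          lambda = sum(w) / (Tn * M),
                          penalty.factor = w * M / sum(w),
                          lower.limits = 0, thresh = 1e-14)
    a <- weighted_nonneg_lasso(y, Phi, w, rwl1_config(lambda0 = 1, noise_var = 1))
    expect_equal(drop(a), as.numeric(fit$beta), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})
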