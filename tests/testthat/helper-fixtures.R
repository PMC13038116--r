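# Shared fixtures and independent oracles for the test suite.

# Small random video with a planted nonnegative factorization.
make_planted_video <- function(nx = 8, ny = 8, Tn = 60, M = 3, noise = 0,
                               seed = 1) {
  set.seed(seed)
  N <- nx * ny
  A <- matrix(0, N, M)
  groups <- split(sample(N), rep(seq_len(M), length.out = N))
  for (m in seq_len(M)) # disjoint supports: the model's minimal-overlap case
    A[groups[[m]], m] <- runif(length(groups[[m]]), 0.5, 1.5)
  Phi <- matrix(0, Tn, M)
  for (m in seq_len(M)) { # sparse transient trains, mutually near-uncorrelated
    s <- rbinom(Tn, 1, 0.02)
    if (!any(s)) s[sample(Tn, 2)] <- 1
    Phi[, m] <- as.numeric(stats::filter(s, 0.8, method = "recursive"))
  }
  Y <- tcrossprod(A, Phi) + noise * matrix(rnorm(N * Tn), N, Tn)
  list(video = video_matrix(Y, fov_shape = c(nx, ny)), A = A, Phi = Phi)
}

# Exhaustive support-enumeration oracle for min .5 a'Qa + f'a s.t. a >= 0.
# Exact up to solve() precision; independent of the package's solvers.
nnqp_enum_oracle <- function(Q, f) {
  p <- length(f)
  best <- NULL; bobj <- Inf
  for (s in 0:(2^p - 1)) {
    S <- which(bitwAnd(s, 2^(0:(p - 1))) > 0)
    a <- numeric(p)
    if (length(S)) {
      z <- tryCatch(solve(Q[S, S, drop = FALSE], -f[S]),
                    error = function(e) NULL)
      if (is.null(z) || any(z < -1e-12)) next
      a[S] <- pmax(z, 0)
    }
    if (any(Q %*% a + f < -1e-8)) next # KKT: gradient nonneg off-support
    obj <- 0.5 * sum(a * (Q %*% a)) + sum(f * a)
    if (obj < bobj) { bobj <- obj; best <- a }
  }
  best
}

# Generic convex oracle for inequality QPs: ADMM splitting on the slack
# (independent algorithm family from both package solvers), polished by an
# exact KKT solve on the detected active set.
qp_admm_oracle <- function(qp, rho = 1, iters = 20000) {
  H <- qp$H; f <- qp$f; C <- qp$C; b <- qp$b
  n <- length(f)
  M <- H + rho * crossprod(C)
  ch <- chol(M)
  x <- numeric(n); z <- numeric(length(b)); u <- numeric(length(b))
  for (it in seq_len(iters)) {
    x <- backsolve(ch, forwardsolve(t(ch), -f + rho * drop(crossprod(C, z - u))))
    Cx <- drop(C %*% x)
    z <- pmin(Cx + u, b)
    u <- u + Cx - z
  }
  fn <- function(x) 0.5 * sum(x * (H %*% x)) + sum(f * x)
  act <- which(b - drop(C %*% x) < 1e-6 * (1 + max(abs(b))))
  if (length(act)) { # polish: equality KKT on the active set
    Ca <- C[act, , drop = FALSE]
    K <- rbind(cbind(H, t(Ca)),
               cbind(Ca, matrix(0, length(act), length(act))))
    sol <- tryCatch(solve(K, c(-f, b[act])), error = function(e) NULL)
    if (!is.null(sol)) {
      xp <- sol[seq_len(n)]
      if (all(b - drop(C %*% xp) > -1e-9) && fn(xp) <= fn(x) + 1e-10)
        x <- xp
    }
  }
  x
}

# Random feasible dense QP with 0 strictly interior.
make_random_qp <- function(n = 6, m = 10, seed = 1) {
  set.seed(seed)
  Aq <- matrix(rnorm(n * n), n)
  H <- crossprod(Aq) + 0.1 * diag(n)
  f <- rnorm(n)
  C <- matrix(rnorm(m * n), m, n)
  b <- runif(m, 0.2, 1.5)
  structure(list(H = H, f = f, C = C, b = b, variable_split = NULL),
            class = "qp_problem")
}

# Cached default-scale study runs shared across acceptance tests (computed
# lazily, once per test session).
study_cache <- new.env(parent = emptyenv())

study_runs <- function(ratios = c(1, 4, 16, 64, 512), seed = 7) {
  key <- paste0("runs_", seed)
  if (!is.null(study_cache[[key]])) {
    have <- names(study_cache[[key]])
    need <- setdiff(as.character(ratios), have)
    if (!length(need)) return(study_cache[[key]][as.character(ratios)])
  }
  gen <- study_video(seed)
  runs <- study_cache[[key]] %||% list()
  for (r in as.character(setdiff(as.character(ratios), names(runs)))) {
    ratio <- as.numeric(r)
    cfg <- graft_config(rng_seed = seed,
                        sketch = if (ratio > 1) list(ratio = ratio, normalized = FALSE))
    runs[[r]] <- run_graft(gen$video, cfg)
  }
  study_cache[[key]] <- runs
  runs[as.character(ratios)]
}

study_video <- function(seed = 7) {
  key <- paste0("video_", seed)
  if (is.null(study_cache[[key]]))
    study_cache[[key]] <- generate_video(synthetic_spec(seed = seed))
  study_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
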