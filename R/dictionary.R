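#' Settings for the temporal dictionary update
#'
#' The dictionary solves
#' \deqn{\Phi = \arg\min_{\Phi \ge 0} \|Y - A\Phi^T\|_F^2 + \gamma_1\|\Phi\|_F^2
#'   + \gamma_2 \mathrm{SAV}(\Phi) + \gamma_3 \|\Phi - \Phi^{prev}\|_F^2}
#' where SAV is the sum of off-diagonal Gram entries (see [sav_offdiag()]).
#'
#' @param gamma1 Frobenius magnitude penalty (default 0.2).
#' @param gamma2 trace-decorrelation (SAV) penalty (default 0.1).
#' @param gamma3 iterate-smoothness penalty (default 0.1).
#' @param nonneg constrain the traces to be nonnegative (default TRUE; turned
#'   off for sketched dictionaries, whose entries are sign-indefinite).
#' @param solver_tol relative objective change at which the block-coordinate
#'   sweeps stop (default 1e-8).
#' @param max_sweeps cap on coordinate sweeps (default 200).
#' @param method `"bcd"` (cyclic column block coordinate descent with exact
#'   nonnegative column solves; monotone, the default) or
#'   `"projected_gradient"` (step-size schedule semantics `step_s`,
#'   `step_decay`, `gd_iters`).
#' @param step_s,step_decay,gd_iters projected-gradient schedule (defaults 1,
#'   0.995, 1).
#' @return A `dictionary_config` list.
#' @export
dictionary_config <- function(gamma1 = 0.2, gamma2 = 0.1, gamma3 = 0.1,
                              nonneg = TRUE, solver_tol = 1e-8,
                              max_sweeps = 200,
                              method = c("bcd", "projected_gradient"),
                              step_s = 1, step_decay = 0.995, gd_iters = 1) {
  method <- match.arg(method)
  stopifnot(gamma1 >= 0, gamma2 >= 0, gamma3 >= 0, solver_tol > 0)
  structure(list(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
                 nonneg = nonneg, solver_tol = solver_tol,
                 max_sweeps = as.integer(max_sweeps), method = method,
                 step_s = step_s, step_decay = step_decay,
                 gd_iters = as.integer(gd_iters)),
            class = "dictionary_config")
}

#' Sum of off-diagonal Gram entries of the dictionary
#'
#' `sum_{i != k} Phi_i' Phi_k`, the sum-absolute-value (SAV) norm of the
#' off-diagonal Gram matrix for nonnegative traces; penalizing it discourages
#' redundant (correlated) dictionary traces.
#'
#' @param Phi `T x M` dictionary matrix.
#' @return Scalar.
#' @export
sav_offdiag <- function(Phi) {
  G <- crossprod(as.matrix(Phi))
  sum(G) - sum(diag(G))
}

#' Evaluate the dictionary objective
#'
#' Data fidelity is evaluated in the pixels-by-time orientation,
#' `||Y - A Phi'||_F^2`.
#'
#' @param Y `N x T` data matrix (full or sketched; T must match `Phi`).
#' @param A `N x M` spatial coefficients (or a `spatial_maps`).
#' @param Phi `T x M` candidate dictionary.
#' @param Phi_prev `T x M` previous iterate (for the smoothness term).
#' @param cfg a [dictionary_config()].
#' @return Scalar objective value.
#' @export
dictionary_objective <- function(Y, A, Phi, Phi_prev, cfg = dictionary_config()) {
  if (inherits(A, "spatial_maps")) A <- A$A
  Y <- if (inherits(Y, "video_matrix")) Y$data else as.matrix(Y)
  if (ncol(Y) != nrow(Phi) || nrow(Y) != nrow(A) || ncol(A) != ncol(Phi))
    stop("dimension mismatch in dictionary objective")
  sum((Y - tcrossprod(A, Phi))^2) + cfg$gamma1 * sum(Phi^2) +
    cfg$gamma2 * sav_offdiag(Phi) + cfg$gamma3 * sum((Phi - Phi_prev)^2)
}

# Fast objective from precomputed pieces: ||Y - A Phi'||_F^2 =
# ||Y||^2 - 2 <B, Phi> + <G, Phi'Phi> with B = Y'A, G = A'A.
dict_obj_fast <- function(ynorm2, B, G, Phi, Phi_prev, cfg) {
  PtP <- crossprod(Phi)
  ynorm2 - 2 * sum(B * Phi) + sum(G * PtP) + cfg$gamma1 * sum(diag(PtP)) +
    cfg$gamma2 * (sum(PtP) - sum(diag(PtP))) + cfg$gamma3 * sum((Phi - Phi_prev)^2)
}

#' Update the temporal dictionary
#'
#' Minimizes the four-term objective over `Phi` (nonnegative if configured).
#' The default solver is cyclic column block coordinate descent: for each
#' column the subproblem is a strictly convex quadratic with a diagonal
#' Hessian, so the exact (projected) column minimizer is available in closed
#' form and every sweep decreases the objective. Columns whose spatial
#' coefficients are all zero are anchored to the smoothness term
#' (`gamma3 / (gamma1 + gamma3) * Phi_prev`). If a step fails to decrease the
#' objective (only possible under `projected_gradient`), the previous iterate
#' is returned with a warning.
#'
#' @inheritParams dictionary_objective
#' @param A `N x M` spatial coefficients from [rwl1gf()]; at least one column
#'   must be nonzero.
#' @return `T x M` dictionary matrix with attribute `"objective"` (value at
#'   return) and `"sweeps"`.
#' @export
update_dictionary <- function(Y, A, Phi_prev, cfg = dictionary_config()) {
  if (inherits(A, "spatial_maps")) A <- A$A
  Y <- if (inherits(Y, "video_matrix")) Y$data else as.matrix(Y)
  A <- as.matrix(A); Phi_prev <- as.matrix(Phi_prev)
  M <- ncol(A)
  if (ncol(Y) != nrow(Phi_prev) || nrow(Y) != nrow(A) || ncol(Phi_prev) != M)
    stop("dimension mismatch in dictionary update")
  colA2 <- colSums(A^2)
  if (all(colA2 == 0)) stop("all spatial coefficient columns are zero")
  G <- crossprod(A)                 # M x M
  B <- crossprod(Y, A)              # T x M
  ynorm2 <- sum(Y^2)
  obj0 <- dict_obj_fast(ynorm2, B, G, Phi_prev, Phi_prev, cfg)
  if (cfg$method == "projected_gradient") {
    Phi <- update_dictionary_pg(B, G, Phi_prev, cfg)
  } else {
    Phi <- update_dictionary_bcd(B, G, colA2, Phi_prev, cfg,
                                 ynorm2 = ynorm2)
  }
  obj1 <- dict_obj_fast(ynorm2, B, G, Phi, Phi_prev, cfg)
  if (obj1 > obj0 + 1e-10 * (1 + abs(obj0))) {
    warning("dictionary update did not decrease the objective; keeping previous iterate")
    Phi <- Phi_prev
    obj1 <- obj0
  }
  structure(Phi, objective = obj1, objective_before = obj0,
            sweeps = attr(Phi, "sweeps"))
}

# Cyclic column BCD with exact (projected) column solves.
update_dictionary_bcd <- function(B, G, colA2, Phi_prev, cfg, ynorm2 = 0) {
  M <- ncol(B); Tn <- nrow(B)
  Phi <- Phi_prev
  denom <- colA2 + cfg$gamma1 + cfg$gamma3
  obj <- dict_obj_fast(ynorm2, B, G, Phi, Phi_prev, cfg)
  sweeps <- 0L
  dead <- which(colA2 == 0)
  repeat {
    sweeps <- sweeps + 1L
    for (m in seq_len(M)) {
      if (colA2[m] == 0) {
        # smoothness-anchored value for dead components
        anchor <- if (cfg$gamma1 + cfg$gamma3 > 0)
          cfg$gamma3 / (cfg$gamma1 + cfg$gamma3) else 0
        phi <- anchor * Phi_prev[, m]
        if (cfg$nonneg) phi <- pmax(phi, 0)
        Phi[, m] <- phi
        next
      }
      # residual correlation: B[,m] - Phi G[,m] + phi_m G[m,m]
      r <- B[, m] - Phi %*% G[, m] + Phi[, m] * G[m, m]
      s_other <- rowSums(Phi) - Phi[, m]
      phi <- (r + cfg$gamma3 * Phi_prev[, m] - cfg$gamma2 * s_other) / denom[m]
      if (cfg$nonneg) phi <- pmax(phi, 0)
      Phi[, m] <- phi
    }
    obj_new <- dict_obj_fast(ynorm2, B, G, Phi, Phi_prev, cfg)
    if (abs(obj - obj_new) <= cfg$solver_tol * (1 + abs(obj)) ||
        sweeps >= cfg$max_sweeps) break
    obj <- obj_new
  }
  attr(Phi, "sweeps") <- sweeps
  Phi
}

# Projected gradient with the step/decay schedule exposed by the pipeline
# configuration ("step s", "step decay", "GD iters").
update_dictionary_pg <- function(B, G, Phi_prev, cfg) {
  Phi <- Phi_prev
  M <- ncol(B)
  lip <- 2 * (norm(G, "2") + cfg$gamma1 + cfg$gamma3 + cfg$gamma2 * (M - 1))
  step <- cfg$step_s / lip
  ones_off <- matrix(1, M, M) - diag(M)
  for (it in seq_len(max(cfg$gd_iters, 1))) {
    grad <- 2 * (Phi %*% G - B) + 2 * cfg$gamma1 * Phi +
      2 * cfg$gamma2 * (Phi %*% ones_off) + 2 * cfg$gamma3 * (Phi - Phi_prev)
    Phi <- Phi - step * grad
    if (cfg$nonneg) Phi[Phi < 0] <- 0
    step <- step * cfg$step_decay
  }
  attr(Phi, "sweeps") <- cfg$gd_iters
  Phi
}
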