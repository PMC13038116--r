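#' Solver settings for the LASSO quadratic programs
#'
#' @param method `"interior_point"`, `"active_set"`, or `"auto"` (choose by
#'   problem size via [select_solver()]).
#' @param mu0 initial barrier parameter (interior point).
#' @param mu_decay multiplicative barrier decrease per outer stage, in (0,1).
#' @param tol convergence tolerance on the KKT residual / duality measure.
#' @param max_iter iteration cap (outer Newton iterations or active-set steps).
#' @param warm_start optional list with `x` (start point) and/or `active_set`
#'   (integer constraint indices) from a previous related solve.
#' @param size_threshold [select_solver()] threshold on the coefficient count.
#' @return A `solver_config` list.
#' @export
solver_config <- function(method = c("auto", "active_set", "interior_point"),
                          mu0 = 1, mu_decay = 0.1, tol = 1e-8, max_iter = 500,
                          warm_start = NULL, size_threshold = 64) {
  method <- match.arg(method)
  stopifnot(tol > 0, mu_decay > 0, mu_decay < 1, mu0 > 0)
  structure(list(method = method, mu0 = mu0, mu_decay = mu_decay, tol = tol,
                 max_iter = as.integer(max_iter), warm_start = warm_start,
                 size_threshold = size_threshold),
            class = "solver_config")
}

#' Reformulate a (weighted, optionally nonnegative) LASSO as a QP
#'
#' The weighted LASSO `min_a 1/2 ||y - Phi a||^2 + sum_j lambda_j |a_j|` becomes
#' a smooth quadratic program with linear inequality constraints. In the
#' general case auxiliary variables `u >= |a|` are introduced, giving variables
#' `x = (a, u)` in `R^{2p}` with `H = blockdiag(Phi'Phi, 0)`,
#' `f = (-Phi'y, lambda)` and constraints stacked as rows
#' `a - u <= 0`, `-a - u <= 0`, `-u <= 0` (in that order). With `nonneg = TRUE`
#' the `l1` term is linear (`|a| = a`), so the reduced p-variable form
#' `H = Phi'Phi`, `f = -Phi'y + lambda`, `-a <= 0` is used.
#'
#' @param y response vector (a pixel time trace), length n.
#' @param Phi `n x p` predictor matrix (the temporal dictionary).
#' @param lambda_vec nonnegative per-coefficient l1 weights, length p (a scalar
#'   is recycled).
#' @param nonneg constrain `a >= 0` and use the reduced form?
#' @return A `qp_problem` list: `H`, `f`, `C`, `b`, `variable_split` (with
#'   `form`, `p`, and index vectors `a_idx`, `u_idx`).
#' @export
lasso_to_qp <- function(y, Phi, lambda_vec, nonneg = FALSE) {
  Phi <- as.matrix(Phi)
  p <- ncol(Phi)
  if (length(lambda_vec) == 1) lambda_vec <- rep(lambda_vec, p)
  if (length(lambda_vec) != p) stop("lambda_vec length must equal ncol(Phi)")
  if (any(lambda_vec < 0)) stop("negative l1 weights")
  if (length(y) != nrow(Phi)) stop("length(y) must equal nrow(Phi)")
  G <- crossprod(Phi)
  q <- drop(crossprod(Phi, y))
  if (nonneg) {
    qp <- list(H = G, f = -q + lambda_vec,
               C = -diag(p), b = rep(0, p),
               variable_split = list(form = "nonneg", p = p,
                                     a_idx = seq_len(p), u_idx = integer(0)))
  } else {
    H <- matrix(0, 2 * p, 2 * p)
    H[seq_len(p), seq_len(p)] <- G
    f <- c(-q, lambda_vec)
    Ip <- diag(p); Z <- matrix(0, p, p)
    C <- rbind(cbind(Ip, -Ip),    # a - u <= 0
               cbind(-Ip, -Ip),   # -a - u <= 0
               cbind(Z, -Ip))     # -u <= 0
    qp <- list(H = H, f = f, C = C, b = rep(0, 3 * p),
               variable_split = list(form = "general", p = p,
                                     a_idx = seq_len(p),
                                     u_idx = p + seq_len(p)))
  }
  structure(qp, class = "qp_problem")
}

# Strictly feasible start for a qp_problem, honoring an optional warm start.
feasible_start <- function(qp, warm = NULL, strict = FALSE) {
  n <- length(qp$f)
  slack_ok <- function(x) {
    s <- qp$b - drop(qp$C %*% x)
    if (strict) all(s > 1e-10) else all(s >= -1e-10)
  }
  if (!is.null(warm$x) && length(warm$x) == n && slack_ok(warm$x)) return(warm$x)
  vs <- qp$variable_split
  if (!is.null(vs) && identical(vs$form, "general")) {
    x <- numeric(n); x[vs$u_idx] <- 1
    if (slack_ok(x)) return(x)
  }
  if (!is.null(vs) && identical(vs$form, "nonneg")) {
    x <- rep(if (strict) 1 else 0, n)
    if (slack_ok(x)) return(x)
  }
  x <- numeric(n)
  if (slack_ok(x)) return(x)
  stop("no feasible start available; supply one via warm_start$x")
}

qp_objective <- function(qp, x) drop(0.5 * crossprod(x, qp$H %*% x) + sum(qp$f * x))

# Stationarity residual ||Hx + f + C'nu||_inf given duals nu >= 0.
kkt_residual <- function(qp, x, nu) {
  max(abs(drop(qp$H %*% x) + qp$f + drop(crossprod(qp$C, nu))))
}

#' Solve a QP by a log-barrier interior-point method
#'
#' Minimizes `1/2 x'Hx + f'x` subject to `Cx <= b` by damped Newton steps on
#' the barrier objective `1/2 x'Hx + f'x - mu * sum_i log(b_i - (Cx)_i)`, with
#' `mu` decreased geometrically (`mu <- mu * mu_decay`) until `m * mu < tol`.
#'
#' @param qp a `qp_problem` (from [lasso_to_qp()] or hand-built).
#' @param cfg a [solver_config()].
#' @return List with `x` (solution), `nu` (dual estimates `mu / slack`), and
#'   `diagnostics` (`iterations`, `final_mu`, `converged`, `kkt_residual`,
#'   `objective`).
#' @export
solve_qp_barrier <- function(qp, cfg = solver_config()) {
  H <- qp$H; f <- qp$f; C <- qp$C; b <- qp$b
  m <- length(b); n <- length(f)
  x <- feasible_start(qp, cfg$warm_start, strict = TRUE)
  mu <- cfg$mu0
  iters <- 0L
  barrier_val <- function(x, s) qp_objective(qp, x) - mu * sum(log(s))
  obj_trace <- numeric(0)
  repeat {
    # Newton iterations at fixed mu
    for (it in seq_len(50)) {
      s <- b - drop(C %*% x)
      g <- drop(H %*% x) + f + mu * drop(crossprod(C, 1 / s))
      Hb <- H + mu * crossprod(C / s)
      dx <- tryCatch(solve(Hb, -g),
                     error = function(e) solve(Hb + diag(1e-10 * max(diag(Hb)), n), -g))
      dec <- -sum(g * dx)
      iters <- iters + 1L
      if (dec / 2 < max(cfg$tol^2, 1e-24) * (1 + abs(qp_objective(qp, x)))) break
      # backtracking line search keeping strict feasibility
      alpha <- 1
      f0 <- barrier_val(x, s)
      repeat {
        xn <- x + alpha * dx
        sn <- b - drop(C %*% xn)
        if (all(sn > 0) && barrier_val(xn, sn) <= f0 - 1e-4 * alpha * dec) break
        alpha <- alpha / 2
        if (alpha < 1e-14) break
      }
      if (alpha < 1e-14) break
      x <- x + alpha * dx
      if (iters >= cfg$max_iter) break
    }
    obj_trace <- c(obj_trace, qp_objective(qp, x))
    if (m * mu < cfg$tol || iters >= cfg$max_iter) break
    mu <- mu * cfg$mu_decay
  }
  s <- b - drop(C %*% x)
  nu <- mu / s
  # refine duals: least-squares multipliers on the near-active set
  act <- which(s < sqrt(.Machine$double.eps) * max(1, max(abs(b)), max(abs(x))) |
                 nu > sqrt(cfg$tol))
  if (length(act)) {
    nu_act <- tryCatch(
      qr.solve(t(C[act, , drop = FALSE]), -(drop(H %*% x) + f)),
      error = function(e) NULL)
    if (!is.null(nu_act) && all(nu_act > -sqrt(cfg$tol))) {
      nu <- numeric(m)
      nu[act] <- pmax(nu_act, 0)
    }
  }
  res <- kkt_residual(qp, x, nu)
  list(x = x, nu = nu,
       diagnostics = list(iterations = iters, final_mu = mu,
                          converged = iters < cfg$max_iter && m * mu < cfg$tol,
                          kkt_residual = res, objective = qp_objective(qp, x),
                          objective_trace = obj_trace))
}

#' Solve a QP by a primal active-set method
#'
#' Iterates on a working set of binding constraints: at each step an
#' equality-constrained QP is solved on the working set; either the step is
#' blocked by a new constraint (added) or a negative multiplier releases one
#' (dropped). Warm-startable via `cfg$warm_start$active_set` and `$x`.
#' Nonnegativity-only problems (`variable_split$form == "nonneg"`) are routed
#' to a compiled Lawson-Hanson-type kernel operating on the Gram system, which
#' is the same algorithm specialized to bound constraints.
#'
#' @inheritParams solve_qp_barrier
#' @return List with `x`, `active_set` (integer indices of binding constraint
#'   rows, usable as a warm start), `nu` (duals, supported on the active set),
#'   and `diagnostics`.
#' @export
solve_qp_active_set <- function(qp, cfg = solver_config()) {
  vs <- qp$variable_split
  if (!is.null(vs) && identical(vs$form, "nonneg")) {
    p <- length(qp$f)
    x0 <- cfg$warm_start$x %||% numeric(p)
    if (length(x0) != p || any(x0 < 0)) x0 <- numeric(p)
    fit <- nnqp_solve_cpp(qp$H, qp$f, x0, as.integer(cfg$max_iter), cfg$tol)
    x <- drop(fit$x)
    act <- which(x <= 0)
    nu <- numeric(p)
    nu[act] <- pmax(0, (drop(qp$H %*% x) + qp$f)[act])
    return(list(x = x, active_set = act, nu = nu,
                diagnostics = list(iterations = fit$iterations,
                                   converged = fit$converged == 1,
                                   kkt_residual = kkt_residual(qp, x, nu),
                                   objective = qp_objective(qp, x))))
  }
  solve_qp_active_set_general(qp, cfg)
}

# Primal active-set iteration for a general inequality QP.
solve_qp_active_set_general <- function(qp, cfg) {
  H <- qp$H; f <- qp$f; C <- qp$C; b <- qp$b
  m <- length(b); n <- length(f)
  scl <- max(abs(H), abs(f), 1)
  x <- feasible_start(qp, cfg$warm_start, strict = FALSE)
  wset <- cfg$warm_start$active_set %||% which(b - drop(C %*% x) < 1e-10)
  wset <- sort(unique(as.integer(wset)))
  wset <- wset[b[wset] - drop(C[wset, , drop = FALSE] %*% x) < 1e-8]
  ridge <- 0
  zero_steps <- 0L; bland <- FALSE
  iters <- 0L; converged <- FALSE
  nu_full <- numeric(m)
  while (iters < cfg$max_iter) {
    iters <- iters + 1L
    g <- drop(H %*% x) + f
    nw <- length(wset)
    Cw <- C[wset, , drop = FALSE]
    KKT <- rbind(cbind(H + diag(ridge, n), t(Cw)),
                 cbind(Cw, matrix(0, nw, nw)))
    rhs <- c(-g, rep(0, nw))
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      ridge <- max(ridge * 10, 1e-10 * scl)
      next
    }
    pstep <- sol[seq_len(n)]
    nu <- if (nw) sol[n + seq_len(nw)] else numeric(0)
    if (max(abs(pstep)) < 1e-10 * (1 + max(abs(x)))) {
      neg <- which(nu < -cfg$tol)
      if (!length(neg)) {
        nu_full <- numeric(m); nu_full[wset] <- pmax(nu, 0)
        converged <- TRUE
        break
      }
      drop_i <- if (bland) min(neg) else neg[which.min(nu[neg])]
      wset <- wset[-drop_i]
      zero_steps <- zero_steps + 1L
    } else {
      Cp <- drop(C %*% pstep)
      cand <- setdiff(which(Cp > 1e-12 * scl), wset)
      alpha <- 1; blocking <- NA
      if (length(cand)) {
        ratios <- (b[cand] - drop(C[cand, , drop = FALSE] %*% x)) / Cp[cand]
        jmin <- which.min(ratios)
        if (ratios[jmin] < 1) {
          alpha <- max(ratios[jmin], 0)
          blocking <- cand[if (bland) min(which(ratios <= alpha + 1e-14)) else jmin]
        }
      }
      x <- x + alpha * pstep
      if (!is.na(blocking)) wset <- sort(c(wset, blocking))
      zero_steps <- if (alpha <= 1e-14) zero_steps + 1L else 0L
    }
    if (!bland && zero_steps > 2L * m) {
      warning("active-set cycling suspected; switching to Bland-style selection")
      bland <- TRUE
      zero_steps <- 0L
    }
  }
  list(x = x, active_set = wset, nu = nu_full,
       diagnostics = list(iterations = iters, converged = converged,
                          kkt_residual = kkt_residual(qp, x, nu_full),
                          objective = qp_objective(qp, x)))
}

#' Choose between the active-set and interior-point solvers
#'
#' Active-set methods win on small, warm-startable problems; interior-point
#' methods scale better with many variables and constraints. The rule is a
#' pure function of the inputs: `active_set` when warm starts are available
#' (`repeated = TRUE`) or when `p < threshold` (strict; `p = threshold` gives
#' `interior_point`).
#'
#' @param p number of coefficients in the LASSO subproblem.
#' @param m number of constraints.
#' @param repeated will the problem be re-solved with slowly-changing data
#'   (enabling warm starts)?
#' @param threshold coefficient-count cutoff (default 64, i.e. 128 QP
#'   variables in the general reformulation).
#' @return `"active_set"` or `"interior_point"`.
#' @export
select_solver <- function(p, m = 3 * p, repeated = FALSE, threshold = 64) {
  if (repeated || p < threshold) "active_set" else "interior_point"
}

#' Solve a qp_problem with the configured method
#'
#' Dispatches on `cfg$method`, resolving `"auto"` through [select_solver()].
#'
#' @inheritParams solve_qp_barrier
#' @param repeated passed to [select_solver()] under `"auto"`.
#' @return As [solve_qp_barrier()] / [solve_qp_active_set()].
#' @export
solve_qp <- function(qp, cfg = solver_config(), repeated = FALSE) {
  method <- cfg$method
  if (method == "auto") {
    p <- qp$variable_split$p %||% length(qp$f)
    method <- select_solver(p, length(qp$b), repeated, cfg$size_threshold)
  }
  if (method == "active_set") solve_qp_active_set(qp, cfg) else solve_qp_barrier(qp, cfg)
}
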