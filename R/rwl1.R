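#' Settings for re-weighted l1 graph filtering
#'
#' Parameters of the per-pixel sparse-coding objective
#' \deqn{\hat a_i = \arg\min_{a \ge 0} \frac{1}{2\sigma_y^2}\|y_i - \Phi a\|_2^2
#'   + \lambda_0 \sum_k \lambda_{ik} a_k}
#' and of the graph-filtered weight update
#' \deqn{\lambda_{ik} = \xi / (\beta + a_{ik} + [K a_k]_i).}
#'
#' @param lambda0 global sparsity scale (default 0.7).
#' @param xi weight-update numerator (default 1; its scale is absorbed by
#'   `lambda0`).
#' @param beta weight-update denominator offset (default 0.09); bounds the
#'   weights at `xi / beta`.
#' @param noise_var Gaussian noise variance `sigma_y^2` weighting the data
#'   term. Default 1: the penalty `lambda0` is then applied against the
#'   unscaled residual, which is the scale at which the reference parameter
#'   set (`lambda0 = 0.7`) is meaningful. Set it to [estimate_noise_var()]
#'   output to weight the fit by the inverse noise variance instead.
#' @param inner_iters reweighting rounds per outer iteration (default 3).
#' @param solver a [solver_config()] for the per-pixel QPs.
#' @return An `rwl1_config` list.
#' @export
rwl1_config <- function(lambda0 = 0.7, xi = 1, beta = 0.09, noise_var = 1,
                        inner_iters = 3, solver = solver_config()) {
  stopifnot(lambda0 >= 0, xi > 0, beta > 0, inner_iters >= 1)
  structure(list(lambda0 = lambda0, xi = xi, beta = beta,
                 noise_var = noise_var, inner_iters = as.integer(inner_iters),
                 solver = solver),
            class = "rwl1_config")
}

#' Robust per-pixel noise variance estimate
#'
#' Pools the median absolute deviation of first differences across pixels:
#' for white Gaussian noise, `sd(diff(y)) = sigma * sqrt(2)`, and the MAD is
#' insensitive to the (sparse) calcium transients riding on the noise.
#'
#' @param video a [video_matrix()] or `N x T` matrix.
#' @return Scalar variance estimate.
#' @export
estimate_noise_var <- function(video) {
  Y <- if (inherits(video, "video_matrix")) video$data else as.matrix(video)
  d <- Y[, -1, drop = FALSE] - Y[, -ncol(Y), drop = FALSE]
  sig <- median(abs(d)) * 1.4826 / sqrt(2)
  max(sig^2, 1e-12)
}

#' Weighted nonnegative LASSO for one pixel
#'
#' Solves the per-pixel objective above through the QP module
#' ([lasso_to_qp()] in the reduced nonnegative form, then [solve_qp()]).
#'
#' @param y length-T trace.
#' @param Phi `T x M` dictionary.
#' @param lambda_row length-M positive weights `lambda_{ik}`.
#' @param cfg an [rwl1_config()]; `cfg$noise_var` must be set (scalar).
#' @return Nonnegative coefficient vector of length M, with the solver
#'   diagnostics in attribute `"diagnostics"`.
#' @export
weighted_nonneg_lasso <- function(y, Phi, lambda_row, cfg = rwl1_config()) {
  if (is.null(cfg$noise_var)) cfg$noise_var <- 1
  if (length(lambda_row) != ncol(Phi)) stop("weight length must equal ncol(Phi)")
  # minimizing Eq over a >= 0 is equivalent to a plain weighted nonneg LASSO
  # with l1 weights sigma_y^2 * lambda0 * lambda_row
  qp <- lasso_to_qp(y, Phi, cfg$noise_var * cfg$lambda0 * lambda_row, nonneg = TRUE)
  fit <- solve_qp(qp, cfg$solver, repeated = TRUE)
  structure(fit$x, diagnostics = fit$diagnostics)
}

#' Graph-filtered LASSO weight update
#'
#' `lambda_ik = xi / (beta + a_ik + [K a_k]_i)`: a component strongly expressed
#' at pixel i's graph neighbours gets a low weight there (encouraged), an
#' unsupported component a high one (suppressed). With nonnegative `A` the
#' modulus in the graph term is inert. Weights always lie in `(0, xi/beta]`.
#'
#' @param A `N x M` nonnegative coefficient matrix.
#' @param K row-stochastic diffusion operator (sparse `N x N`).
#' @param cfg an [rwl1_config()].
#' @return `N x M` matrix of positive weights.
#' @export
update_weights <- function(A, K, cfg = rwl1_config()) {
  KA <- as.matrix(K %*% A)
  cfg$xi / (cfg$beta + A + abs(KA))
}

#' Re-weighted l1 graph filtering over all pixels
#'
#' For every pixel, weights start at 1 and `inner_iters` rounds alternate the
#' weighted nonnegative LASSO with the graph-filtered weight update. Rounds
#' are synchronous: all pixels solve, then all weights update, so the result
#' is independent of pixel order. Per-pixel solves share the dictionary Gram
#' matrix and warm-start from the previous round's support.
#'
#' @param video a [video_matrix()] (possibly sketched) or `N x T` matrix.
#' @param Phi `T x M` dictionary (same T as `video`).
#' @param K sparse row-stochastic `N x N` diffusion operator.
#' @param cfg an [rwl1_config()].
#' @return A `spatial_maps` object: list with `A` (`N x M` nonnegative
#'   matrix), `weights` (`N x M`), and `failed_pixels` (indices whose QP hit
#'   the iteration cap, empty in normal operation).
#' @export
rwl1gf <- function(video, Phi, K, cfg = rwl1_config()) {
  Y <- if (inherits(video, "video_matrix")) video$data else as.matrix(video)
  Phi <- as.matrix(Phi)
  if (ncol(Y) != nrow(Phi)) stop("video frame count must match nrow(Phi)")
  if (nrow(Y) != nrow(K)) stop("graph size must match pixel count")
  nv <- cfg$noise_var %||% 1
  M <- ncol(Phi); N <- nrow(Y)
  Q <- crossprod(Phi) / nv
  Qlin <- crossprod(Phi, t(Y)) / nv # M x N
  Lambda <- matrix(1, N, M)
  A <- matrix(0, M, N) # transposed orientation for the batch kernel
  failed <- integer(0)
  for (l in seq_len(cfg$inner_iters)) {
    Pen <- cfg$lambda0 * t(Lambda)
    fit <- nnlasso_batch_cpp(Q, Qlin, Pen, A,
                             max_iter = cfg$solver$max_iter,
                             tol = cfg$solver$tol)
    A <- fit$A
    failed <- union(failed, fit$failed)
    Lambda <- update_weights(t(A), K, cfg)
  }
  structure(list(A = t(A), weights = Lambda, failed_pixels = sort(failed)),
            class = "spatial_maps")
}

#' @export
print.spatial_maps <- function(x, ...) {
  cat("<spatial_maps> ", nrow(x$A), " pixels x ", ncol(x$A), " components; ",
      round(100 * mean(x$A > 0), 1), "% nonzero\n", sep = "")
  invisible(x)
}

# Eq-3 objective for one pixel, at given weights (used by tests/diagnostics).
rwl1_objective <- function(y, Phi, a, lambda_row, cfg) {
  nv <- cfg$noise_var
  drop(sum((y - Phi %*% a)^2) / (2 * nv) + cfg$lambda0 * sum(lambda_row * abs(a)))
}
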