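#' Build a temporal random-projection (sketch) operator
#'
#' A `T~ x T` matrix `Psi` with i.i.d. Gaussian entries of variance `1/T~`
#' (so `E||Psi x||^2 = ||x||^2`, i.e. scaling `alpha ~ 1`). In normalized mode
#' each row is additionally rescaled to unit l2 norm, which shrinks sketched
#' trace energy by about `T~/T` and so changes the effective sparsity penalty.
#' `ratio = 1` returns an exact identity passthrough (used for equivalence
#' checks between compressed and uncompressed pipelines).
#'
#' @param T_full number of frames T.
#' @param ratio compression level `T / T~` (>= 1).
#' @param normalized rescale rows to unit norm?
#' @param seed RNG seed; the operator is deterministic given the seed.
#' @return A `sketch_operator`: list with `Psi`, `T_full`, `T_sketch`,
#'   `ratio`, `normalized`, `seed`, `alpha` (expected scaling: 1 when
#'   non-normalized, `T~/T` when normalized), `identity` flag and `id` (a
#'   fingerprint used to guard operator mismatches).
#' @export
make_sketch <- function(T_full, ratio = 1, normalized = FALSE, seed = 1) {
  stopifnot(ratio >= 1)
  t_sk <- as.integer(round(T_full / ratio))
  if (t_sk < 1) stop("compression ratio leaves no frames (T~ < 1)")
  ident <- ratio == 1
  if (ident) {
    Psi <- diag(T_full)
  } else {
    set.seed(as.integer(seed))
    Psi <- matrix(rnorm(t_sk * T_full, sd = 1 / sqrt(t_sk)), t_sk, T_full)
    if (normalized) Psi <- Psi / sqrt(rowSums(Psi^2))
  }
  structure(list(Psi = Psi, T_full = as.integer(T_full), T_sketch = t_sk,
                 ratio = ratio, normalized = normalized,
                 seed = as.integer(seed),
                 alpha = if (normalized && !ident) t_sk / T_full else 1,
                 identity = ident,
                 id = paste(T_full, t_sk, normalized, seed, ident, sep = ":")),
            class = "sketch_operator")
}

#' @export
print.sketch_operator <- function(x, ...) {
  cat("<sketch_operator> ", x$T_sketch, " x ", x$T_full, " (", x$ratio, "x",
      if (x$normalized) ", normalized" else "",
      if (x$identity) ", identity" else "", ")\n", sep = "")
  invisible(x)
}

#' Apply a sketch operator along the time dimension
#'
#' For a video, every pixel trace is replaced by its `T~`-length sketch
#' (`Y~ = Y Psi'` in the pixels-by-time orientation); for a dictionary matrix,
#' columns are sketched (`Phi~ = Psi Phi`). Sketched objects carry the
#' operator fingerprint so mismatched combinations are caught.
#'
#' @param op a [make_sketch()] operator.
#' @param x a [video_matrix()] or a `T x M` matrix.
#' @return Sketched object of the same kind.
#' @export
sketch_apply <- function(op, x) {
  stopifnot(inherits(op, "sketch_operator"))
  if (inherits(x, "video_matrix")) {
    if (ncol(x$data) != op$T_full)
      stop("video has ", ncol(x$data), " frames; sketch expects ", op$T_full)
    x$data <- tcrossprod(x$data, op$Psi)
    x$sketch <- list(id = op$id, ratio = op$ratio, normalized = op$normalized,
                     seed = op$seed, identity = op$identity)
    return(x)
  }
  x <- as.matrix(x)
  if (nrow(x) != op$T_full)
    stop("matrix has ", nrow(x), " rows; sketch expects ", op$T_full)
  out <- op$Psi %*% x
  attr(out, "sketch_id") <- op$id
  out
}

#' Empirical restricted-isometry distortion of a sketch
#'
#' Samples pairs of K-sparse-in-basis vectors and measures the ratio
#' `||Psi(y1 - y2)||^2 / ||y1 - y2||^2`. Returns the empirical scaling
#' `alpha_hat` (median ratio) and distortion `delta_hat` (maximum relative
#' deviation of the ratios from `alpha_hat`).
#'
#' @param op a [make_sketch()] operator.
#' @param sparsity K, the number of active basis columns per vector.
#' @param basis `T x M` representational basis (e.g. a dictionary); defaults
#'   to the identity (sparsity in the canonical basis).
#' @param trials number of sampled pairs (>= 10).
#' @param seed RNG seed.
#' @return List with `alpha_hat`, `delta_hat` and the per-trial `ratios`.
#' @export
rip_distortion <- function(op, sparsity = 5, basis = NULL, trials = 100, seed = 1) {
  stopifnot(trials >= 10)
  Tn <- op$T_full
  if (is.null(basis)) basis <- diag(Tn)
  basis <- as.matrix(basis)
  if (any(colSums(abs(basis)) == 0)) stop("basis has zero columns")
  set.seed(as.integer(seed))
  ratios <- vapply(seq_len(trials), function(i) {
    draw <- function() {
      idx <- sample(ncol(basis), sparsity)
      drop(basis[, idx, drop = FALSE] %*% rnorm(sparsity))
    }
    d <- draw() - draw()
    sum((op$Psi %*% d)^2) / sum(d^2)
  }, numeric(1))
  alpha_hat <- median(ratios)
  delta_hat <- if (alpha_hat > 0) max(abs(ratios - alpha_hat)) / alpha_hat else 1
  list(alpha_hat = alpha_hat, delta_hat = delta_hat, ratios = ratios)
}

#' Spatial-coefficient step in the compressed space
#'
#' Delegates to [rwl1gf()] with the sketched dictionary `Phi~ = Psi Phi`;
#' the contract is identical. Errors if the video and dictionary were
#' sketched by different operators.
#'
#' @param video_sk sketched [video_matrix()] (from [sketch_apply()]).
#' @param Phi_sk sketched dictionary (`T~ x M`, from [sketch_apply()]).
#' @param K diffusion operator.
#' @param cfg an [rwl1_config()].
#' @return A `spatial_maps` object.
#' @export
compressed_spatial_step <- function(video_sk, Phi_sk, K, cfg = rwl1_config()) {
  vid_id <- video_sk$sketch$id
  phi_id <- attr(Phi_sk, "sketch_id")
  if (is.null(vid_id) || is.null(phi_id) || !identical(vid_id, phi_id))
    stop("sketch operator mismatch between video and dictionary")
  rwl1gf(video_sk, Phi_sk, K, cfg)
}

#' Dictionary step in the compressed space
#'
#' Delegates to [update_dictionary()] on the `T~`-row problem. Nonnegativity
#' is not enforced on a sketched dictionary (sketched traces are
#' sign-indefinite); it is re-imposed at final recovery.
#'
#' @inheritParams compressed_spatial_step
#' @param A spatial coefficients from the compressed spatial step.
#' @param Phi_prev_sk previous sketched dictionary iterate.
#' @param cfg a [dictionary_config()].
#' @return Sketched `T~ x M` dictionary (sketch fingerprint preserved).
#' @export
compressed_dictionary_step <- function(video_sk, A, Phi_prev_sk,
                                       cfg = dictionary_config()) {
  cfg$nonneg <- FALSE
  out <- update_dictionary(video_sk, A, Phi_prev_sk, cfg)
  attr(out, "sketch_id") <- attr(Phi_prev_sk, "sketch_id")
  out
}

#' Recover full-length traces after a compressed run
#'
#' One dictionary solve at full T with nonnegativity on, using the final
#' spatial coefficients and the uncompressed data. The smoothness term is
#' dropped (`gamma3 = 0`): there is no previous full-length iterate to anchor
#' to.
#'
#' @param video the uncompressed [video_matrix()].
#' @param A final `spatial_maps` (or matrix) from the compressed loop.
#' @param cfg a [dictionary_config()].
#' @return `T x M` nonnegative dictionary matrix.
#' @export
recover_full_dictionary <- function(video, A, cfg = dictionary_config()) {
  if (inherits(A, "spatial_maps")) A <- A$A
  Y <- if (inherits(video, "video_matrix")) video$data else as.matrix(video)
  if (all(colSums(A^2) == 0)) stop("all spatial coefficient columns are zero")
  cfg$nonneg <- TRUE
  cfg$gamma3 <- 0
  Phi0 <- matrix(0, ncol(Y), ncol(A))
  update_dictionary(Y, A, Phi0, cfg)
}
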