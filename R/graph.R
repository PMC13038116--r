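#' Graph construction settings
#'
#' Controls the k-nearest-neighbour pixel-similarity graph. Bandwidths are
#' self-tuning in the Zelnik-Manor/Perona sense: `sigma_i` is the distance from
#' pixel `i`'s trace to its `k_sigma`-th nearest neighbour, and the edge
#' bandwidth is `sigma_i * sigma_j`.
#'
#' @param k_neighbors neighbours per pixel in the kNN search (default 12).
#' @param k_sigma neighbour rank used for the local bandwidth (default 7).
#' @param symmetrize `"union"` (edge kept if either endpoint lists the other;
#'   default, preserves connectivity) or `"mutual"`.
#' @param distance_on `"raw"` (default: distances on the raw traces even when
#'   the learning loop runs sketched) or `"compressed"` (distances on whatever
#'   representation the pipeline holds).
#' @return A `graph_config` list.
#' @export
graph_config <- function(k_neighbors = 12, k_sigma = 7,
                         symmetrize = c("union", "mutual"),
                         distance_on = c("raw", "compressed")) {
  symmetrize <- match.arg(symmetrize)
  distance_on <- match.arg(distance_on)
  stopifnot(k_sigma >= 1, k_neighbors >= k_sigma)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 k_sigma = as.integer(k_sigma),
                 symmetrize = symmetrize, distance_on = distance_on),
            class = "graph_config")
}

# Dense Euclidean distance matrix between pixel traces via the Gram trick.
trace_distances <- function(Y) {
  G <- tcrossprod(Y)
  n2 <- diag(G)
  D2 <- outer(n2, n2, "+") - 2 * G
  D2[D2 < 0] <- 0
  sqrt(D2)
}

#' Self-tuning local kernel bandwidths
#'
#' `sigma_i` is the Euclidean distance from pixel `i`'s trace to its
#' `k_sigma`-th nearest neighbour trace. Duplicate traces (zero distance) are
#' floored at `1e-8 *` the median pairwise distance, with a warning.
#'
#' @param video a [video_matrix()] (or a plain `N x T` matrix).
#' @param k_sigma neighbour rank (must be `< N`).
#' @param dist_mat optional precomputed `N x N` distance matrix.
#' @return Positive numeric vector of length `N`.
#' @export
local_bandwidths <- function(video, k_sigma = 7, dist_mat = NULL) {
  Y <- if (inherits(video, "video_matrix")) video$data else as.matrix(video)
  n <- nrow(Y)
  if (k_sigma >= n) stop("k_sigma must be smaller than the number of pixels")
  if (is.null(dist_mat)) dist_mat <- trace_distances(Y)
  sig <- apply(dist_mat, 1, function(d) sort(d, partial = k_sigma + 1)[k_sigma + 1])
  if (any(sig <= 0)) {
    floor_eps <- 1e-8 * median(dist_mat[upper.tri(dist_mat)])
    if (floor_eps <= 0) floor_eps <- 1e-8
    warning(sum(sig <= 0), " duplicate traces: bandwidth floored at ",
            format(floor_eps))
    sig[sig <= 0] <- floor_eps
  }
  sig
}

#' Build the kNN affinity matrix W
#'
#' On kept kNN edges, `W_ij = exp(-||y_i - y_j||^2 / (sigma_i * sigma_j))`;
#' elsewhere 0. W is symmetric with zero diagonal.
#'
#' @inheritParams local_bandwidths
#' @param sigmas local bandwidths from [local_bandwidths()].
#' @param config a [graph_config()].
#' @return Sparse symmetric `N x N` [Matrix::sparseMatrix] of affinities.
#' @export
build_affinity <- function(video, sigmas, config = graph_config(), dist_mat = NULL) {
  Y <- if (inherits(video, "video_matrix")) video$data else as.matrix(video)
  n <- nrow(Y)
  k <- config$k_neighbors
  if (k >= n) stop("k_neighbors must be smaller than the number of pixels")
  if (is.null(dist_mat)) dist_mat <- trace_distances(Y)
  # kNN edge list (excluding self)
  nb <- t(apply(dist_mat, 1, function(d) order(d)[2:(k + 1)]))
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(nb))
  Adj <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  Adj <- if (config$symmetrize == "union") {
    (Adj + Matrix::t(Adj)) > 0
  } else {
    (Adj * Matrix::t(Adj)) > 0
  }
  Adj <- as(Adj, "TsparseMatrix")
  ii <- Adj@i + 1L; jj <- Adj@j + 1L
  w <- exp(-dist_mat[cbind(ii, jj)]^2 / (sigmas[ii] * sigmas[jj]))
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  Matrix::drop0((W + Matrix::t(W)) / 2) # enforce exact symmetry
}

#' Row-normalize W into the diffusion operator K
#'
#' `K = D^-1 W` where `D` is the diagonal degree matrix; every row of `K` sums
#' to 1. Applying `K` averages a pixel-indexed quantity over graph neighbours.
#'
#' @param W sparse affinity matrix from [build_affinity()].
#' @return List with `K` (sparse row-stochastic matrix) and `degrees`.
#' @export
normalize_diffusion <- function(W) {
  deg <- Matrix::rowSums(W)
  iso <- which(deg <= 0)
  if (length(iso))
    stop("isolated pixels (zero graph degree): ", paste(head(iso, 5), collapse = ", "))
  K <- Matrix::Diagonal(x = 1 / deg) %*% W
  list(K = as(K, "CsparseMatrix"), degrees = deg)
}

#' Build the full pixel-similarity graph
#'
#' Convenience wrapper running [local_bandwidths()], [build_affinity()] and
#' [normalize_diffusion()] on one shared distance matrix.
#'
#' @inheritParams build_affinity
#' @return An `affinity_graph` object: list with `W`, `sigmas`, `K`, `degrees`,
#'   `config`.
#' @export
build_graph <- function(video, config = graph_config()) {
  Y <- if (inherits(video, "video_matrix")) video$data else as.matrix(video)
  dist_mat <- trace_distances(Y)
  sigmas <- local_bandwidths(Y, config$k_sigma, dist_mat = dist_mat)
  W <- build_affinity(Y, sigmas, config, dist_mat = dist_mat)
  nd <- normalize_diffusion(W)
  structure(list(W = W, sigmas = sigmas, K = nd$K, degrees = nd$degrees,
                 config = config),
            class = "affinity_graph")
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat("<affinity_graph> ", nrow(x$W), " pixels, ",
      Matrix::nnzero(x$W), " edges (k=", x$config$k_neighbors, ", ",
      x$config$symmetrize, ")\n", sep = "")
  invisible(x)
}

#' Export graph matrices in MatrixMarket format
#'
#' @param graph an `affinity_graph`.
#' @param dir output directory; writes `W.mtx` and `K.mtx`.
#' @export
export_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(graph$W, file.path(dir, "W.mtx"))
  Matrix::writeMM(as(graph$K, "generalMatrix"), file.path(dir, "K.mtx"))
  invisible(dir)
}
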