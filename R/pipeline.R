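#' Full pipeline configuration
#'
#' Defaults reproduce the reference hyper-parameter set used for somatic
#' two-photon data: `lambda0 = 0.7`, `gamma1 = 0.2` (Frobenius), `gamma2 = 0.1`
#' (decorrelation), `gamma3 = 0.1` (continuity), `beta = 0.09`,
#' `learn_eps = 5e-4`, `max_components = 50`, nonnegative spatial maps and
#' dictionary, and per-iteration spatial normalization.
#'
#' @param lambda0 global sparsity scale.
#' @param gamma1,gamma2,gamma3 dictionary regularizers (see
#'   [dictionary_config()]).
#' @param beta,xi re-weighting parameters (see [rwl1_config()]).
#' @param noise_var Gaussian noise variance weighting the data term (see
#'   [rwl1_config()]); default 1. When set explicitly it is estimated/applied
#'   on the raw data and reused for compressed runs.
#' @param learn_eps relative dictionary-change convergence threshold.
#' @param max_components dictionary size M (pruning shrinks the effective
#'   count).
#' @param inner_iters re-weighting rounds per outer iteration.
#' @param outer_max_iters outer-iteration cap.
#' @param nonneg,nneg_dict nonnegativity of the spatial maps / dictionary.
#' @param normalize_spatial rescale surviving spatial columns to unit l2 norm
#'   each iteration (dictionary columns inversely, leaving `A Phi'` fixed).
#' @param prune_rel relative spatial-column-norm threshold below which a
#'   component is pruned (default 1e-3).
#' @param reseed_dead re-seed dead dictionary columns from the
#'   worst-reconstructed pixel's residual instead of pruning (default FALSE).
#' @param graph a [graph_config()].
#' @param sketch `NULL` for the uncompressed pipeline, or a list with `ratio`,
#'   `normalized` (default FALSE) and optional `seed`.
#' @param solver a [solver_config()].
#' @param dict_method dictionary solver (see [dictionary_config()]).
#' @param rng_seed master seed; all randomness (dictionary initialization,
#'   sketch draw) derives from it through named substreams.
#' @param delta_f apply [delta_f_over_f()] before analysis (default FALSE).
#' @return A `graft_config` list.
#' @export
graft_config <- function(lambda0 = 0.7, gamma1 = 0.2, gamma2 = 0.1,
                         gamma3 = 0.1, beta = 0.09, xi = 1, noise_var = NULL,
                         learn_eps = 5e-4, max_components = 50,
                         inner_iters = 3, outer_max_iters = 50,
                         nonneg = TRUE, nneg_dict = TRUE,
                         normalize_spatial = TRUE, prune_rel = 1e-3,
                         reseed_dead = FALSE,
                         graph = graph_config(), sketch = NULL,
                         solver = solver_config(),
                         dict_method = c("bcd", "projected_gradient"),
                         rng_seed = 1, delta_f = FALSE) {
  dict_method <- match.arg(dict_method)
  stopifnot(max_components >= 1, learn_eps > 0, outer_max_iters >= 0)
  if (!is.null(sketch)) {
    stopifnot(is.list(sketch), !is.null(sketch$ratio))
    sketch$normalized <- isTRUE(sketch$normalized)
  }
  structure(list(lambda0 = lambda0, gamma1 = gamma1, gamma2 = gamma2,
                 gamma3 = gamma3, beta = beta, xi = xi, noise_var = noise_var,
                 learn_eps = learn_eps,
                 max_components = as.integer(max_components),
                 inner_iters = as.integer(inner_iters),
                 outer_max_iters = as.integer(outer_max_iters),
                 nonneg = nonneg, nneg_dict = nneg_dict,
                 normalize_spatial = normalize_spatial,
                 prune_rel = prune_rel, reseed_dead = reseed_dead,
                 graph = graph, sketch = sketch, solver = solver,
                 dict_method = dict_method, rng_seed = rng_seed,
                 delta_f = delta_f),
            class = "graft_config")
}

#' Random dictionary initialization
#'
#' I.i.d. uniform(0, 1) entries with columns scaled to unit l2 norm;
#' deterministic given the seed.
#'
#' @param rows trace length (T, or `T~` when sketched).
#' @param M number of components.
#' @param seed RNG seed.
#' @return `rows x M` matrix with unit-norm columns.
#' @export
init_dictionary <- function(rows, M, seed = 1) {
  set.seed(as.integer(seed))
  Phi <- matrix(runif(rows * M), rows, M)
  sweep(Phi, 2, sqrt(colSums(Phi^2)), "/")
}

#' Convergence check on the dictionary iterates
#'
#' True iff `||Phi_t - Phi_prev||_F / max(||Phi_prev||_F, 1e-12) < learn_eps`.
#'
#' @param Phi_t,Phi_prev same-shape dictionary iterates.
#' @param learn_eps relative threshold.
#' @return Logical.
#' @export
check_convergence <- function(Phi_t, Phi_prev, learn_eps = 5e-4) {
  denom <- max(sqrt(sum(Phi_prev^2)), 1e-12)
  sqrt(sum((Phi_t - Phi_prev)^2)) / denom < learn_eps
}

#' Prune dead components and normalize spatial columns
#'
#' Components whose spatial column l2 norm falls below `prune_rel` times the
#' largest column norm are removed from both `A` and `Phi`. If
#' `normalize_spatial`, each surviving spatial column is rescaled to unit l2
#' norm and its dictionary column inversely, leaving the reconstruction
#' `A Phi'` unchanged.
#'
#' @param A `N x M` spatial coefficients (or `spatial_maps`).
#' @param Phi `rows x M` dictionary.
#' @param prune_rel relative norm threshold (0 disables pruning).
#' @param normalize_spatial rescale surviving columns?
#' @return List with `A`, `Phi`, and `dropped` (original column indices
#'   removed).
#' @export
prune_and_normalize <- function(A, Phi, prune_rel = 1e-3,
                                normalize_spatial = TRUE) {
  if (inherits(A, "spatial_maps")) A <- A$A
  A <- as.matrix(A); Phi <- as.matrix(Phi)
  norms <- sqrt(colSums(A^2))
  keep <- norms > prune_rel * max(norms)
  if (!any(keep))
    stop("all components pruned; consider reducing lambda0")
  dropped <- which(!keep)
  A <- A[, keep, drop = FALSE]
  Phi <- Phi[, keep, drop = FALSE]
  if (normalize_spatial) {
    cn <- sqrt(colSums(A^2))
    A <- sweep(A, 2, cn, "/")
    Phi <- sweep(Phi, 2, cn, "*")
  }
  list(A = A, Phi = Phi, dropped = dropped)
}

#' Run the full graph-filtered dictionary-learning pipeline
#'
#' Orchestrates the alternating optimization: builds the pixel graph once,
#' optionally sketches the data along time, then loops spatial-coefficient
#' estimation ([rwl1gf()]) and dictionary updates ([update_dictionary()]) with
#' per-iteration pruning/normalization until the dictionary stops changing
#' (relative change `< learn_eps`) or `outer_max_iters` is reached. Compressed
#' runs end with one full-length dictionary recovery
#' ([recover_full_dictionary()]). Deterministic given `rng_seed`.
#'
#' @param video a [video_matrix()].
#' @param config a [graft_config()].
#' @return A `graft_result`: list with `A` (`N x M`, rows aligned with
#'   `video`), `Phi` (`T x M`, full length), and `diagnostics` (per-iteration
#'   dictionary objective, reconstruction error and component count,
#'   convergence flag, pruning log, sketch metadata, solver failures, config
#'   echo).
#' @export
run_graft <- function(video, config = graft_config()) {
  stopifnot(inherits(video, "video_matrix"), inherits(config, "graft_config"))
  if (config$delta_f) video <- delta_f_over_f(video)
  Yfull <- video$data
  N <- nrow(Yfull); Tn <- ncol(Yfull)

  # zero-variance pixels have undefined graph bandwidths; exclude, report A = 0
  rv <- rowSums((Yfull - rowMeans(Yfull))^2)
  live <- which(rv > 0)
  if (length(live) < 2) stop("fewer than two pixels with temporal variance")
  Ylive <- Yfull[live, , drop = FALSE]

  noise_var <- config$noise_var %||% 1

  # sketch (built and applied once, before the learning loop)
  op <- NULL
  vid_loop <- video_matrix(Ylive, fov_shape = c(length(live), 1L))
  if (!is.null(config$sketch)) {
    op <- make_sketch(Tn, ratio = config$sketch$ratio,
                      normalized = config$sketch$normalized,
                      seed = config$sketch$seed %||%
                        substream_seed(config$rng_seed, "sketch"))
    vid_sk <- sketch_apply(op, vid_loop)
  }
  compressed <- !is.null(op) && !op$identity

  # graph from raw or sketched traces (built once)
  graph_src <- if (config$graph$distance_on == "compressed" && compressed)
    vid_sk$data else Ylive
  graph <- build_graph(graph_src, config$graph)

  loop_vid <- if (compressed) vid_sk else vid_loop
  rows <- ncol(loop_vid$data)

  Phi <- init_dictionary(Tn, config$max_components,
                         substream_seed(config$rng_seed, "dict_init"))
  if (compressed) Phi <- sketch_apply(op, Phi)

  rw_cfg <- rwl1_config(lambda0 = config$lambda0, xi = config$xi,
                        beta = config$beta, noise_var = noise_var,
                        inner_iters = config$inner_iters,
                        solver = config$solver)
  d_cfg <- dictionary_config(gamma1 = config$gamma1, gamma2 = config$gamma2,
                             gamma3 = config$gamma3,
                             nonneg = config$nneg_dict,
                             method = config$dict_method)

  diag_obj <- diag_obj_pre <- diag_rec <- diag_m <- numeric(0)
  pruned_log <- list()
  failed <- integer(0)
  converged <- FALSE
  iter <- 0L
  A <- matrix(0, length(live), ncol(Phi))
  yn2 <- sum(loop_vid$data^2)
  while (iter < config$outer_max_iters) {
    iter <- iter + 1L
    maps <- if (compressed) {
      compressed_spatial_step(loop_vid, Phi, graph$K, rw_cfg)
    } else {
      rwl1gf(loop_vid, Phi, graph$K, rw_cfg)
    }
    failed <- union(failed, maps$failed_pixels)
    A <- maps$A
    if (config$reseed_dead) {
      res <- reseed_dead_components(loop_vid$data, A, Phi)
      A <- res$A; Phi <- res$Phi
    }
    pr <- prune_and_normalize(A, Phi, prune_rel = config$prune_rel,
                              normalize_spatial = FALSE)
    if (length(pr$dropped)) pruned_log[[length(pruned_log) + 1]] <-
      list(iteration = iter, dropped = pr$dropped)
    A <- pr$A
    Phi_prev <- pr$Phi
    attr(Phi_prev, "sketch_id") <- attr(Phi, "sketch_id") # survives pruning
    Phi <- if (compressed) {
      compressed_dictionary_step(loop_vid, A, Phi_prev, d_cfg)
    } else {
      update_dictionary(loop_vid, A, Phi_prev, d_cfg)
    }
    if (config$normalize_spatial) {
      cn <- sqrt(colSums(A^2))
      pos <- cn > 0
      A[, pos] <- sweep(A[, pos, drop = FALSE], 2, cn[pos], "/")
      sk_id <- attr(Phi, "sketch_id")
      Phi[, pos] <- sweep(Phi[, pos, drop = FALSE], 2, cn[pos], "*")
      attr(Phi, "sketch_id") <- sk_id
      Phi_prev[, pos] <- sweep(Phi_prev[, pos, drop = FALSE], 2, cn[pos], "*")
    }
    diag_obj <- c(diag_obj, attr(Phi, "objective") %||%
                    dictionary_objective(loop_vid$data, A, Phi, Phi_prev, d_cfg))
    diag_obj_pre <- c(diag_obj_pre, attr(Phi, "objective_before") %||% NA_real_)
    diag_rec <- c(diag_rec,
                  sqrt(sum((loop_vid$data - tcrossprod(A, Phi))^2) / yn2))
    diag_m <- c(diag_m, ncol(Phi))
    if (check_convergence(Phi, Phi_prev, config$learn_eps)) {
      converged <- TRUE
      break
    }
  }

  Phi_full <- if (compressed) {
    recover_full_dictionary(vid_loop, A, d_cfg)
  } else {
    as.matrix(Phi)
  }
  attr(Phi_full, "objective") <- NULL; attr(Phi_full, "sweeps") <- NULL
  attr(Phi_full, "objective_before") <- NULL
  attr(Phi_full, "sketch_id") <- NULL

  # a component whose recovered trace is (near-)zero contributes nothing to
  # the factorization; drop it (keeps the no-all-zero-column invariant)
  tn <- sqrt(colSums(Phi_full^2))
  keep_tr <- tn > config$prune_rel * max(tn)
  final_pruned <- which(!keep_tr)
  if (length(final_pruned)) {
    Phi_full <- Phi_full[, keep_tr, drop = FALSE]
    A <- A[, keep_tr, drop = FALSE]
  }

  # re-insert zero-variance pixels as all-zero rows
  A_out <- matrix(0, N, ncol(Phi_full))
  A_out[live, ] <- A

  structure(list(
    A = A_out, Phi = Phi_full,
    diagnostics = list(
      objective = diag_obj, objective_before_update = diag_obj_pre,
      reconstruction_error = diag_rec,
      n_components = diag_m, iterations = iter, converged = converged,
      pruned = pruned_log, final_pruned = final_pruned,
      failed_pixels = failed,
      noise_var = noise_var,
      sketch = if (!is.null(op))
        list(ratio = op$ratio, normalized = op$normalized, seed = op$seed,
             T_sketch = op$T_sketch, identity = op$identity),
      zero_variance_pixels = setdiff(seq_len(N), live),
      config = config)),
    class = "graft_result")
}

# Replace traces of dead components with the residual trace of the worst
# reconstructed pixel (standard dictionary-learning re-seeding).
reseed_dead_components <- function(Y, A, Phi) {
  norms <- sqrt(colSums(A^2))
  dead <- which(norms < 1e-8 * max(norms))
  if (length(dead)) {
    R <- Y - tcrossprod(A, Phi)
    worst <- order(rowSums(R^2), decreasing = TRUE)
    for (j in seq_along(dead)) {
      tr <- pmax(R[worst[j], ], 0)
      n <- sqrt(sum(tr^2))
      if (n > 0) Phi[, dead[j]] <- tr / n
    }
  }
  list(A = A, Phi = Phi)
}

#' @export
print.graft_result <- function(x, ...) {
  d <- x$diagnostics
  cat("<graft_result> ", ncol(x$A), " components over ", nrow(x$A),
      " pixels x ", nrow(x$Phi), " frames\n", sep = "")
  cat("  outer iterations: ", d$iterations,
      if (d$converged) " (converged)" else " (iteration cap)", "\n", sep = "")
  cat("  final reconstruction error: ",
      signif(tail(d$reconstruction_error, 1), 4), "\n", sep = "")
  if (!is.null(d$sketch) && !isTRUE(d$sketch$identity))
    cat("  sketched ", d$sketch$ratio, "x",
        if (d$sketch$normalized) " (normalized)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.graft_result <- function(object, ...) {
  d <- object$diagnostics
  data.frame(iteration = seq_along(d$objective),
             objective = d$objective,
             reconstruction_error = d$reconstruction_error,
             n_components = d$n_components)
}

#' Save / load a result bundle
#'
#' Serializes the result (plus optional component images) next to each other.
#'
#' @param result a `graft_result`.
#' @param path `.rds` output path.
#' @export
save_result <- function(result, path) {
  saveRDS(result, path)
  invisible(path)
}

#' @rdname save_result
#' @export
load_result <- function(path) readRDS(path)
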