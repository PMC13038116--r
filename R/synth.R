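#' Specification of a synthetic calcium-imaging video
#'
#' Describes a ground-truth-bearing simulation that reproduces the statistical
#' structure the learning model assumes — a nonnegative factorization
#' `Y = A Phi' + E` with sparse spatial components, spike-driven calcium
#' transients and additive Gaussian sensor noise. Spatial components are
#' isotropic Gaussian blobs (somata, sd 2-4 px) or curvilinear random-walk
#' paths (processes, width 1-2 px); traces are Poisson spike trains convolved
#' with a double-exponential kernel `(1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`.
#' No optical model (PSF, scanning) is simulated.
#'
#' @param fov_shape FOV in pixels (default `c(40, 40)`).
#' @param n_frames number of frames T (default 4096).
#' @param frame_rate Hz (default 30).
#' @param n_components number of true components (default 20).
#' @param morphology_mix fractions of `c(soma, process)` shapes, summing to 1
#'   (default `c(0.8, 0.2)`).
#' @param amplitude_range transient amplitude range (default `c(0.5, 1.5)`).
#' @param spike_rate Poisson spike rate in Hz (default 0.1).
#' @param tau_rise,tau_decay kernel time constants in seconds (defaults 0.1, 1).
#' @param target_snr pixel signal-to-noise ratio: mean temporal sd of the
#'   clean trace over core pixels (footprint >= 0.5), divided by the noise sd
#'   (default 5). Used only when `noise_sigma` is `NULL`.
#' @param noise_sigma additive Gaussian noise sd; `NULL` derives it from
#'   `target_snr`.
#' @param baseline_frac constant baseline as a fraction of amplitude
#'   (default 0.05).
#' @param overlap_fraction maximum allowed fraction of a new component's core
#'   (half-maximum) pixels already covered by earlier components (default
#'   0.25); colliding components are re-drawn.
#' @param seed RNG seed (default 11).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(fov_shape = c(40, 40), n_frames = 4096,
                           frame_rate = 30, n_components = 20,
                           morphology_mix = c(soma = 0.8, process = 0.2),
                           amplitude_range = c(0.5, 1.5), spike_rate = 0.1,
                           tau_rise = 0.1, tau_decay = 1, target_snr = 5,
                           noise_sigma = NULL, baseline_frac = 0.05,
                           overlap_fraction = 0.25, seed = 11) {
  stopifnot(abs(sum(morphology_mix) - 1) < 1e-8, spike_rate >= 0,
            tau_rise > 0, tau_decay > 0, overlap_fraction >= 0,
            overlap_fraction < 1, n_components >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Double-exponential calcium impulse response, peak-normalized.
calcium_kernel <- function(frame_rate, tau_rise, tau_decay, max_len) {
  t <- seq(0, by = 1 / frame_rate, length.out = max_len)
  h <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  keep <- seq_len(max(which(h > 1e-4 * max(h)), 2))
  h <- h[keep]
  h / max(h)
}

# One spatial footprint on the FOV grid; values in [0, 1].
draw_footprint <- function(kind, nx, ny) {
  gx <- matrix(rep(seq_len(nx), ny), nx, ny)
  gy <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  if (kind == "soma") {
    sig <- runif(1, 2, 4)
    cx <- runif(1, 1 + sig, nx - sig)
    cy <- runif(1, 1 + sig, ny - sig)
    fp <- exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * sig^2))
  } else {
    width <- runif(1, 1, 2)
    n_steps <- sample(15:35, 1)
    pos <- matrix(NA_real_, n_steps, 2)
    pos[1, ] <- c(runif(1, 5, nx - 5), runif(1, 5, ny - 5))
    ang <- runif(1, 0, 2 * pi)
    for (s in 2:n_steps) {
      ang <- ang + rnorm(1, 0, 0.35)
      pos[s, ] <- pmin(pmax(pos[s - 1, ] + c(cos(ang), sin(ang)), 1.5),
                       c(nx, ny) - 0.5)
    }
    d2 <- matrix(Inf, nx, ny)
    for (s in seq_len(n_steps))
      d2 <- pmin(d2, (gx - pos[s, 1])^2 + (gy - pos[s, 2])^2)
    fp <- exp(-d2 / (2 * (width / 2)^2))
  }
  fp[fp < 0.05] <- 0
  fp
}

#' Generate a synthetic video with ground truth
#'
#' Deterministic given `spec$seed`. Components whose half-maximum core
#' overlaps already-placed components by more than `overlap_fraction` are
#' re-drawn (bounded retries). Every component ends with at least one pixel
#' and at least one spike.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `video` (a [video_matrix()]), `ground_truth` (list:
#'   `A_true` `N x M`, `Phi_true` `T x M`, `spike_times` list of frame
#'   indices), `noise_sigma` (the value actually used), and `spec`.
#' @export
generate_video <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(spec$seed))
  nx <- spec$fov_shape[1]; ny <- spec$fov_shape[2]
  N <- nx * ny; Tn <- spec$n_frames; M <- spec$n_components
  kinds <- sample(rep(names(spec$morphology_mix),
                      times = round(spec$morphology_mix * M))[seq_len(M)])
  kinds[is.na(kinds)] <- "soma"

  A <- matrix(0, N, M)
  core <- matrix(FALSE, N, M)
  im <- full_index_map(c(nx, ny))
  covered <- rep(FALSE, N)
  for (m in seq_len(M)) {
    placed <- FALSE
    for (try in seq_len(200)) {
      fp <- draw_footprint(kinds[m], nx, ny)
      v <- fp[im] # flatten in row-major pixel order
      cr <- v >= 0.5
      if (!any(cr)) next
      if (mean(covered[cr]) <= spec$overlap_fraction) {
        A[, m] <- v
        core[, m] <- cr
        covered <- covered | cr
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place component ", m,
                      " within the overlap budget; lower n_components or ",
                      "raise overlap_fraction")
  }

  kern <- calcium_kernel(spec$frame_rate, spec$tau_rise, spec$tau_decay, Tn)
  Phi <- matrix(0, Tn, M)
  spikes <- vector("list", M)
  amp <- runif(M, spec$amplitude_range[1], spec$amplitude_range[2])
  p_spike <- min(spec$spike_rate / spec$frame_rate, 1)
  for (m in seq_len(M)) {
    counts <- rpois(Tn, p_spike)
    for (try in seq_len(100)) {
      if (sum(counts) >= 1) break
      counts <- rpois(Tn, p_spike)
    }
    if (sum(counts) < 1) counts[sample(Tn, 1)] <- 1
    tr <- convolve_counts(counts, kern)
    spikes[[m]] <- which(counts > 0)
    Phi[, m] <- amp[m] * (tr + spec$baseline_frac)
  }

  clean <- tcrossprod(A, Phi)
  sig <- spec$noise_sigma
  if (is.null(sig)) {
    core_any <- rowSums(core) > 0
    sds <- apply(clean[core_any, , drop = FALSE], 1, sd)
    sig <- mean(sds) / spec$target_snr
  }
  Y <- clean + matrix(rnorm(N * Tn, sd = sig), N, Tn)
  # fluorescence is nonnegative; shift is irrelevant to the factorization model
  video <- video_matrix(Y, fov_shape = c(nx, ny),
                        frame_rate = spec$frame_rate)
  list(video = video,
       ground_truth = list(A_true = A, Phi_true = Phi, spike_times = spikes),
       noise_sigma = sig, spec = spec)
}

# Linear convolution of spike counts with a kernel, truncated to length(x).
convolve_counts <- function(x, kern) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(kern))), rev(kern), type = "open")
  out[seq_len(n)]
}

#' Tag estimated traces by their best-correlated reference trace
#'
#' Computes the Pearson correlation of every (estimated, reference) trace
#' pair and tags each estimated trace with its maximum; several estimated
#' traces may map to the same reference. Zero-variance traces get rho = 0 and
#' are flagged.
#'
#' @param Phi_est `T x M_est` estimated traces (or a `graft_result`).
#' @param Phi_ref `T x M_ref` reference traces.
#' @param zscore z-score traces before correlating (Pearson correlation is
#'   already location/scale invariant; exposed for parity with other
#'   definitions).
#' @return A `match_report`: list with `matches` (data.frame `est`, `ref`,
#'   `rho`), `cor_matrix`, `n_est`, `n_ref`, `flagged`.
#' @export
match_traces <- function(Phi_est, Phi_ref, zscore = FALSE) {
  if (inherits(Phi_est, "graft_result")) Phi_est <- Phi_est$Phi
  if (inherits(Phi_ref, "graft_result")) Phi_ref <- Phi_ref$Phi
  Phi_est <- as.matrix(Phi_est); Phi_ref <- as.matrix(Phi_ref)
  if (nrow(Phi_est) != nrow(Phi_ref)) stop("trace lengths differ")
  if (!ncol(Phi_est) || !ncol(Phi_ref)) stop("empty trace set")
  if (zscore) {
    Phi_est <- scale(Phi_est); Phi_ref <- scale(Phi_ref)
  }
  flagged_e <- which(apply(Phi_est, 2, sd) == 0)
  flagged_r <- which(apply(Phi_ref, 2, sd) == 0)
  suppressWarnings(cm <- cor(Phi_est, Phi_ref))
  cm[!is.finite(cm)] <- 0
  best <- max.col(cm, ties.method = "first")
  structure(list(
    matches = data.frame(est = seq_len(ncol(Phi_est)), ref = best,
                         rho = cm[cbind(seq_len(nrow(cm)), best)]),
    cor_matrix = cm, n_est = ncol(Phi_est), n_ref = ncol(Phi_ref),
    flagged = list(est = flagged_e, ref = flagged_r)),
    class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report> ", x$n_est, " estimated vs ", x$n_ref,
      " reference traces; median tag rho = ",
      signif(median(x$matches$rho), 3), "\n", sep = "")
  invisible(x)
}

#' Fraction of reference traces recovered above a correlation level
#'
#' Each reference trace is tagged by its best-correlated estimated trace;
#' returns the percentage tagged at `rho >= level`.
#'
#' @param report a [match_traces()] report built with the reference set as
#'   `Phi_est` (i.e. tags follow the reference traces), or a pair of matrices.
#' @param level correlation level.
#' @return Percentage in `[0, 100]`.
#' @export
recovered_fraction <- function(report, level = 0.8) {
  stopifnot(inherits(report, "match_report"))
  100 * mean(report$matches$rho >= level)
}

#' Cross-run agreement matrix
#'
#' For an ordered pair of runs (reference r, comparison c), the `"reference"`
#' convention (default) reports `100 x` the fraction of reference-run traces
#' whose best match among comparison-run traces exceeds `rho_thresh`. The
#' `"comparison"` convention counts comparison-run traces tagged (best match)
#' above threshold against the reference run, divided by the reference-run
#' trace count; this can exceed 100 when the comparison run finds more traces.
#'
#' @param results list of `T x M` trace matrices or `graft_result`s (all
#'   sharing T, i.e. after full-length recovery).
#' @param rho_thresh correlation threshold (default 0.5).
#' @param convention `"reference"` or `"comparison"` (see above).
#' @return Square matrix of percentages with `dimnames` from `names(results)`.
#' @export
agreement_matrix <- function(results, rho_thresh = 0.5,
                             convention = c("reference", "comparison")) {
  convention <- match.arg(convention)
  mats <- lapply(results, function(r) if (inherits(r, "graft_result")) r$Phi else as.matrix(r))
  if (!length(mats)) stop("no results")
  n <- length(mats)
  out <- matrix(0, n, n, dimnames = list(names(results), names(results)))
  for (r in seq_len(n)) for (cc in seq_len(n)) {
    if (convention == "reference") {
      rep_ <- match_traces(mats[[r]], mats[[cc]])
      out[r, cc] <- 100 * mean(rep_$matches$rho > rho_thresh)
    } else {
      rep_ <- match_traces(mats[[cc]], mats[[r]])
      out[r, cc] <- 100 * sum(rep_$matches$rho > rho_thresh) / ncol(mats[[r]])
    }
  }
  out
}

#' Histogram of trace-correlation tags
#'
#' @param report a [match_traces()] report.
#' @param bin_width bin width over `[-1, 1]` (default 0.05).
#' @return List with `breaks`, `mids`, `counts`; counts sum to the number of
#'   estimated traces.
#' @export
correlation_histogram <- function(report, bin_width = 0.05) {
  stopifnot(inherits(report, "match_report"))
  breaks <- seq(-1, 1, by = bin_width)
  if (tail(breaks, 1) < 1) breaks <- c(breaks, 1)
  h <- hist(pmin(pmax(report$matches$rho, -1), 1), breaks = breaks,
            plot = FALSE, include.lowest = TRUE)
  list(breaks = h$breaks, mids = h$mids, counts = h$counts)
}
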