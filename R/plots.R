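#' Plot dictionary time traces
#'
#' Stacked trace plot of the learned dictionary, one offset line per
#' component.
#'
#' @param x a `graft_result`.
#' @param max_traces show at most this many traces (default 20).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.graft_result <- function(x, max_traces = 20, ...) {
  Phi <- x$Phi[, seq_len(min(ncol(x$Phi), max_traces)), drop = FALSE]
  rng <- max(apply(Phi, 2, function(v) diff(range(v))), 1e-12)
  off <- sweep(Phi, 2, (seq_len(ncol(Phi)) - 1) * rng, "+")
  graphics::matplot(off, type = "l", lty = 1, xlab = "frame",
                    ylab = "trace (offset)", ...)
  invisible(x)
}

#' Plot spatial component images
#'
#' @param result a `graft_result` (or `N x M` matrix).
#' @param video the [video_matrix()] providing FOV geometry.
#' @param components which components to draw (default all, up to 25).
#' @export
plot_components <- function(result, video, components = NULL) {
  imgs <- unflatten(result, video)
  M <- dim(imgs)[3]
  components <- components %||% seq_len(min(M, 25))
  nrow_ <- ceiling(sqrt(length(components)))
  op <- graphics::par(mfrow = c(nrow_, ceiling(length(components) / nrow_)),
                      mar = c(0.5, 0.5, 1.2, 0.5))
  on.exit(graphics::par(op))
  for (m in components) {
    graphics::image(t(imgs[dim(imgs)[1]:1, , m]), axes = FALSE,
                    main = paste("component", m), col = grDevices::hcl.colors(64))
  }
  invisible(result)
}

#' Plot a trace-correlation histogram
#'
#' @param report a [match_traces()] report.
#' @param bin_width histogram bin width (default 0.05).
#' @param ... passed to [graphics::barplot()].
#' @export
plot_correlation_histogram <- function(report, bin_width = 0.05, ...) {
  h <- correlation_histogram(report, bin_width)
  graphics::barplot(h$counts, names.arg = signif(h$mids, 2), space = 0,
                    xlab = "best-match correlation", ylab = "traces", ...)
  invisible(h)
}
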