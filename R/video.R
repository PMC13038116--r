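#' Construct a pixel-by-time video matrix
#'
#' The central data container: fluorescence data as an `N x T` matrix whose
#' rows are pixel time traces, together with the field-of-view geometry and an
#' optional analysis mask. Rows are ordered row-major over the FOV (pixel
#' `(r, c)` maps to row `(r - 1) * Ny + c` when unmasked); the exact mapping is
#' recorded in `index_map` so downstream results are order-independent.
#'
#' @param data numeric `N x T` matrix (or `Nx x Ny x T` array, which is
#'   flattened) of fluorescence values; must be finite.
#' @param fov_shape integer `(Nx, Ny)`; inferred from an array input.
#' @param mask optional logical `Nx x Ny` matrix restricting analysis to the
#'   `TRUE` pixels.
#' @param frame_rate optional sampling rate in Hz (metadata only).
#' @return An object of class `video_matrix`: a list with elements `data`
#'   (`N x T` matrix), `fov_shape`, `index_map` (`N x 2` matrix of (row, col)
#'   pixel coordinates), `mask`, `frame_rate` and `sketch` (`NULL` until
#'   [sketch_apply()] is used).
#' @examples
#' v <- video_matrix(array(runif(4 * 4 * 10), c(4, 4, 10)))
#' dim(v$data) # 16 x 10
#' @export
video_matrix <- function(data, fov_shape = NULL, mask = NULL, frame_rate = NULL) {
  if (is.array(data) && length(dim(data)) == 3) {
    fov_shape <- dim(data)[1:2]
    data <- flatten_frames(data)
  }
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("video data must be numeric")
  bad <- which(!is.finite(data))
  if (length(bad)) {
    fr <- unique(ceiling(bad / nrow(data)))
    stop("non-finite entries in video data (frames: ",
         paste(head(fr, 5), collapse = ", "), ")")
  }
  if (ncol(data) < 2) stop("a video needs at least T = 2 frames")
  if (is.null(fov_shape)) stop("fov_shape required for matrix input")
  fov_shape <- as.integer(fov_shape)
  im <- full_index_map(fov_shape)
  v <- structure(list(data = data, fov_shape = fov_shape, index_map = im,
                      mask = NULL, frame_rate = frame_rate, sketch = NULL),
                 class = "video_matrix")
  if (nrow(data) != prod(fov_shape))
    stop("nrow(data) [", nrow(data), "] != prod(fov_shape) [", prod(fov_shape), "]")
  if (!is.null(mask)) v <- apply_mask(v, mask)
  v
}

# Row-major (row index major, column minor) index map of a full FOV.
full_index_map <- function(fov_shape) {
  cbind(row = rep(seq_len(fov_shape[1]), each = fov_shape[2]),
        col = rep(seq_len(fov_shape[2]), times = fov_shape[1]))
}

# Nx x Ny x T array -> N x T matrix, rows ordered row-major over (row, col).
flatten_frames <- function(arr) {
  d <- dim(arr)
  m <- matrix(aperm(arr, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  m
}

#' @export
print.video_matrix <- function(x, ...) {
  cat("<video_matrix> ", nrow(x$data), " pixels x ", ncol(x$data), " frames; FOV ",
      x$fov_shape[1], "x", x$fov_shape[2],
      if (!is.null(x$mask)) " (masked)" else "",
      if (!is.null(x$sketch)) sprintf(" [sketched %gx]", x$sketch$ratio) else "",
      "\n", sep = "")
  invisible(x)
}

#' Load a video from a multipage TIFF stack
#'
#' Frames are read along TIFF pages and flattened row-major into an `N x T`
#' matrix. A `pixels-by-time` layout reads a single-page TIFF directly as the
#' matrix (rows = pixels), in which case `fov_shape` must be supplied.
#'
#' @param path path to a `.tif`/`.tiff` file.
#' @param layout `"frames-stack"` (default) or `"pixels-by-time"`.
#' @param fov_shape required for `layout = "pixels-by-time"`.
#' @inheritParams video_matrix
#' @return A [video_matrix()].
#' @export
load_video <- function(path, layout = c("frames-stack", "pixels-by-time"),
                       fov_shape = NULL, frame_rate = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("inconsistent frame shapes in ", path)
  for (i in seq_along(pages)) {
    if (any(!is.finite(pages[[i]])))
      stop("non-finite values in frame ", i, " of ", path)
  }
  if (layout == "pixels-by-time") {
    if (length(pages) != 1) stop("pixels-by-time layout expects a single page")
    if (is.null(fov_shape)) stop("fov_shape required for pixels-by-time layout")
    return(video_matrix(pages[[1]], fov_shape = fov_shape, frame_rate = frame_rate))
  }
  arr <- array(unlist(pages), dim = c(shp[1], shp[2], length(pages)))
  video_matrix(arr, frame_rate = frame_rate)
}

#' Save a video as a 32-bit multipage TIFF
#'
#' Values must lie in `[0, 1]` (TIFF sample convention) and round-trip through
#' [load_video()] to 32-bit quantization precision (about 2e-10).
#'
#' @param video a [video_matrix()] (must be unmasked and unsketched).
#' @param path output path.
#' @export
save_video <- function(video, path) {
  stopifnot(inherits(video, "video_matrix"))
  if (!is.null(video$mask)) stop("cannot save a masked video as a dense stack")
  nx <- video$fov_shape[1]; ny <- video$fov_shape[2]
  frames <- lapply(seq_len(ncol(video$data)), function(t) {
    matrix(video$data[, t], nrow = nx, ncol = ny, byrow = TRUE)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Restrict a video to the pixels of a boolean mask
#'
#' Keeps only rows whose pixel falls inside the mask, preserving the original
#' row order, and updates `index_map` accordingly.
#'
#' @param video a [video_matrix()].
#' @param mask logical `Nx x Ny` matrix (or a numeric image; nonzero = TRUE).
#' @return The masked [video_matrix()].
#' @export
apply_mask <- function(video, mask) {
  stopifnot(inherits(video, "video_matrix"))
  if (is.numeric(mask)) mask <- mask != 0
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  if (!identical(dim(mask), as.integer(video$fov_shape)) &&
      !all(dim(mask) == video$fov_shape))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match FOV ", paste(video$fov_shape, collapse = "x"))
  keep <- mask[video$index_map]
  if (!any(keep)) stop("mask selects no pixels")
  video$data <- video$data[keep, , drop = FALSE]
  video$index_map <- video$index_map[keep, , drop = FALSE]
  video$mask <- if (is.null(video$mask)) mask else (video$mask & mask)
  video
}

#' Read a mask image (TIFF or PNG; nonzero pixels are TRUE)
#'
#' @param path path to a `.tif`/`.tiff`/`.png` image.
#' @return Logical matrix.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img != 0
}

#' Normalize traces to relative fluorescence change (dF/F)
#'
#' Each pixel trace `F` is replaced by `(F - mean(F)) / mean(F)`, so output
#' rows have mean zero. This normalization is opt-in: the learning pipeline
#' runs on whatever matrix it is given.
#'
#' @param video a [video_matrix()].
#' @param on_zero what to do with pixels whose time-mean is not strictly
#'   positive: `"error"` (default) or `"flag"` (trace set to 0 and the pixel
#'   index recorded in attribute `"flagged"`).
#' @return A [video_matrix()] with zero-mean rows.
#' @export
delta_f_over_f <- function(video, on_zero = c("error", "flag")) {
  stopifnot(inherits(video, "video_matrix"))
  on_zero <- match.arg(on_zero)
  mu <- rowMeans(video$data)
  bad <- which(mu <= 0)
  if (length(bad) && on_zero == "error")
    stop("pixels with non-positive time-mean: ", paste(head(bad, 5), collapse = ", "))
  out <- (video$data - mu) / ifelse(mu > 0, mu, 1)
  if (length(bad)) out[bad, ] <- 0
  video$data <- out
  attr(video, "flagged") <- bad
  video
}

#' Expand spatial coefficients into component images
#'
#' @param A `N x M` spatial coefficient matrix (or a `graft_result`, whose `A`
#'   is used), rows aligned with `video`'s pixels.
#' @param video the [video_matrix()] providing geometry; off-mask pixels are 0.
#' @return `Nx x Ny x M` array of component images.
#' @export
unflatten <- function(A, video) {
  if (inherits(A, "graft_result")) A <- A$A
  A <- as.matrix(A)
  stopifnot(inherits(video, "video_matrix"))
  if (nrow(A) != nrow(video$data))
    stop("A has ", nrow(A), " rows but video has ", nrow(video$data), " pixels")
  nx <- video$fov_shape[1]; ny <- video$fov_shape[2]
  out <- array(0, dim = c(nx, ny, ncol(A)))
  idx <- cbind(video$index_map[rep(seq_len(nrow(A)), ncol(A)), , drop = FALSE],
               rep(seq_len(ncol(A)), each = nrow(A)))
  out[idx] <- as.vector(A)
  out
}

#' Write component images as a multipage TIFF
#'
#' @param A spatial maps (`N x M` matrix or `graft_result`).
#' @param video geometry provider.
#' @param path output TIFF path; each component becomes one page, rescaled to
#'   its own maximum.
#' @export
save_component_images <- function(A, video, path) {
  imgs <- unflatten(A, video)
  pages <- lapply(seq_len(dim(imgs)[3]), function(m) {
    im <- imgs[, , m]
    mx <- max(im)
    if (mx > 0) im <- im / mx
    im
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
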