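#' Recurrence-plot configuration
#'
#' Parameters of the 1D-to-2D conversion: delay, norm, rendered image size,
#' colormap, and how a long segment is reduced to the matrix size.
#'
#' With the default path a z-scored segment is uniformly decimated to
#' `target_points` samples (default `size + tau`, so that a 10 s, 300 Hz
#' segment decimated to 300 samples embeds into a 299 x 299 matrix rendered
#' one-to-one). With `full_matrix = TRUE` the full distance matrix of the
#' undecimated segment is computed and then resized to `size` by
#' area-average interpolation.
#'
#' @param tau embedding delay in samples (default 1).
#' @param norm distance norm: `"euclidean"` (default), `"max"`,
#'   `"manhattan"`.
#' @param size rendered image side in pixels (default 299).
#' @param colormap `"viridis"` (default) or `"gray"`.
#' @param target_points decimation target before embedding; defaults to
#'   `size + tau`.
#' @param full_matrix compute the full matrix and resize instead of
#'   decimating first.
#' @param zscore z-score the segment before embedding.
#' @return a list of class `rp_config`.
#' @export
rp_config <- function(tau = 1L, norm = c("euclidean", "max", "manhattan"),
                      size = 299L, colormap = c("viridis", "gray"),
                      target_points = NULL, full_matrix = FALSE,
                      zscore = TRUE) {
  norm <- match.arg(norm)
  colormap <- match.arg(colormap)
  stopifnot(tau >= 1, size >= 2)
  if (is.null(target_points)) target_points <- size + tau
  structure(list(tau = as.integer(tau), norm = norm, size = as.integer(size),
                 colormap = colormap,
                 target_points = as.integer(target_points),
                 full_matrix = isTRUE(full_matrix), zscore = isTRUE(zscore)),
            class = "rp_config")
}

#' Takens delay embedding into a 2D phase space
#'
#' Pairs each sample with its lagged copy: point `t` is
#' `(X_t, X_{t - tau})` for `t = tau + 1, ..., N`, giving `N - tau`
#' trajectory points in the reconstructed 2D phase space.
#'
#' @param x numeric vector of length `> tau`.
#' @param tau delay in samples (default 1).
#' @return object of class `trajectory`: list with `points`
#'   (`(N - tau) x 2` matrix, columns `x`, `y`) and `tau`.
#' @export
#' @examples
#' takens_embed(c(1, 2, 3, 4))$points
takens_embed <- function(x, tau = 1L) {
  tau <- as.integer(tau)
  n <- length(x)
  if (tau < 1) stop("tau must be >= 1")
  if (n <= tau) stop("series must be longer than tau")
  pts <- cbind(x = x[(tau + 1):n], y = x[1:(n - tau)])
  structure(list(points = pts, tau = tau), class = "trajectory")
}

rp_dist <- function(points, norm) {
  method <- switch(norm, euclidean = "euclidean", max = "maximum",
                   manhattan = "manhattan",
                   stop("unknown norm: ", norm))
  as.matrix(stats::dist(points, method = method))
}

#' Un-thresholded recurrence matrix
#'
#' Pairwise phase-space distances `R[i, j] = ||S_i - S_j||` without
#' Heaviside binarization, retaining the full distance information that a
#' thresholded plot discards; this is the representation rendered to RGB
#' for the classifier.
#'
#' @param traj a [takens_embed()] trajectory.
#' @param norm distance norm (see [rp_config()]).
#' @return object of class `recurrence_matrix` with fields `values`
#'   (square symmetric matrix, zero diagonal), `mode = "unthresholded"`,
#'   `norm`.
#' @export
unthresholded_rp <- function(traj, norm = "euclidean") {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj$points) < 2) stop("trajectory must contain at least 2 points")
  d <- rp_dist(traj$points, norm)
  dimnames(d) <- NULL
  structure(list(values = d, mode = "unthresholded", epsilon = NULL,
                 norm = norm),
            class = "recurrence_matrix")
}

#' Thresholded (binary) recurrence matrix
#'
#' Heaviside-thresholded recurrences:
#' `R[i, j] = 1` iff `||S_i - S_j|| <= epsilon`, with the boundary case
#' `||.|| == epsilon` counted as recurrent (the Heaviside step maps 0 to
#' 1). The diagonal is therefore all ones for any `epsilon >= 0`.
#'
#' @param traj a [takens_embed()] trajectory.
#' @param epsilon non-negative threshold distance.
#' @param norm distance norm (see [rp_config()]).
#' @return object of class `recurrence_matrix` with binary `values`,
#'   `mode = "thresholded"` and the `epsilon` used.
#' @export
thresholded_rp <- function(traj, epsilon, norm = "euclidean") {
  if (epsilon < 0) stop("epsilon must be >= 0")
  r <- unthresholded_rp(traj, norm)
  r$values <- (r$values <= epsilon) + 0
  r$mode <- "thresholded"
  r$epsilon <- epsilon
  r
}

# area-average (box) resampling weights mapping n source cells to m targets
area_weights <- function(n, m) {
  w <- matrix(0, m, n)
  scale <- n / m
  for (i in seq_len(m)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1
    j1 <- min(ceiling(hi), n)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) w[i, j] <- ov
    }
    w[i, ] <- w[i, ] / scale
  }
  w
}

resize_area <- function(m, size) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  wr <- area_weights(nrow(m), size)
  wc <- area_weights(ncol(m), size)
  wr %*% m %*% t(wc)
}

colormap_lut <- function(colormap, n = 256L) {
  cols <- switch(colormap,
                 viridis = grDevices::hcl.colors(n, "Viridis"),
                 gray = grDevices::gray(seq(0, 1, length.out = n)),
                 stop("unknown colormap: ", colormap))
  t(grDevices::col2rgb(cols) / 255)
}

#' Render a recurrence matrix as a square RGB image
#'
#' The matrix is min-max normalized to `[0, 1]` (a zero-range matrix maps
#' to all zeros), resized to `size x size` by area-average interpolation,
#' and passed through the colormap to produce three channels. Because of
#' the min-max normalization the rendering is invariant to positive
#' rescaling of the matrix.
#'
#' @param r a `recurrence_matrix` (or plain numeric matrix).
#' @param size output side length in pixels (default 299).
#' @param colormap `"viridis"` (default) or `"gray"`.
#' @return object of class `rp_image`: list with `pixels`
#'   (`size x size x 3` array in `[0, 1]`), `size`, `colormap`.
#' @export
render_rp_image <- function(r, size = 299L, colormap = "viridis") {
  m <- if (inherits(r, "recurrence_matrix")) r$values else as.matrix(r)
  if (!length(m)) stop("empty recurrence matrix")
  if (size < 2) stop("size must be >= 2")
  rng <- range(m)
  m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  m <- resize_area(m, size)
  m[m < 0] <- 0
  m[m > 1] <- 1
  lut <- colormap_lut(colormap)
  idx <- matrix(1L + as.integer(round(m * (nrow(lut) - 1))), nrow(m), ncol(m))
  pix <- array(0, c(size, size, 3))
  for (ch in 1:3) pix[, , ch] <- matrix(lut[idx, ch], size, size)
  structure(list(pixels = pix, size = as.integer(size), colormap = colormap),
            class = "rp_image")
}

# uniform anti-aliased decimation to n_out samples: each output sample is
# the mean of one of n_out equal-length windows (area average), so narrow
# transients such as QRS spikes contribute their energy to the decimated
# trace instead of being hit-or-miss subsampled
decimate_uniform <- function(x, n_out) {
  if (length(x) <= n_out) return(x)
  as.vector(area_weights(length(x), n_out) %*% x)
}

#' Convert a prepared 1D ECG segment into a recurrence-plot image
#'
#' Composition of the full 1D-to-2D path: optional z-score, reduction to
#' matrix scale (uniform decimation by default, full matrix plus
#' area-average resize when `cfg$full_matrix`), Takens embedding,
#' un-thresholded recurrence matrix, RGB rendering. Deterministic.
#'
#' @param x numeric vector (a prepared lead segment) or a `lead_segment`.
#' @param fs sampling rate in Hz (unused for the default decimation path,
#'   kept for provenance; taken from `x` when it is a `lead_segment`).
#' @param cfg an [rp_config()].
#' @return an `rp_image`.
#' @export
ecg_to_rp <- function(x, fs = NULL, cfg = rp_config()) {
  if (inherits(x, "lead_segment")) {
    fs <- x$fs
    x <- x$samples
  }
  if (cfg$zscore) x <- zscore(x)
  if (!cfg$full_matrix) x <- decimate_uniform(x, cfg$target_points)
  r <- unthresholded_rp(takens_embed(x, cfg$tau), cfg$norm)
  render_rp_image(r, cfg$size, cfg$colormap)
}

#' Write a recurrence-plot image to a PNG file
#'
#' @param img an `rp_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rp_png <- function(img, path) {
  stopifnot(inherits(img, "rp_image"))
  png::writePNG(img$pixels, path)
  invisible(path)
}
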