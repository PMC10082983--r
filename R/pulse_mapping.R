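#' A time-ordered stack of fundus video frames
#'
#' @param frames Numeric array `T x H x W`: `T` frames of `H x W`
#'   green-channel intensities. Color input should be reduced to the green
#'   channel before construction (see [read_stack()], which does this).
#' @param fps Frame rate in frames per second.
#' @param origin Frame index of the first analyzed frame in the source video
#'   (0-based, informational).
#' @return An object of class `frame_stack`.
#' @examples
#' frame_stack(array(rnorm(10 * 4 * 5), c(10, 4, 5)), fps = 120)
#' @export
frame_stack <- function(frames, fps, origin = 0L) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L)
    stop("frames must be a T x H x W array")
  if (dim(frames)[1L] < 8L)
    stop("need at least 8 frames")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  structure(list(frames = frames * 1.0, fps = as.numeric(fps),
                 origin = as.integer(origin)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("<frame_stack> ", d[1L], " frames of ", d[2L], " x ", d[3L],
      " px at ", x$fps, " FPS\n", sep = "")
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Extract one pixel's intensity series
#'
#' Pulls the intensity time series of a pixel (optionally the mean over a
#' `k x k` neighborhood) and pairs it with the cycle-fraction time grid.
#' Pixel coordinates are 1-based `(row, col)` with row 1 at the image top,
#' as in R matrix indexing.
#'
#' @param stack A `frame_stack`.
#' @param pixel Length-2 integer vector `(row, col)`.
#' @param timing Optional [cardiac_timing()]; when supplied, the returned
#'   series carries the cycle-fraction times of its frames.
#' @param k Odd neighborhood size for spatial averaging (default 1 = none).
#' @return A list with elements `y` (intensities) and `t` (cycle-fraction
#'   times, or `NULL` when no timing is given).
#' @examples
#' st <- frame_stack(array(1, c(10, 4, 5)), fps = 120)
#' extract_green_series(st, c(2, 3))$y
#' @export
extract_green_series <- function(stack, pixel, timing = NULL, k = 1L) {
  d <- dim(stack$frames)
  r <- pixel[1L]; cc <- pixel[2L]
  if (r < 1L || r > d[2L] || cc < 1L || cc > d[3L])
    stop("pixel (", r, ", ", cc, ") out of bounds for ", d[2L], " x ", d[3L],
         " frames")
  if (k %% 2L != 1L || k < 1L) stop("k must be a positive odd integer")
  h <- (k - 1L) %/% 2L
  rows <- max(1L, r - h):min(d[2L], r + h)
  cols <- max(1L, cc - h):min(d[3L], cc + h)
  block <- stack$frames[, rows, cols, drop = FALSE]
  y <- apply(block, 1L, mean)
  t <- NULL
  if (!is.null(timing)) {
    grid <- build_time_grid(timing)
    if (nrow(grid) != d[1L])
      stop("timing covers ", nrow(grid), " frames but the stack has ", d[1L])
    t <- grid$t
  }
  list(y = y, t = t)
}

#' Fit the harmonic regression to every pixel of a stack
#'
#' Applies [fit_harmonic_regression()] independently to each pixel series
#' (no spatial smoothing) and collects the per-pixel harmonic regression wave
#' amplitude (HRWa) and time-to-trough into maps. Per-pixel failures are
#' recorded in the `qc` mask instead of aborting the run; degenerate
#' (constant) pixels get amplitude 0 and a missing trough.
#'
#' @param stack A `frame_stack`.
#' @param timing A [cardiac_timing()] covering the stack's frames.
#' @param order Harmonic order K (default 2, the order preferred by AIC for
#'   retinal pulse series).
#' @param roi Optional logical `H x W` matrix; pixels outside the region of
#'   interest are skipped (their map entries stay `NA`).
#' @param knots,basis Passed to [build_design_matrix()].
#' @param neighborhood Odd `k` for a k x k neighborhood-mean pre-filter
#'   (default 1, i.e. off).
#' @return An object of class `pulse_maps`: a list with `H x W` matrices
#'   `amplitude` (HRWa, >= 0), `trough` (cycle fractions in `[0, 1)`, `NA`
#'   where undefined) and `qc` (0 = ok, 1 = degenerate/zero-amplitude,
#'   2 = non-convergence, `NA` = outside roi), plus `fps` and `order`.
#' @examples
#' sim <- simulate_stack(simulation_config(width = 16, height = 10,
#'   frames_per_cycle = c(12, 12), sigma_u = 0, drift = c(0, 0, 0)))
#' maps <- fit_stack(sim$stack, sim$timing)
#' range(maps$amplitude)
#' @export
fit_stack <- function(stack, timing, order = 2L, roi = NULL, knots = NULL,
                      basis = "2pi", neighborhood = 1L) {
  d <- dim(stack$frames)
  grid <- build_time_grid(timing)
  if (nrow(grid) != d[1L])
    stop("timing covers ", nrow(grid), " frames but the stack has ", d[1L])
  H <- d[2L]; W <- d[3L]
  if (is.null(roi)) roi <- matrix(TRUE, H, W)
  if (!identical(dim(roi), c(H, W))) stop("roi must be an H x W logical matrix")

  X <- build_design_matrix(grid$t, order = order, knots = knots, basis = basis)
  amplitude <- matrix(NA_real_, H, W)
  trough <- matrix(NA_real_, H, W)
  qc <- matrix(NA_integer_, H, W)

  idx <- which(roi)
  if (length(idx)) {
    Y <- matrix(NA_real_, d[1L], length(idx))
    for (j in seq_along(idx)) {
      r <- (idx[j] - 1L) %% H + 1L
      cc <- (idx[j] - 1L) %/% H + 1L
      Y[, j] <- if (neighborhood > 1L)
        extract_green_series(stack, c(r, cc), k = neighborhood)$y
      else stack$frames[, r, cc]
    }
    # coarse rho grid shared across pixels; refinement is per-pixel
    rho_init <- grid_rho_matrix(Y, X)
    for (j in seq_along(idx)) {
      init <- rho_init[j]
      fit <- fit_harmonic_design(Y[, j], X,
                                 grid_init = if (is.na(init)) NULL else init)
      amplitude[idx[j]] <- fit$hrw_amplitude
      trough[idx[j]] <- fit$time_to_trough
      qcj <- switch(fit$status, ok = 0L, exact = 0L, degenerate = 1L, 2L)
      if (fit$hrw_amplitude == 0) qcj <- max(qcj, 1L)
      qc[idx[j]] <- qcj
    }
  }
  structure(list(amplitude = amplitude, trough = trough, qc = qc,
                 fps = stack$fps, order = as.integer(order)),
            class = "pulse_maps")
}

#' @export
print.pulse_maps <- function(x, ...) {
  cat("<pulse_maps> ", nrow(x$amplitude), " x ", ncol(x$amplitude),
      " px, order ", x$order, "\n", sep = "")
  ok <- sum(x$qc == 0L, na.rm = TRUE)
  cat("  fitted pixels:", sum(!is.na(x$qc)), " (ok:", ok, ")\n")
  invisible(x)
}

#' Sample pulse maps at measurement points
#'
#' Reads amplitude and trough values at a set of pixel locations (for
#' example the nasal, central and temporal venous-wall points of a
#' measurement site). Troughs at pixels with a nonzero `qc` flag are returned
#' as missing.
#'
#' @param maps A `pulse_maps` object.
#' @param points Matrix or data frame with two columns `(row, col)`, 1-based.
#' @return A data frame with columns `row`, `col`, `amplitude`, `trough`,
#'   `qc`.
#' @export
sample_map <- function(maps, points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have two columns (row, col)")
  H <- nrow(maps$amplitude); W <- ncol(maps$amplitude)
  if (any(points[, 1L] < 1L | points[, 1L] > H |
          points[, 2L] < 1L | points[, 2L] > W))
    stop("point out of bounds for ", H, " x ", W, " maps")
  idx <- cbind(points[, 1L], points[, 2L])
  qc <- maps$qc[idx]
  trough <- maps$trough[idx]
  trough[!is.na(qc) & qc != 0L] <- NA_real_
  data.frame(row = points[, 1L], col = points[, 2L],
             amplitude = maps$amplitude[idx], trough = trough, qc = qc)
}
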