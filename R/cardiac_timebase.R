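#' Cardiac-cycle timing for a frame sequence
#'
#' Bundles the cycle boundary frame indices and the mean cardiac cycle
#' duration that together map video frames onto a cycle-fraction time axis.
#' Cycle boundaries are typically derived upstream from the pulse-oximetry
#' audio track synchronized with the video.
#'
#' @param cycle_boundaries Integer vector of frame indices in the source video
#'   (0-based, as video frames are usually numbered) marking the start of each
#'   cardiac cycle. The last element is one past the final analyzed frame, so
#'   `length(cycle_boundaries) == n_cycles + 1` and cycle `c` spans frames
#'   `cycle_boundaries[c]` to `cycle_boundaries[c + 1] - 1`.
#' @param cycle_time_s Mean cardiac cycle duration in seconds.
#'
#' @return An object of class `cardiac_timing`: a list with elements
#'   `cycle_boundaries`, `cycle_time_s`, `n_cycles`, and `frames_per_cycle`.
#' @examples
#' cardiac_timing(c(0, 102, 204, 307), 0.852743)
#' @export
cardiac_timing <- function(cycle_boundaries, cycle_time_s) {
  cycle_boundaries <- as.integer(cycle_boundaries)
  if (length(cycle_boundaries) < 2L)
    stop("at least two cycle boundaries (one complete cycle) are required")
  if (any(diff(cycle_boundaries) <= 0L))
    stop("cycle_boundaries must be strictly increasing")
  if (!is.numeric(cycle_time_s) || length(cycle_time_s) != 1L || cycle_time_s <= 0)
    stop("cycle_time_s must be a single positive number of seconds")
  structure(
    list(
      cycle_boundaries = cycle_boundaries,
      cycle_time_s = as.numeric(cycle_time_s),
      n_cycles = length(cycle_boundaries) - 1L,
      frames_per_cycle = diff(cycle_boundaries)
    ),
    class = "cardiac_timing"
  )
}

#' @export
print.cardiac_timing <- function(x, ...) {
  cat("<cardiac_timing> ", x$n_cycles, " cycle(s), ",
      sum(x$frames_per_cycle), " frames, cycle time ",
      format(x$cycle_time_s), " s\n", sep = "")
  cat("  frames per cycle:", paste(x$frames_per_cycle, collapse = ", "), "\n")
  invisible(x)
}

#' Nominal cycle-fraction time of a frame
#'
#' The nominal time of frame `i` (1-based within its cycle) in cycle `c`
#' containing `n_c` frames is `i / n_c + c - 1`, so time is measured in
#' fractions of the cardiac cycle and the last frame of cycle `c` lands
#' exactly at `t = c`. Per-cycle normalization absorbs heart-rate variability
#' across cycles.
#'
#' @param i Frame index within the cycle, `1 <= i <= n_c`. Vectorized.
#' @param c Cycle index (1-based). Vectorized.
#' @param n_c Number of frames in cycle `c`. Vectorized.
#' @return Nominal time in cardiac-cycle fractions, in `(c - 1, c]`.
#' @examples
#' nominal_frame_time(102, 1, 102)  # 1.0
#' nominal_frame_time(51, 2, 102)   # 1.5
#' @export
nominal_frame_time <- function(i, c, n_c) {
  if (any(n_c <= 0L)) stop("n_c must be positive")
  if (any(c < 1L)) stop("cycle index c must be >= 1")
  if (any(i < 1L) || any(i > n_c)) stop("frame index i out of range 1..n_c")
  i / n_c + c - 1
}

#' Cycle-fraction time grid for all analyzed frames
#'
#' Applies [nominal_frame_time()] to every frame covered by a
#' [cardiac_timing()] object, yielding the time axis used by the harmonic
#' regression.
#'
#' @param timing A `cardiac_timing` object.
#' @return A data frame with one row per analyzed frame and columns `frame`
#'   (original 0-based video frame index), `cycle` (1-based cycle label), `i`
#'   (1-based index within the cycle), and `t` (cycle-fraction time, strictly
#'   increasing, ending exactly at `n_cycles`).
#' @examples
#' build_time_grid(cardiac_timing(c(0, 4, 8), 0.85))$t
#' @export
build_time_grid <- function(timing) {
  if (!inherits(timing, "cardiac_timing"))
    timing <- cardiac_timing(timing$cycle_boundaries, timing$cycle_time_s)
  b <- timing$cycle_boundaries
  cyc <- rep.int(seq_len(timing$n_cycles), timing$frames_per_cycle)
  i <- sequence(timing$frames_per_cycle)
  n_c <- rep.int(timing$frames_per_cycle, timing$frames_per_cycle)
  data.frame(
    frame = seq.int(b[1L], b[length(b)] - 1L),
    cycle = cyc,
    i = i,
    t = nominal_frame_time(i, cyc, n_c)
  )
}

#' Convert cycle-fraction time to seconds
#'
#' @param t_cycles Time in cardiac-cycle fractions.
#' @param cycle_time_s Cardiac cycle duration in seconds.
#' @return `t_cycles * cycle_time_s`, in seconds.
#' @examples
#' cycles_to_seconds(0.4, 0.852743)
#' @export
cycles_to_seconds <- function(t_cycles, cycle_time_s) {
  if (!is.numeric(cycle_time_s) || cycle_time_s <= 0)
    stop("cycle_time_s must be positive")
  t_cycles * cycle_time_s
}

#' Duration of a single video frame
#'
#' @param fps Frame rate in frames per second.
#' @param round_6dp Report-mode rounding: round the period to six decimal
#'   places, matching the convention of quoting all derived quantities to six
#'   decimal places (e.g. 1/120 becomes 0.008333 s).
#' @return Frame period in seconds.
#' @examples
#' frame_period(120, round_6dp = TRUE)  # 0.008333
#' frame_period(25, round_6dp = TRUE)   # 0.04
#' @export
frame_period <- function(fps, round_6dp = FALSE) {
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  p <- 1 / fps
  if (isTRUE(round_6dp)) round(p, 6L) else p
}
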