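#' Spatial calibration from a reference of known size
#'
#' Retinal images carry no absolute scale; the customary reference is the
#' optic disc, assumed to measure 1.65 mm along its vertical diameter.
#'
#' @param reference_px Measured pixel length of the reference.
#' @param reference_mm Physical length of the reference in mm (default 1.65,
#'   the assumed optic-disc diameter).
#' @return An object of class `spatial_calibration` with `mm_per_pixel`,
#'   `reference_mm`, `reference_px`.
#' @examples
#' calibrate(165)$mm_per_pixel  # 0.01
#' @export
calibrate <- function(reference_px, reference_mm = 1.65) {
  if (!is.numeric(reference_px) || reference_px <= 0)
    stop("reference_px must be positive")
  if (!is.numeric(reference_mm) || reference_mm <= 0)
    stop("reference_mm must be positive")
  structure(list(mm_per_pixel = reference_mm / reference_px,
                 reference_mm = reference_mm,
                 reference_px = reference_px),
            class = "spatial_calibration")
}

as_mm_per_pixel <- function(calib) {
  if (inherits(calib, "spatial_calibration")) return(calib$mm_per_pixel)
  if (is.numeric(calib) && length(calib) == 1L && calib > 0) return(calib)
  stop("calib must be a spatial_calibration object or a positive scale")
}

#' Geodesic length of a vessel path
#'
#' Arc length of a polyline traced along the vessel (pixel centers), in
#' calibrated millimetres: the sum of Euclidean segment lengths times the
#' mm-per-pixel scale.
#'
#' @param path Matrix or data frame of ordered `(row, col)` pixel
#'   coordinates, at least two points.
#' @param calib A [calibrate()] result, or a bare mm-per-pixel scale.
#' @return Path length in mm.
#' @examples
#' geodesic_length(rbind(c(0, 0), c(3, 4)), 0.01)  # 0.05
#' @export
geodesic_length <- function(path, calib) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop("path needs at least 2 points")
  seg <- diff(path)
  len <- sum(sqrt(rowSums(seg^2)))
  if (any(sqrt(rowSums(seg^2)) == 0))
    stop("consecutive path points must be distinct")
  len * as_mm_per_pixel(calib)
}

#' Mean site trough time in seconds
#'
#' Converts the per-point trough times of one measurement site (nasal,
#' central and temporal venous-wall points) from cycle fractions to seconds
#' and averages them.
#'
#' @param trough_cycles Trough times in cycle fractions (typically three).
#' @param cycle_time_s Cardiac cycle duration in seconds.
#' @param require_all If `TRUE` (default) any missing trough makes the site
#'   time missing, with a warning; if `FALSE` the mean is over the available
#'   points.
#' @return Site mean trough time in seconds.
#' @examples
#' site_time_seconds(c(0.4, 0.4, 0.4), 0.852743)  # 0.3410972
#' @export
site_time_seconds <- function(trough_cycles, cycle_time_s,
                              require_all = TRUE) {
  if (!is.numeric(cycle_time_s) || cycle_time_s <= 0)
    stop("cycle_time_s must be positive")
  if (anyNA(trough_cycles)) {
    if (require_all) {
      warning("missing trough value(s) at site; site time is NA")
      return(NA_real_)
    }
    trough_cycles <- trough_cycles[!is.na(trough_cycles)]
    if (!length(trough_cycles)) return(NA_real_)
  }
  mean(cycles_to_seconds(trough_cycles, cycle_time_s))
}

#' Pulse transit time between two sites
#'
#' Distal-minus-proximal difference of site trough times. A zero or negative
#' result indicates a non-physical propagation direction and is returned with
#' a warning (attribute `direction_warning`), not dropped. When both times sit
#' near opposite ends of the cycle, the cross-cycle wrap can be resolved by
#' supplying `cycle_time_s` and `wrap = TRUE`, which takes the difference
#' modulo one cycle using the representative in `(-cycle/2, cycle/2]`.
#'
#' @param t_a_s Proximal site trough time, seconds.
#' @param t_b_s Distal site trough time, seconds.
#' @param cycle_time_s Cycle duration, required when `wrap = TRUE`.
#' @param wrap Resolve cycle-boundary wrap-around (default off; the
#'   within-cycle case needs none).
#' @return Transit time in seconds.
#' @examples
#' transit_time(0.334377, 0.349660)  # 0.015283
#' @export
transit_time <- function(t_a_s, t_b_s, cycle_time_s = NULL, wrap = FALSE) {
  d <- t_b_s - t_a_s
  if (isTRUE(wrap)) {
    if (is.null(cycle_time_s) || cycle_time_s <= 0)
      stop("wrap = TRUE requires a positive cycle_time_s")
    d <- d %% cycle_time_s
    if (isTRUE(d > cycle_time_s / 2)) d <- d - cycle_time_s
  }
  if (isTRUE(d <= 0)) {
    warning("non-positive transit time: pulse appears to travel distal ",
            "to proximal; check the propagation direction")
    attr(d, "direction_warning") <- TRUE
  }
  d
}

#' Pulse wave velocity
#'
#' Distance along the vessel divided by the pulse transit time.
#'
#' @param distance_mm Geodesic vessel distance between the sites, mm.
#' @param transit_s Pulse transit time, seconds (> 0).
#' @param round_6dp Report-mode rounding to six decimal places.
#' @return Velocity in mm/s.
#' @examples
#' pulse_wave_velocity(0.34, 0.015283)  # ~22.24694
#' @export
pulse_wave_velocity <- function(distance_mm, transit_s, round_6dp = FALSE) {
  if (!is.numeric(transit_s) || is.na(transit_s) || transit_s <= 0)
    stop("transit_s must be positive; velocity is undefined otherwise")
  if (distance_mm < 0) stop("distance_mm must be nonnegative")
  v <- distance_mm / transit_s
  if (isTRUE(round_6dp)) round(v, 6L) else v
}

#' Temporal and velocity resolution limits of an imaging setup
#'
#' The frame period sets the minimum resolvable time scale; the largest
#' vessel span visible in the field divided by that period bounds the fastest
#' measurable pulse wave velocity.
#'
#' @param fps Frame rate in frames per second.
#' @param window_mm Spatial window (maximum measurable vessel span), mm.
#' @param round_6dp Use the six-decimal frame period in the ratio, matching
#'   report-mode arithmetic.
#' @return A list with `min_time_s` and `max_velocity_mm_s`.
#' @examples
#' resolution_limits(120, 1.197, round_6dp = TRUE)
#' resolution_limits(25, 4.5)
#' @export
resolution_limits <- function(fps, window_mm, round_6dp = FALSE) {
  if (!is.numeric(window_mm) || window_mm <= 0)
    stop("window_mm must be positive")
  p <- frame_period(fps, round_6dp = round_6dp)
  list(min_time_s = p, max_velocity_mm_s = window_mm / p)
}

#' Duration of an event observed between two frames
#'
#' @param frame_start,frame_end Frame indices bounding the event
#'   (`frame_end > frame_start`).
#' @param fps Frame rate in frames per second.
#' @param round_6dp Multiply by the six-decimal frame period (report mode).
#' @return A list with `frame_count` and `seconds`.
#' @examples
#' event_duration(221, 272, 120, round_6dp = TRUE)  # 51 frames, 0.424983 s
#' @export
event_duration <- function(frame_start, frame_end, fps, round_6dp = FALSE) {
  if (frame_end <= frame_start)
    stop("frame_end must exceed frame_start")
  n <- frame_end - frame_start
  list(frame_count = n, seconds = n * frame_period(fps, round_6dp = round_6dp))
}

#' Estimate pulse wave velocity from fitted maps
#'
#' End-to-end velocimetry: samples the time-to-trough map at the proximal and
#' distal measurement sites (three venous-wall points each), averages each
#' site and converts to seconds, takes the distal-minus-proximal transit time
#' (with cross-cycle wrap resolution), measures the geodesic path length, and
#' divides.
#'
#' @param maps A [fit_stack()] result.
#' @param sites List with elements `site_a` (proximal) and `site_b` (distal),
#'   each a matrix of `(row, col)` points.
#' @param path Vessel-path polyline between the sites, `(row, col)` pixel
#'   coordinates.
#' @param calib A [calibrate()] result or mm-per-pixel scale.
#' @param cycle_time_s Cardiac cycle duration in seconds.
#' @param require_all Passed to [site_time_seconds()].
#' @param round_6dp Report-mode rounding of the velocity.
#' @return An object of class `pwv_result`: list with `t_a_s`, `t_b_s`,
#'   `transit_s`, `distance_mm`, `pwv_mm_s`, and the per-point site samples.
#' @export
estimate_pwv <- function(maps, sites, path, calib, cycle_time_s,
                         require_all = TRUE, round_6dp = FALSE) {
  sa <- sample_map(maps, sites$site_a)
  sb <- sample_map(maps, sites$site_b)
  # align the two sites' troughs on a common cycle branch before averaging:
  # a site straddling t = 0 would otherwise average to mid-cycle
  ta_cyc <- unwrap_to_reference(sa$trough)
  tb_cyc <- unwrap_to_reference(sb$trough)
  t_a_s <- site_time_seconds(ta_cyc, cycle_time_s, require_all = require_all)
  t_b_s <- site_time_seconds(tb_cyc, cycle_time_s, require_all = require_all)
  transit_s <- if (is.na(t_a_s) || is.na(t_b_s)) NA_real_ else
    transit_time(t_a_s, t_b_s, cycle_time_s = cycle_time_s, wrap = TRUE)
  distance_mm <- geodesic_length(path, calib)
  pwv <- if (is.na(transit_s) || transit_s <= 0) NA_real_ else
    pulse_wave_velocity(distance_mm, transit_s, round_6dp = round_6dp)
  structure(list(t_a_s = t_a_s, t_b_s = t_b_s, transit_s = transit_s,
                 distance_mm = distance_mm, pwv_mm_s = pwv,
                 site_a = sa, site_b = sb),
            class = "pwv_result")
}

# Shift trough fractions onto the branch nearest the first finite value
# (representative within +/- 0.5 cycle), so averaging across a site is safe
# when points straddle the cycle boundary.
unwrap_to_reference <- function(x) {
  ref <- x[is.finite(x)][1L]
  if (is.na(ref)) return(x)
  ref + vapply(x - ref, function(d) {
    if (is.na(d)) return(NA_real_)
    d <- d %% 1
    if (d > 0.5) d - 1 else d
  }, numeric(1L))
}

#' @export
print.pwv_result <- function(x, ...) {
  cat("<pwv_result>\n")
  cat("  T_a =", format(x$t_a_s), "s   T_b =", format(x$t_b_s), "s\n")
  cat("  transit =", format(x$transit_s), "s over",
      format(x$distance_mm), "mm\n")
  cat("  PWV =", format(x$pwv_mm_s), "mm/s\n")
  invisible(x)
}
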