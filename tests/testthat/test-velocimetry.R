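test_that("spatial calibration divides the reference length by its pixels", {
  expect_equal(calibrate(165)$mm_per_pixel, 0.01)
  expect_equal(calibrate(330)$mm_per_pixel, 0.005)
  expect_equal(calibrate(100, 1.0)$mm_per_pixel, 0.01)
  expect_error(calibrate(0), "positive")
  expect_error(calibrate(100, -1), "positive")
})

test_that("geodesic length sums calibrated segment lengths", {
  expect_equal(geodesic_length(rbind(c(0, 0), c(3, 4)), 0.01), 0.05)
  expect_equal(geodesic_length(rbind(c(0, 0), c(0, 10), c(10, 10)), 0.01), 0.2)
  p <- rbind(c(1, 2), c(4, 6), c(10, 3))
  expect_equal(geodesic_length(p, calibrate(165)),
               geodesic_length(p[3:1, ], calibrate(165)))
  expect_error(geodesic_length(rbind(c(0, 0)), 0.01), "at least 2")
})

test_that("site trough times average in seconds", {
  expect_equal(site_time_seconds(c(0.4, 0.4, 0.4), 0.852743), 0.3410972)
  expect_equal(site_time_seconds(c(0, 0, 0), 0.852743), 0)
  expect_equal(site_time_seconds(c(0.3, 0.4, 0.5), 1), 0.4)
  expect_warning(out <- site_time_seconds(c(0.3, NA, 0.5), 1), "missing")
  expect_true(is.na(out))
  expect_equal(site_time_seconds(c(0.3, NA, 0.5), 1, require_all = FALSE), 0.4)
})

test_that("transit time is distal minus proximal and antisymmetric", {
  expect_equal(transit_time(0.334377, 0.349660), 0.015283)
  expect_equal(suppressWarnings(transit_time(0.2, 0.2)), 0,
               ignore_attr = TRUE)
  expect_warning(back <- transit_time(0.349660, 0.334377), "direction")
  expect_equal(as.numeric(back), -0.015283)
  expect_true(attr(back, "direction_warning"))
  # cross-cycle wrap picks the representative in (-cycle/2, cycle/2]
  expect_equal(transit_time(0.98, 0.02, cycle_time_s = 1, wrap = TRUE), 0.04)
  w <- suppressWarnings(
    transit_time(0.02, 0.98, cycle_time_s = 1, wrap = TRUE))
  expect_equal(as.numeric(w), -0.04)
})

test_that("pulse wave velocity reproduces the worked arithmetic", {
  expect_equal(round(pulse_wave_velocity(0.34, 0.015283), 5), 22.24694)
  expect_equal(pulse_wave_velocity(0, 0.015283), 0)
  expect_equal(round(pulse_wave_velocity(1.197, 0.008333), 3), 143.646)
  expect_error(pulse_wave_velocity(0.34, 0), "positive")
  # linear in the distance scale, inverse in transit
  expect_equal(pulse_wave_velocity(geodesic_length(rbind(c(0, 0), c(0, 10)),
                                                   0.02), 0.01),
               2 * pulse_wave_velocity(geodesic_length(rbind(c(0, 0), c(0, 10)),
                                                       0.01), 0.01))
  expect_equal(pulse_wave_velocity(0.34, 0.02),
               pulse_wave_velocity(0.34, 0.01) / 2)
})

test_that("resolution limits match the frame period and spatial window", {
  lim <- resolution_limits(120, 1.197, round_6dp = TRUE)
  expect_equal(lim$min_time_s, 0.008333)
  expect_equal(round(lim$max_velocity_mm_s, 3), 143.646)
  lim25 <- resolution_limits(25, 4.5, round_6dp = TRUE)
  expect_equal(lim25$min_time_s, 0.04)
  expect_equal(lim25$max_velocity_mm_s, 112.5)
  expect_equal(resolution_limits(25, 9.5, round_6dp = TRUE)$max_velocity_mm_s,
               237.5)
  expect_equal(resolution_limits(25, 0.610, round_6dp = TRUE)$max_velocity_mm_s,
               15.25)
  expect_error(resolution_limits(25, 0), "positive")
})

test_that("event durations count frames times the frame period", {
  ev <- event_duration(221, 272, 120, round_6dp = TRUE)
  expect_equal(ev$frame_count, 51)
  expect_equal(ev$seconds, 0.424983)
  ev2 <- event_duration(0, 120, 120)
  expect_equal(ev2$seconds, 1)
  expect_equal(event_duration(10, 11, 120)$seconds, 1 / 120)
  expect_error(event_duration(272, 221, 120), "exceed")
})

test_that("end-to-end velocimetry over fitted maps matches hand arithmetic", {
  maps <- structure(list(
    amplitude = matrix(1, 3, 40),
    trough = matrix(rep(seq(0.39, by = 0.001, length.out = 40), each = 3),
                    3, 40),
    qc = matrix(0L, 3, 40), fps = 120, order = 2L), class = "pulse_maps")
  sites <- list(site_a = cbind(1:3, 5), site_b = cbind(1:3, 35))
  path <- rbind(c(2, 5), c(2, 35))
  res <- estimate_pwv(maps, sites, path, 0.02, cycle_time_s = 0.852743)
  expect_equal(res$distance_mm, 0.6)
  expect_equal(res$t_a_s, cycles_to_seconds(0.394, 0.852743))
  expect_equal(res$transit_s, cycles_to_seconds(0.03, 0.852743))
  expect_equal(res$pwv_mm_s, 0.6 / cycles_to_seconds(0.03, 0.852743))

  # troughs straddling the cycle boundary average on a common branch
  maps$trough[, 5] <- c(0.99, 0.01, 0.98)
  maps$trough[, 35] <- c(0.02, 0.03, 0.04)
  res2 <- estimate_pwv(maps, sites, path, 0.02, cycle_time_s = 1)
  expect_equal(res2$transit_s, mean(c(0.02, 0.03, 0.04)) -
                 mean(c(-0.01, 0.01, -0.02)))
})
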