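# Contour extraction, circularity, phase segmentation and jump detection.

test_that("circularity matches closed forms on analytic polygons", {
  expect_equal(circularity(polygon_circle(50, 720)), 1, tolerance = 1e-3)
  sq <- cbind(y = c(0, 0, 2, 2), x = c(0, 2, 2, 0))
  expect_equal(circularity(sq), pi / 4, tolerance = 1e-9)
  rect <- cbind(y = c(0, 0, 1, 1), x = c(0, 3, 3, 0))
  expect_equal(circularity(rect), 3 * pi / 16, tolerance = 1e-9)
})

test_that("circularity is scale invariant and errors on degenerate input", {
  poly <- cbind(y = c(0, 1, 3, 2), x = c(0, 4, 3, -1))
  expect_equal(circularity(poly * 17.3), circularity(poly))
  expect_error(circularity(poly[1:2, , drop = FALSE]))
})

test_that("extract_contour recovers areas of known shapes", {
  # square mask occupying most of the frame
  m <- matrix(FALSE, 120, 120)
  m[11:110, 11:110] <- TRUE
  a <- abs(spheromorph:::polygon_area_yx(extract_contour(m)))
  expect_equal(a, 100^2, tolerance = 0.01)

  d <- disc_mask(50)
  ad <- abs(spheromorph:::polygon_area_yx(extract_contour(d)))
  expect_equal(ad, pi * 50^2, tolerance = 0.01)
  expect_equal(circularity(extract_contour(d)), 1, tolerance = 0.01)
})

test_that("interior holes are filled and multiple components are pruned", {
  d <- disc_mask(30)
  holed <- d
  holed[45:55, 45:55] <- FALSE
  expect_equal(extract_contour(holed), extract_contour(d))

  two <- d
  two[2:5, 2:5] <- TRUE # small spurious component
  expect_message(p <- extract_contour(two), "components")
  expect_equal(abs(spheromorph:::polygon_area_yx(p)),
               abs(spheromorph:::polygon_area_yx(extract_contour(d))))
  expect_error(extract_contour(matrix(FALSE, 10, 10)), "empty mask")
})

test_that("constant disc movie yields a constant circularity series", {
  d <- disc_mask(30)
  movie <- array(d, dim = c(dim(d), 5))
  ts <- circularity_timeseries(movie, interval_h = 1, smooth_window_h = 0)
  expect_equal(diff(range(ts$circularity)), 0)
  expect_warning(segment_phases(ts), "flat")
  expect_true(all(suppressWarnings(segment_phases(ts))$labels == "latent"))
})

test_that("empty frames are flagged NA, not interpolated", {
  d <- disc_mask(20)
  movie <- array(d, dim = c(dim(d), 4))
  movie[, , 3] <- FALSE
  expect_warning(ts <- circularity_timeseries(movie, smooth_window_h = 0),
                 "empty")
  expect_true(is.na(ts$circularity[3]))
  expect_false(anyNA(ts$circularity[-3]))
})

test_that("a step-function series segments latent before, static after", {
  v <- c(rep(0.6, 10), rep(0.9, 10))
  ser <- data.frame(frame = 1:20, time_h = 0:19, circularity = v, smoothed = v)
  seg <- segment_phases(ser)
  expect_lte(abs(seg$t_latent_end - 9), 1)
  expect_lte(abs(seg$t_static_start - 10), 1)
  expect_true(all(seg$labels[1:9] == "latent"))
  expect_true(all(seg$labels[12:20] == "static"))
})

test_that("programmed phase boundaries are recovered within one hour", {
  kin <- rounding_kinetics(c_inf = 0.95, t_latent = 5, t_static = 18)
  g <- generate_rounding_movie(3, kin, frames = 25, interval_h = 1)
  ts <- circularity_timeseries(g$movie)
  seg <- segment_phases(ts)
  expect_lte(abs(seg$t_latent_end - 5), 1)
  expect_lte(abs(seg$t_static_start - 18), 1)
})

test_that("jump detection finds programmed steps and nothing else", {
  # no jumps: empty detection at a sane min_step
  kin <- rounding_kinetics(c_inf = 0.9, t_latent = 5, t_static = 18)
  g <- generate_rounding_movie(2, kin, frames = 25)
  ts <- circularity_timeseries(g$movie)
  expect_equal(nrow(detect_jumps(ts, min_step = 0.08)), 0)

  # one programmed jump of 0.15 at t = 10 h
  kinj <- rounding_kinetics(c_inf = 0.8, t_latent = 5, t_static = 18,
                            jumps = data.frame(time_h = 10, delta = 0.15))
  gj <- generate_rounding_movie(3, kinj, frames = 25)
  jm <- detect_jumps(circularity_timeseries(gj$movie), min_step = 0.08)
  expect_equal(nrow(jm), 1)
  expect_lte(abs(jm$time_h - 10), 1)
  expect_gte(jm$delta, 0.15 * 0.8)

  # two well-separated jumps arrive in time order
  kin2 <- rounding_kinetics(c_inf = 0.7, t_latent = 5, t_static = 18,
                            jumps = data.frame(time_h = c(8, 14),
                                               delta = c(0.1, 0.12)))
  g2 <- generate_rounding_movie(3, kin2, frames = 25)
  j2 <- detect_jumps(circularity_timeseries(g2$movie), min_step = 0.06)
  expect_equal(nrow(j2), 2)
  expect_lte(abs(j2$time_h[1] - 8), 1)
  expect_lte(abs(j2$time_h[2] - 14), 1)
})
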