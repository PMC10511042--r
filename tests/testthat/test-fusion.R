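# Fusion generator and doublet metrics.

test_that("tangent discs give doublet length 4r and near-zero contact", {
  g <- generate_fusion_movie(radii = c(30, 30), neck_growth = list(rate = 8),
                             frames = 5, interval_h = 0.5)
  m0 <- g$movie[, , 1] # neck width 0 at t = 0
  expect_equal(g$truth$contact_length_px[1], 0)
  expect_equal(g$truth$doublet_length_px[1], 120)
  expect_lte(abs(doublet_axis_length(m0, open_radius = 0) - 120), 1)
  expect_lte(contact_length(m0)$contact_px, 2)
})

test_that("a single disc is flagged fully fused with contact = diameter", {
  sz <- 101
  Y <- outer(1:sz, rep(1, sz)); X <- t(Y)
  disc <- (Y - 51)^2 + (X - 51)^2 <= 40^2
  expect_lte(abs(doublet_axis_length(disc, open_radius = 0) - 80), 1)
  cc <- contact_length(disc)
  expect_true(cc$fully_fused)
  expect_lte(abs(cc$contact_px - 80), 2)
})

test_that("full coalescence of equal radii approaches circularity 1", {
  g <- generate_fusion_movie(radii = c(25, 25),
                             neck_growth = function(t) pmin(10 * t, 49.9),
                             frames = 12, interval_h = 1)
  final <- g$movie[, , 12]
  expect_equal(circularity(extract_contour(final)), 1, tolerance = 0.02)
})

test_that("programmed linear neck growth is recovered within 2 px", {
  g <- generate_fusion_movie(radii = c(30, 26), neck_growth = list(rate = 6),
                             frames = 14, interval_h = 0.5)
  fs <- fusion_timeseries(g$movie, interval_h = 0.5)
  expect_true(all(abs(fs$contact_length_px - g$truth$contact_length_px) <= 2))
  expect_true(all(abs(fs$doublet_length_px - g$truth$doublet_length_px) <= 2))
  # monotonicity under the coalescence law
  expect_true(all(diff(fs$contact_length_px) >= -1e-9))
  expect_true(all(diff(fs$doublet_length_px) <= 1e-9))
  # normalisation contracts
  expect_equal(fs$doublet_length_norm[1], 1)
  renorm <- fs$doublet_length_norm / fs$doublet_length_norm[1]
  expect_equal(renorm, fs$doublet_length_norm)
})

test_that("excessive neck widths are clamped with a warning", {
  expect_warning(
    g <- generate_fusion_movie(radii = c(20, 20), neck_growth = list(rate = 30),
                               frames = 8, interval_h = 1),
    "clamped"
  )
  expect_true(all(g$truth$contact_length_px <= 40))
})

test_that("disconnected doublets are rejected", {
  m <- matrix(FALSE, 60, 120)
  Y <- outer(1:60, rep(1, 120)); X <- outer(rep(1, 60), 1:120)
  m[(Y - 30)^2 + (X - 25)^2 <= 15^2] <- TRUE
  m[(Y - 30)^2 + (X - 95)^2 <= 15^2] <- TRUE
  expect_error(doublet_axis_length(m), "not in contact")
})

test_that("constant movies give constant fusion series", {
  g <- generate_fusion_movie(radii = c(20, 20), neck_growth = function(t) 10,
                             frames = 4, interval_h = 1)
  fs <- fusion_timeseries(g$movie, interval_h = 1)
  expect_equal(diff(range(fs$contact_length_px)), 0)
  expect_equal(diff(range(fs$doublet_length_px)), 0)
})
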