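# Junction morphometrics: projection, PA detection, Feret, TJ skeleton
# length.

test_that("maximum projection keeps every bright structure", {
  one <- array(0, dim = c(1, 5, 5)); one[1, 3, 3] <- 2
  expect_equal(project_max(one), one[1, , ])
  two <- array(0, dim = c(2, 5, 5))
  two[1, 2, 2] <- 1; two[2, 4, 4] <- 3
  p <- project_max(two)
  expect_equal(p[2, 2], 1)
  expect_equal(p[4, 4], 3)
  expect_equal(max(p), 3)
})

test_that("max Feret uses the corner convention and matches brute force", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(max_feret(m), sqrt(2))
  bar <- matrix(FALSE, 5, 12); bar[3, 2:11] <- TRUE
  expect_equal(max_feret(bar), sqrt(10^2 + 1^2))
  # exhaustive all-pairs oracle on irregular objects up to 500 px
  set.seed(19)
  for (k in 1:5) {
    m <- matrix(runif(30 * 30) < 0.3, 30, 30)
    m[15, 15] <- TRUE
    expect_equal(max_feret(m), feret_bruteforce(m))
  }
  # lower bound: at least the bounding-box extent
  bb <- which(bar, arr.ind = TRUE)
  expect_gte(max_feret(bar),
             max(diff(range(bb[, 1])), diff(range(bb[, 2]))))
})

test_that("PA detection recovers programmed spots and enforces attachment", {
  g <- generate_junction_image(n_cells = 9, pa_spec = list(n = 6, length_px = 10),
                               side = 22, seed = 5)
  pa <- detect_pa(g$channels$spots, g$channels$actin)
  expect_equal(nrow(pa), length(g$truth$pa_lengths_px))
  expect_true(all(abs(pa$feret_px - 10) <= 1.5))

  # a spot far from any actin bundle is rejected
  spots <- matrix(0, 60, 60)
  spots[10:12, 10:18] <- 1 # isolated bar
  actin <- matrix(0, 60, 60)
  actin[40:42, 10:50] <- 1
  out <- detect_pa(spots, actin, threshold = 0.5)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "rejected"), 1L)

  # empty spot channel
  none <- detect_pa(matrix(0, 60, 60), actin, threshold = 0.5)
  expect_equal(nrow(none), 0)
  expect_error(detect_pa(matrix(0, 10, 10), matrix(0, 20, 20)), "shapes")
})

test_that("pa_density is count per area", {
  objs <- data.frame(id = 1:10, area_px = 5, feret_px = 3, attached = TRUE)
  expect_equal(pa_density(objs, 100 * 100), 1e-3)
  expect_equal(pa_density(objs[0, ], 100), 0)
})

test_that("skeletonization preserves single-pixel lines", {
  m <- matrix(FALSE, 20, 40)
  m[10, 5:34] <- TRUE
  sk <- spheromorph:::skeletonize(m)
  expect_equal(sum(sk), 30)
  len <- spheromorph:::skeleton_length(sk)
  expect_equal(len$pixel_count, 30)
  expect_equal(len$euclidean_px, 29) # 29 unit steps between 30 pixels
})

test_that("skeleton length is invariant to line thickening", {
  g2 <- generate_junction_image(n_cells = 7, pa_spec = list(n = 0),
                                side = 20, line_width = 2, seed = 8)
  g6 <- generate_junction_image(n_cells = 7, pa_spec = list(n = 0),
                                side = 20, line_width = 6, seed = 8)
  l2 <- tj_length(g2$channels$tj, tophat_radius = 8)$length_euclidean_px
  l6 <- tj_length(g6$channels$tj, tophat_radius = 8)$length_euclidean_px
  expect_lt(abs(l6 / l2 - 1), 0.05)
})

test_that("hexagonal tessellation TJ length is recovered within 5%", {
  g <- generate_junction_image(n_cells = 12, pa_spec = list(n = 0),
                               side = 20, seed = 3)
  # oracle: sum of programmed edge lengths, computed independently
  e <- g$truth$edges
  expected <- sum(sqrt((e[, "y2"] - e[, "y1"])^2 + (e[, "x2"] - e[, "x1"])^2))
  res <- tj_length(g$channels$tj, g$channels$nuclei)
  expect_lt(abs(res$length_euclidean_px / expected - 1), 0.05)
  expect_equal(res$cell_count, 12)
  # arithmetic identities
  expect_equal(res$per_cell * res$cell_count, res$total_length_px)
  expect_equal(res$per_area * res$field_area_px2, res$total_length_px)
})

test_that("two cells sharing one straight border measure its length", {
  g <- generate_junction_image(n_cells = 2, pa_spec = list(n = 0),
                               layout = "two_cell", border_length_px = 40,
                               seed = 2)
  expect_equal(g$truth$tj_length_px, 40)
  res <- tj_length(g$channels$tj, g$channels$nuclei)
  expect_lt(abs(res$length_euclidean_px / 40 - 1), 0.08)
  expect_equal(res$cell_count, 2)
})

test_that("round blobs without linear structure yield near-zero TJ length", {
  img <- matrix(0, 80, 80)
  for (cc in list(c(20, 20), c(60, 50))) {
    Y <- outer(1:80, rep(1, 80)); X <- t(Y)
    img[(Y - cc[1])^2 + (X - cc[2])^2 <= 8^2] <- 1
  }
  res <- tj_length(img, tophat_radius = 5)
  g <- generate_junction_image(n_cells = 9, pa_spec = list(n = 0), side = 20,
                               seed = 1)
  full <- tj_length(g$channels$tj, tophat_radius = 5)
  expect_lt(res$total_length_px, 0.15 * full$total_length_px)
})
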