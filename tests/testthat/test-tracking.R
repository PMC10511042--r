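# DoG filtering, nucleus detection and nearest-neighbor linking.

test_that("DoG rejects constant input and is linear", {
  vol <- array(7.3, dim = c(16, 20, 20))
  out <- dog_filter(vol)
  expect_lt(max(abs(out)), 1e-6 * 7.3)

  set.seed(5)
  v <- array(rnorm(16 * 20 * 20), dim = c(16, 20, 20))
  expect_equal(dog_filter(v * 3.7), 3.7 * dog_filter(v), tolerance = 1e-12)
  expect_error(dog_filter(array(0, dim = c(4, 20, 20))), "sigma_large")
})

test_that("DoG response peaks at the center of a matched blob", {
  shape <- c(16, 32, 32)
  ctr <- c(8, 17, 15)
  g <- array(0, dim = shape)
  for (z in 1:16) for (y in 1:32) for (x in 1:32) {
    g[z, y, x] <- exp(-((z - ctr[1])^2 / (2 * 1^2) +
                          (y - ctr[2])^2 / (2 * 2.2^2) +
                          (x - ctr[3])^2 / (2 * 2.2^2)))
  }
  out <- dog_filter(g)
  amax <- which(out == max(out), arr.ind = TRUE)[1, ]
  expect_true(all(abs(amax - ctr) <= 1))
})

test_that("detection finds all well-separated blobs with subvoxel accuracy", {
  mm <- motion_model("independent_walk", n_cells = 6, step_scale = 0.5)
  g <- generate_nuclei_movie(mm, shape = c(16, 70, 70), frames = 2,
                             snr = Inf, seed = 13)
  det <- detect_nuclei(dog_filter(g$movie[, , , 1]))
  tru <- g$truth$positions[g$truth$positions$frame == 1, ]
  expect_equal(nrow(det), 6)
  for (i in seq_len(6)) {
    dd <- sqrt((det$z - tru$z[i])^2 + (det$y - tru$y[i])^2 +
                 (det$x - tru$x[i])^2)
    j <- which.min(dd)
    expect_lt(abs(det$y[j] - tru$y[i]), 0.5)
    expect_lt(abs(det$x[j] - tru$x[i]), 0.5)
    expect_lt(abs(det$z[j] - tru$z[i]), 1)
  }
})

test_that("empty volumes yield no detections", {
  out <- detect_nuclei(array(0, dim = c(10, 20, 20)))
  expect_equal(nrow(out), 0)
})

test_that("two blobs closer than min_separation collapse to one detection", {
  shape <- c(12, 30, 30)
  vol <- array(0, dim = shape)
  add_blob <- function(v, c0) {
    for (z in 1:shape[1]) for (y in 1:shape[2]) for (x in 1:shape[3]) {
      v[z, y, x] <- v[z, y, x] + exp(-((z - c0[1])^2 / 2 +
                                         (y - c0[2])^2 / (2 * 4) +
                                         (x - c0[3])^2 / (2 * 4)))
    }
    v
  }
  vol <- add_blob(vol, c(6, 15, 14))
  vol <- add_blob(vol, c(6, 15, 17))
  det <- detect_nuclei(dog_filter(vol), min_separation = c(2, 4, 4))
  expect_equal(nrow(det), 1)
  expect_gte(attr(det, "suppressed"), 0)
})

test_that("a drifting singleton links into one trajectory", {
  det <- data.frame(frame = 1:10, z = 5, y = 10 + 0.5 * (1:10), x = 7,
                    score = 1)
  trj <- link_nearest_neighbor(det, max_link_dist = 2)
  expect_equal(length(unique(trj$track_id)), 1)
  expect_equal(trj$frame, 1:10)
})

test_that("gating prevents links beyond max_link_dist", {
  det <- data.frame(frame = rep(1:2, each = 2),
                    z = 0, y = c(0, 50, 10, 60), x = 0, score = 1)
  trj <- link_nearest_neighbor(det, max_link_dist = 5)
  expect_equal(length(unique(trj$track_id)), 4) # all links gated out
  trj2 <- link_nearest_neighbor(det, max_link_dist = 12)
  expect_equal(length(unique(trj2$track_id)), 2) # 0->10, 50->60, no swaps
  t1 <- trj2[trj2$track_id == trj2$track_id[trj2$frame == 1 & trj2$y == 0], ]
  expect_equal(sort(t1$y), c(0, 10))
})

test_that("linking is translation equivariant", {
  set.seed(31)
  det <- data.frame(frame = rep(1:5, each = 4),
                    z = runif(20, 0, 10), y = runif(20, 0, 50),
                    x = runif(20, 0, 50), score = 1)
  trj <- link_nearest_neighbor(det, max_link_dist = 30)
  det2 <- det
  det2$z <- det2$z + 5; det2$y <- det2$y - 13; det2$x <- det2$x + 2.5
  trj2 <- link_nearest_neighbor(det2, max_link_dist = 30)
  expect_equal(trj2$track_id, trj$track_id)
  expect_equal(trj2$y, trj$y - 13)
})

test_that("greedy and optimal linking agree on well-separated movies", {
  mm <- motion_model("independent_walk", n_cells = 8, step_scale = 1)
  g <- generate_nuclei_movie(mm, shape = c(16, 90, 90), frames = 8,
                             snr = 10, seed = 17)
  res_g <- track_nuclei(g$movie, max_link_dist = 4, method = "greedy")
  res_o <- track_nuclei(g$movie, max_link_dist = 4, method = "optimal")
  expect_equal(res_g$trajectories$track_id, res_o$trajectories$track_id)
})

test_that("tracking recovers ground-truth identities on a clean movie", {
  mm <- motion_model("independent_walk", n_cells = 10, step_scale = 1.2)
  g <- generate_nuclei_movie(mm, shape = c(16, 90, 90), frames = 10,
                             snr = 8, seed = 23)
  res <- track_nuclei(g$movie, max_link_dist = 4)
  pr <- match_detections(res$detections, g$truth$positions, radius = 2)
  expect_gte(pr$precision, 0.95)
  expect_gte(pr$recall, 0.95)
  acc <- link_identity_accuracy(res$trajectories, g$truth$positions)
  expect_gte(acc, 0.95)
})
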