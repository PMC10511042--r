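# Displacement vectors, neighbor graph, direction correlation r and its
# summaries.

test_that("displacement vectors reproduce programmed drift", {
  tracks <- data.frame(track_id = rep(1:2, each = 3),
                       frame = rep(1:3, 2),
                       z = c(0, 0, 0, 1, 1, 1),
                       y = c(0, 0, 0, 2, 2, 2),
                       x = c(0, 1, 2, 5, 5, 5))
  v <- displacement_vectors(tracks, 2)
  expect_equal(v$dx[v$track_id == 1], 1)
  expect_equal(unlist(v[v$track_id == 2, c("dz", "dy", "dx")]),
               c(dz = 0, dy = 0, dx = 0))
  # anisotropy correction scales each axis
  v2 <- displacement_vectors(tracks, 2, scale = c(2, 1, 1))
  expect_equal(v2$dz, v$dz * 2)
})

test_that("cells absent from the previous frame are excluded and counted", {
  tracks <- data.frame(track_id = c(1, 1, 2), frame = c(1, 2, 2),
                       z = 0, y = 0, x = c(0, 1, 5))
  v <- displacement_vectors(tracks, 2)
  expect_equal(nrow(v), 1)
  expect_equal(attr(v, "coverage")$present, 2)
  expect_equal(attr(v, "coverage")$with_vector, 1)
})

test_that("neighbor graph matches a brute-force distance oracle", {
  # regular 5x5 grid, spacing d: R = 1.5 d includes diagonals (d*sqrt(2))
  d <- 10
  pos <- expand.grid(y = d * (0:4), x = d * (0:4))
  pos <- data.frame(id = seq_len(nrow(pos)), z = 0, y = pos$y, x = pos$x)
  prs <- neighbor_pairs(pos)
  # oracle: all pairs within 1.5 * median NN distance, by brute force
  P <- as.matrix(pos[, c("z", "y", "x")])
  D <- as.matrix(stats::dist(P)); diag(D) <- Inf
  R <- 1.5 * stats::median(apply(D, 1, min))
  expected <- sum(D[upper.tri(D)] <= R)
  expect_equal(nrow(prs), expected)
  expect_true(expected > 40) # axial plus diagonal neighbors present

  # all pairs are unordered, unique, no self-pairs
  expect_true(all(prs$id_a < prs$id_b))
  expect_equal(nrow(unique(prs)), nrow(prs))
})

test_that("isolated cells and sub-radius pairs behave at the extremes", {
  two <- data.frame(id = 1:2, z = 0, y = c(0, 3), x = 0)
  expect_equal(nrow(neighbor_pairs(two)), 1)
  one <- data.frame(id = 1, z = 0, y = 0, x = 0)
  expect_equal(nrow(neighbor_pairs(one)), 0)
})

test_that("direction correlation gives the canonical exact values", {
  v <- c(1, 2, -0.5)
  expect_equal(direction_correlation(v, 2 * v), 1)
  expect_equal(direction_correlation(v, -v), -1)
  expect_equal(direction_correlation(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_true(is.na(direction_correlation(c(0, 0, 0), v)))
  expect_true(is.na(direction_correlation(v, c(1e-4, 0, 0),
                                          eps_motion = 0.3)))
  # symmetry and rescaling invariance
  w <- c(-2, 0.3, 1)
  expect_equal(direction_correlation(v, w), direction_correlation(w, v))
  expect_equal(direction_correlation(3.1 * v, w), direction_correlation(v, w))
})

test_that("isotropic 3D directions give r uniform on [-1, 1]", {
  set.seed(101)
  n <- 10000
  va <- matrix(rnorm(3 * n), ncol = 3)
  vb <- matrix(rnorm(3 * n), ncol = 3)
  r <- rowSums(va * vb) / sqrt(rowSums(va^2) * rowSums(vb^2))
  # uniform cosine: fraction above 0.8 = 0.1, mean 0
  expect_lt(abs(mean(r > 0.8) - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  expect_lt(abs(mean(r)), 3 / sqrt(3 * n))
  ks <- suppressWarnings(stats::ks.test(r, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("density matrix normalisation contracts hold", {
  tab <- data.frame(frame = rep(2:4, each = 10),
                    time_h = rep(1:3, each = 10),
                    id_a = 1, id_b = 2, r = 1, speed_a = 1, speed_b = 1)
  M <- correlation_density(tab, r_bins = 10, t_bin_h = 1)
  nz <- colSums(M) > 0
  expect_true(all(apply(M[, nz, drop = FALSE], 2, max) == 1))
  expect_true(all(M[10, nz] == 1)) # all mass in the top r bin
  expect_true(all(M[1:9, ] == 0))

  set.seed(7)
  tab2 <- tab
  tab2$r <- runif(30, -1, 1)
  Mg <- correlation_density(tab2, r_bins = 5, t_bin_h = 1,
                            normalize = "global")
  expect_equal(max(Mg), 1)
})

test_that("fraction_above matches closed forms", {
  tab <- data.frame(time_h = rep(7, 100), r = rep(1, 100))
  expect_equal(fraction_above(tab, 0.8, c(6, 9)), 1)
  expect_error(fraction_above(tab, 0.8, c(20, 30)), "window")
  set.seed(33)
  n <- 20000
  tabu <- data.frame(time_h = 7, r = runif(n, -1, 1))
  expect_lt(abs(fraction_above(tabu, 0.8, c(6, 9)) - 0.1),
            3 * sqrt(0.1 * 0.9 / n))
})

test_that("coordinated fraction rises monotonically with coherence", {
  # a single group isolates the coherence effect: every neighboring pair
  # shares the group step, diluted only by the individual-noise term
  fracs <- vapply(c(0.2, 0.6, 1), function(coh) {
    mm <- motion_model("coherent_groups", n_cells = 12, step_scale = 2,
                       coherence = coh, n_groups = 1)
    g <- generate_nuclei_movie(mm, shape = c(24, 130, 130), frames = 10,
                               snr = Inf, seed = 55)
    pos <- g$truth$positions
    names(pos)[names(pos) == "id"] <- "track_id"
    tab <- pair_correlations(pos, interval_h = 1, eps_motion = 0.1)
    mean(tab$r > 0.8)
  }, 0)
  expect_true(all(diff(fracs) > 0))
  expect_gt(fracs[3], 0.9)
})
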