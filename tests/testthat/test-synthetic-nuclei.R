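# Nuclei-movie generator: rendering fidelity, motion-model contracts,
# determinism, placement diagnostics.

test_that("noise-free single blob centroid matches the true position", {
  mm <- motion_model("independent_walk", n_cells = 1, step_scale = 1)
  g <- generate_nuclei_movie(mm, shape = c(16, 40, 40), frames = 4,
                             snr = Inf, seed = 3)
  for (f in 1:4) {
    vol <- g$movie[, , , f]
    idx <- which(vol > 0.05 * max(vol), arr.ind = TRUE)
    wts <- vol[idx]
    cen <- colSums(idx * wts) / sum(wts)
    tru <- g$truth$positions[g$truth$positions$frame == f, c("z", "y", "x")]
    expect_lt(max(abs(cen - as.numeric(tru))), 0.5)
  }
})

test_that("perfect coherence moves a group with identical displacements", {
  mm <- motion_model("coherent_groups", n_cells = 6, step_scale = 1.5,
                     coherence = 1, n_groups = 1)
  g <- generate_nuclei_movie(mm, shape = c(20, 120, 120), frames = 5,
                             snr = Inf, seed = 11)
  pos <- g$truth$positions
  for (f in 2:5) {
    cur <- pos[pos$frame == f, ]
    prev <- pos[pos$frame == f - 1, ]
    d <- as.matrix(cur[order(cur$id), c("z", "y", "x")]) -
      as.matrix(prev[order(prev$id), c("z", "y", "x")])
    expect_lt(max(apply(d, 2, function(v) diff(range(v)))), 1e-12)
  }
})

test_that("trajectory count is conserved and seeds reproduce exactly", {
  mm <- motion_model("independent_walk", n_cells = 8, step_scale = 1)
  a <- generate_nuclei_movie(mm, shape = c(12, 60, 60), frames = 6,
                             snr = 5, seed = 9)
  b <- generate_nuclei_movie(mm, shape = c(12, 60, 60), frames = 6,
                             snr = 5, seed = 9)
  expect_identical(a$movie, b$movie)
  expect_identical(a$truth, b$truth)
  counts <- table(a$truth$positions$frame)
  expect_true(all(counts == 8))
})

test_that("overcrowded placement is rejected with a diagnostic", {
  mm <- motion_model("independent_walk", n_cells = 500, step_scale = 1)
  expect_error(
    generate_nuclei_movie(mm, shape = c(8, 30, 30), frames = 2, seed = 1),
    "could not place"
  )
})

test_that("mixture ground truth recovers the coherent-pair fraction", {
  mm <- motion_model("mixture", n_cells = 60, step_scale = 2,
                     mixture_weight = 0.5)
  g <- generate_nuclei_movie(mm, shape = c(30, 170, 170), frames = 12,
                             snr = Inf, seed = 21)
  pairs <- g$truth$pairs
  # oracle: pair correlations computed directly from true positions
  pos <- g$truth$positions
  rs <- c()
  for (f in 2:12) {
    cur <- pos[pos$frame == f, ]; prev <- pos[pos$frame == f - 1, ]
    for (p in seq_len(nrow(pairs))) {
      va <- as.numeric(cur[cur$id == pairs$id_a[p], c("z", "y", "x")]) -
        as.numeric(prev[prev$id == pairs$id_a[p], c("z", "y", "x")])
      vb <- as.numeric(cur[cur$id == pairs$id_b[p], c("z", "y", "x")]) -
        as.numeric(prev[prev$id == pairs$id_b[p], c("z", "y", "x")])
      rs <- c(rs, sum(va * vb) / sqrt(sum(va^2) * sum(vb^2)))
    }
  }
  # coherent pairs give r ~ 1, independent ones r ~ uniform[-1, 1]:
  # expected fraction above 0.9 = w + (1 - w) * 0.05
  w_hat <- mean(pairs$coherent)
  frac <- mean(rs > 0.9)
  expected <- w_hat + (1 - w_hat) * 0.05
  n <- length(rs)
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / n) + 0.01)
  # and the realised coherent fraction is binomially consistent with 0.5
  expect_lt(abs(w_hat - 0.5), 3 * sqrt(0.25 / nrow(pairs)))
})
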