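# Displacement-direction correlation of neighboring cell pairs: per-frame
# displacement vectors from trajectories, a neighbor graph, the cosine
# correlation r in [-1, 1], its time-resolved density, and the coordinated
# fraction (share of pairs with r above a cutoff in a time window).

#' Per-cell displacement vectors at one frame
#'
#' `v = position(frame) - position(frame - 1)` for every trajectory
#' present in both frames. Anisotropic voxel calibration can be folded in
#' via `scale` so the vector is in isotropic pixel units.
#'
#' @param tracks data frame `track_id, frame, z, y, x` (from
#'   [link_nearest_neighbor()] or ground-truth positions with `id`
#'   renamed).
#' @param frame frame index, >= second frame present.
#' @param scale per-axis multipliers `c(z, y, x)` converting voxel to
#'   isotropic px units.
#' @return data frame `track_id, dz, dy, dx` with attribute `coverage`
#'   (cells present in `frame` but excluded for lack of a predecessor).
#' @export
displacement_vectors <- function(tracks, frame, scale = c(1, 1, 1)) {
  idc <- if ("track_id" %in% names(tracks)) "track_id" else "id"
  cur <- tracks[tracks$frame == frame, , drop = FALSE]
  prev <- tracks[tracks$frame == frame - 1L, , drop = FALSE]
  if (nrow(cur) == 0) stop(sprintf("no positions at frame %d", frame))
  m <- match(cur[[idc]], prev[[idc]])
  ok <- !is.na(m)
  out <- data.frame(
    track_id = cur[[idc]][ok],
    dz = (cur$z[ok] - prev$z[m[ok]]) * scale[1],
    dy = (cur$y[ok] - prev$y[m[ok]]) * scale[2],
    dx = (cur$x[ok] - prev$x[m[ok]]) * scale[3]
  )
  attr(out, "coverage") <- list(present = nrow(cur), with_vector = sum(ok))
  out
}

#' Neighbor pairs of a point configuration
#'
#' Default rule: two cells are neighbors when their distance is below
#' `alpha` times the median nearest-neighbor distance of the frame
#' (adaptive radius). Alternative: `"knn"` links each cell to its `k`
#' nearest cells (symmetrised).
#'
#' @param positions data frame with columns `id` (or `track_id`), `z`,
#'   `y`, `x` for a single frame.
#' @param rule `"radius"` (default) or `"knn"`.
#' @param alpha radius multiplier for the adaptive-radius rule.
#' @param k neighbor count for the knn rule.
#' @return data frame `id_a, id_b` (unordered pairs, `id_a < id_b`) with
#'   attribute `rule` recording the rule and parameters.
#' @export
neighbor_pairs <- function(positions, rule = c("radius", "knn"),
                           alpha = 1.5, k = 4L) {
  rule <- match.arg(rule)
  idc <- if ("id" %in% names(positions)) "id" else "track_id"
  ids <- positions[[idc]]
  n <- length(ids)
  empty <- data.frame(id_a = ids[0], id_b = ids[0])
  if (n < 2) return(structure(empty, rule = list(name = rule)))
  P <- as.matrix(positions[, c("z", "y", "x")])
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  if (rule == "radius") {
    nn <- apply(D, 1, min)
    R <- alpha * stats::median(nn)
    adj <- D <= R
    params <- list(name = "radius", alpha = alpha, radius = R)
  } else {
    k <- min(k, n - 1L)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) adj[i, order(D[i, ])[seq_len(k)]] <- TRUE
    adj <- adj | t(adj)
    params <- list(name = "knn", k = k)
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  out <- data.frame(id_a = pmin(ids[idx[, 1]], ids[idx[, 2]]),
                    id_b = pmax(ids[idx[, 1]], ids[idx[, 2]]))
  structure(out[order(out$id_a, out$id_b), , drop = FALSE], rule = params)
}

#' Direction correlation of two displacement vectors
#'
#' The cosine of the angle between the two displacement directions:
#' +1 for parallel motion, -1 for antiparallel (cells moving apart or
#' passing), 0 for orthogonal. A componentwise Pearson variant is
#' available for sensitivity analysis.
#'
#' @param v_a,v_b numeric 3-vectors (displacements in px).
#' @param method `"cosine"` (default) or `"pearson"`.
#' @param eps_motion minimum displacement magnitude; below it the
#'   direction is undefined and `NA` is returned.
#' @return r in \[-1, 1\], or `NA` for sub-threshold motion.
#' @export
direction_correlation <- function(v_a, v_b, method = c("cosine", "pearson"),
                                  eps_motion = 0) {
  method <- match.arg(method)
  na_ <- sqrt(sum(v_a^2)); nb_ <- sqrt(sum(v_b^2))
  if (na_ < eps_motion || nb_ < eps_motion || na_ == 0 || nb_ == 0) {
    return(NA_real_)
  }
  if (method == "cosine") {
    r <- sum(v_a * v_b) / (na_ * nb_)
  } else {
    if (stats::sd(v_a) == 0 || stats::sd(v_b) == 0) return(NA_real_)
    r <- stats::cor(v_a, v_b)
  }
  min(max(r, -1), 1)
}

#' Pair correlation table over a whole trajectory set
#'
#' For every frame (from the second onward), builds the neighbor graph on
#' the current positions and records the displacement-direction
#' correlation of each neighboring pair in which both cells moved at
#' least `eps_motion` px.
#'
#' @inheritParams neighbor_pairs
#' @param tracks data frame `track_id, frame, z, y, x`.
#' @param interval_h frame interval in hours.
#' @param eps_motion minimum displacement magnitude in px/frame; slower
#'   cells have no defined direction and their pairs are omitted (the
#'   exclusion count is reported in the `exclusions` attribute).
#' @param method correlation flavor, see [direction_correlation()].
#' @param scale anisotropy correction, see [displacement_vectors()].
#' @return data frame `frame, time_h, id_a, id_b, r, speed_a, speed_b`
#'   with attributes `exclusions` and `rule`.
#' @export
pair_correlations <- function(tracks, interval_h = 1, eps_motion = 0.3,
                              rule = "radius", alpha = 1.5, k = 4L,
                              method = "cosine", scale = c(1, 1, 1)) {
  frames <- sort(unique(tracks$frame))
  rows <- vector("list", length(frames))
  excluded <- 0L
  rule_rec <- NULL
  for (fi in seq_along(frames)[-1]) {
    f <- frames[fi]
    if (frames[fi] != frames[fi - 1] + 1) next
    vec <- displacement_vectors(tracks, f, scale = scale)
    if (nrow(vec) < 2) next
    pos <- tracks[tracks$frame == f, , drop = FALSE]
    pos <- pos[match(vec$track_id,
                     pos[[if ("track_id" %in% names(pos)) "track_id" else "id"]]),
               , drop = FALSE]
    pos$id <- vec$track_id
    prs <- neighbor_pairs(pos, rule = rule, alpha = alpha, k = k)
    rule_rec <- attr(prs, "rule")
    if (nrow(prs) == 0) next
    va <- as.matrix(vec[match(prs$id_a, vec$track_id), c("dz", "dy", "dx")])
    vb <- as.matrix(vec[match(prs$id_b, vec$track_id), c("dz", "dy", "dx")])
    sa <- sqrt(rowSums(va^2)); sb <- sqrt(rowSums(vb^2))
    ok <- sa >= eps_motion & sb >= eps_motion
    excluded <- excluded + sum(!ok)
    if (!any(ok)) next
    r <- rowSums(va[ok, , drop = FALSE] * vb[ok, , drop = FALSE]) /
      (sa[ok] * sb[ok])
    if (method == "pearson") {
      r <- vapply(which(ok), function(i) {
        direction_correlation(va[i, ], vb[i, ], method = "pearson")
      }, 0)
    }
    rows[[fi]] <- data.frame(frame = f, time_h = (f - 1) * interval_h,
                             id_a = prs$id_a[ok], id_b = prs$id_b[ok],
                             r = pmin(pmax(r, -1), 1),
                             speed_a = sa[ok], speed_b = sb[ok])
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(frame = integer(0), time_h = numeric(0), id_a = integer(0),
               id_b = integer(0), r = numeric(0), speed_a = numeric(0),
               speed_b = numeric(0))
  attr(out, "exclusions") <- excluded
  attr(out, "rule") <- rule_rec
  attr(out, "eps_motion") <- eps_motion
  out
}

#' Time-resolved density of the pair correlation r
#'
#' 2D histogram of (time, r). With `normalize = "column"` each time
#' column is rescaled so its maximum is 1 (so every time slice shows its
#' own modal structure); `"global"` rescales by the overall maximum.
#'
#' @param table pair correlation table from [pair_correlations()].
#' @param r_bins number of bins on r in \[-1, 1\].
#' @param t_bin_h time bin width in hours.
#' @param normalize `"column"` (default) or `"global"`.
#' @return matrix r_bins x n_time_bins (rows ordered from r = -1 up),
#'   with attributes `r_breaks`, `t_breaks`, `empty_columns`.
#' @export
correlation_density <- function(table, r_bins = 40L, t_bin_h = 1,
                                normalize = c("column", "global")) {
  normalize <- match.arg(normalize)
  if (nrow(table) == 0) stop("empty pair correlation table")
  r_breaks <- seq(-1, 1, length.out = r_bins + 1L)
  t_max <- max(table$time_h)
  t_breaks <- seq(0, t_max + t_bin_h, by = t_bin_h)
  ri <- findInterval(table$r, r_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ti <- findInterval(table$time_h, t_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  M <- matrix(0, r_bins, length(t_breaks) - 1L)
  for (i in seq_along(ri)) M[ri[i], ti[i]] <- M[ri[i], ti[i]] + 1
  empty <- which(colSums(M) == 0)
  if (normalize == "column") {
    cm <- apply(M, 2, max)
    nonzero <- cm > 0
    M[, nonzero] <- sweep(M[, nonzero, drop = FALSE], 2, cm[nonzero], "/")
  } else {
    M <- M / max(M)
  }
  structure(M, r_breaks = r_breaks, t_breaks = t_breaks,
            empty_columns = empty, normalize = normalize)
}

#' Coordinated fraction of neighboring pairs
#'
#' Share of pair-frame records within a time window whose correlation
#' exceeds `r_min` — e.g. the fraction of pairs with r > 0.8 between 6
#' and 9 hours.
#'
#' @param table pair correlation table from [pair_correlations()].
#' @param r_min correlation cutoff.
#' @param window `c(t0, t1)` in hours, inclusive.
#' @return fraction in \[0, 1\].
#' @export
fraction_above <- function(table, r_min = 0.8, window = c(6, 9)) {
  sel <- table$time_h >= window[1] & table$time_h <= window[2]
  if (!any(sel)) stop("no pair records in the requested time window")
  mean(table$r[sel] > r_min)
}
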