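# Nucleus detection in 3D stacks by anisotropic difference-of-Gaussians
# band-pass filtering, local-maximum extraction with subvoxel refinement,
# and frame-to-frame nearest-neighbor trajectory linking.

#' Difference-of-Gaussians filter parameters
#'
#' Defaults follow the common confocal setting of paired sigmas
#' 1.9/3.8 px in XY and 0.7/1.4 px in Z, reflecting the ~2-3x coarser
#' axial sampling of spinning-disc stacks.
#'
#' @param sigma_small small-kernel sigmas `c(sz, sy, sx)` in voxels.
#' @param sigma_large large-kernel sigmas `c(sz, sy, sx)`; must exceed
#'   `sigma_small` componentwise.
#' @return object of class `dog_params`.
#' @export
dog_params <- function(sigma_small = c(0.7, 1.9, 1.9),
                       sigma_large = c(1.4, 3.8, 3.8)) {
  stopifnot(length(sigma_small) == 3, length(sigma_large) == 3,
            all(sigma_small > 0), all(sigma_large > sigma_small))
  structure(list(sigma_small = sigma_small, sigma_large = sigma_large,
                 border = "reflect"),
            class = "dog_params")
}

#' 3D difference-of-Gaussians filter
#'
#' Band-pass response `G(sigma_small) - G(sigma_large)` emphasising
#' blob-like structures at the nucleus scale; constant (DC) input maps to
#' zero. Borders are mirror-reflected.
#'
#' @param vol numeric 3D array (z, y, x).
#' @param params a [dog_params()] object.
#' @return filtered array, same shape.
#' @export
dog_filter <- function(vol, params = dog_params()) {
  stopifnot(length(dim(vol)) == 3, inherits(params, "dog_params"))
  if (any(dim(vol) < 4 * params$sigma_large)) {
    stop("volume smaller than 4x sigma_large in at least one axis")
  }
  gaussian_blur3d(vol, params$sigma_small) -
    gaussian_blur3d(vol, params$sigma_large)
}

# Strict 26-neighborhood local maxima of a 3D array (logical array).
local_maxima3d <- function(v) {
  d <- dim(v)
  pad <- array(-Inf, d + 2L)
  pad[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- v
  res <- array(TRUE, d)
  iz <- 1L + seq_len(d[1]); iy <- 1L + seq_len(d[2]); ix <- 1L + seq_len(d[3])
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    res <- res & (v > pad[iz + dz, iy + dy, ix + dx])
  }
  res
}

# Per-axis subvoxel refinement by a quadratic fit through the maximum and
# its two axial neighbors; offset clamped to +-0.5 voxel.
quadratic_offset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (fm - fp) / den
  max(min(off, 0.5), -0.5)
}

#' Detect nuclei in a DoG-filtered volume
#'
#' Local maxima of the filtered response above a threshold, greedily
#' suppressed so that no two detections fall within an anisotropic
#' exclusion ellipsoid, then refined to subvoxel coordinates by a local
#' quadratic fit along each axis.
#'
#' @param filtered 3D array from [dog_filter()].
#' @param threshold numeric response threshold, or `"otsu"` (default) for
#'   Otsu's threshold on the positive responses.
#' @param min_separation exclusion radii `c(z, y, x)` in voxels; defaults
#'   2 px in Z and 4 px in XY.
#' @return data frame `z, y, x, score` (one row per detection; possibly
#'   zero rows) with attribute `suppressed` counting discarded maxima.
#' @export
detect_nuclei <- function(filtered, threshold = "otsu",
                          min_separation = c(2, 4, 4)) {
  stopifnot(length(dim(filtered)) == 3, length(min_separation) == 3)
  if (identical(threshold, "otsu")) {
    pos <- filtered[filtered > 0]
    if (length(pos) < 2) {
      return(structure(data.frame(z = numeric(0), y = numeric(0),
                                  x = numeric(0), score = numeric(0)),
                       suppressed = 0L))
    }
    threshold <- otsu_threshold(pos)
  }
  cand <- which(local_maxima3d(filtered) & filtered > threshold,
                arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(structure(data.frame(z = numeric(0), y = numeric(0),
                                x = numeric(0), score = numeric(0)),
                     suppressed = 0L))
  }
  scores <- filtered[cand]
  ord <- order(scores, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  scores <- scores[ord]

  keep <- logical(nrow(cand))
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) > 0) {
      dd <- sweep(kept, 2, p)
      if (any(rowSums(sweep(dd, 2, min_separation, "/")^2) < 1)) next
    }
    keep[i] <- TRUE
    kept <- rbind(kept, p)
  }
  n_suppressed <- sum(!keep)
  cand <- cand[keep, , drop = FALSE]
  scores <- scores[keep]

  d <- dim(filtered)
  refined <- t(vapply(seq_len(nrow(cand)), function(i) {
    p <- cand[i, ]
    out <- as.numeric(p)
    for (ax in 1:3) {
      if (p[ax] > 1 && p[ax] < d[ax]) {
        pm <- p; pm[ax] <- p[ax] - 1L
        pp <- p; pp[ax] <- p[ax] + 1L
        out[ax] <- out[ax] + quadratic_offset(
          filtered[pm[1], pm[2], pm[3]],
          filtered[p[1], p[2], p[3]],
          filtered[pp[1], pp[2], pp[3]])
      }
    }
    out
  }, numeric(3)))

  structure(data.frame(z = refined[, 1], y = refined[, 2], x = refined[, 3],
                       score = scores),
            suppressed = n_suppressed)
}

#' Detect nuclei in every frame of a 3D+t movie
#'
#' Convenience wrapper: DoG-filters and detects each frame, returning a
#' detection table.
#'
#' @inheritParams detect_nuclei
#' @param movie numeric 4D array (z, y, x, frame).
#' @param params a [dog_params()].
#' @return data frame `frame, z, y, x, score`.
#' @export
detect_nuclei_movie <- function(movie, params = dog_params(),
                                threshold = "otsu",
                                min_separation = c(2, 4, 4)) {
  stopifnot(length(dim(movie)) == 4)
  frames <- dim(movie)[4]
  out <- vector("list", frames)
  for (f in seq_len(frames)) {
    det <- detect_nuclei(dog_filter(movie[, , , f], params),
                         threshold = threshold,
                         min_separation = min_separation)
    if (nrow(det) > 0) det <- cbind(frame = f, det)
    out[[f]] <- det
  }
  out <- out[vapply(out, nrow, 0L) > 0]
  if (length(out) == 0) {
    return(data.frame(frame = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), score = numeric(0)))
  }
  do.call(rbind, out)
}

# Greedy nearest-neighbor matching between two point sets: candidate pairs
# sorted by ascending distance, matched one-to-one; ties broken by lowest
# row index (stable order). Returns an integer vector match_b_for_a.
greedy_match <- function(A, B, max_dist) {
  na <- nrow(A); nb <- nrow(B)
  match_ab <- rep(NA_integer_, na)
  if (na == 0 || nb == 0) return(match_ab)
  D <- outer(rowSums(A^2), rep(1, nb)) + outer(rep(1, na), rowSums(B^2)) -
    2 * A %*% t(B)
  D[D < 0] <- 0
  D <- sqrt(D)
  ok <- which(D <= max_dist)
  if (length(ok) == 0) return(match_ab)
  ord <- ok[order(D[ok])]
  used_b <- logical(nb)
  ia <- ((ord - 1L) %% na) + 1L
  ib <- ((ord - 1L) %/% na) + 1L
  for (k in seq_along(ord)) {
    if (is.na(match_ab[ia[k]]) && !used_b[ib[k]]) {
      match_ab[ia[k]] <- ib[k]
      used_b[ib[k]] <- TRUE
    }
  }
  match_ab
}

# Exact rectangular linear assignment (rows <= cols) by the
# shortest-augmenting-path method with potentials (Jonker-Volgenant).
# Returns the assigned column index per row.
lap_solve <- function(C) {
  n <- nrow(C); m <- ncol(C)
  stopifnot(n <= m)
  u <- rep(0, n)
  v <- rep(0, m + 1L)       # index 1 = virtual column 0
  p <- rep(0L, m + 1L)      # p[j] = row owning column j-1 (0 = free)
  way <- rep(0L, m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free_j <- which(!used)
      cur <- C[i0, free_j - 1L] - u[i0] - v[free_j]
      upd <- cur < minv[free_j]
      minv[free_j[upd]] <- cur[upd]
      way[free_j[upd]] <- j0
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assigned <- rep(NA_integer_, n)
  owned <- which(p[-1L] > 0L)
  assigned[p[owned + 1L]] <- owned
  assigned
}

# Optimal (minimum total distance) one-to-one matching with unmatched
# allowed beyond max_dist: dummy columns at cost max_dist absorb unmatched
# rows, gated pairs cost slightly more than the dummy.
optimal_match <- function(A, B, max_dist) {
  na <- nrow(A); nb <- nrow(B)
  match_ab <- rep(NA_integer_, na)
  if (na == 0 || nb == 0) return(match_ab)
  D <- outer(rowSums(A^2), rep(1, nb)) + outer(rep(1, na), rowSums(B^2)) -
    2 * A %*% t(B)
  D[D < 0] <- 0
  D <- sqrt(D)
  big <- max_dist * 1.0001
  C <- matrix(big, na, nb + na)
  C[, seq_len(nb)] <- pmin(D, big)
  C[cbind(seq_len(na), nb + seq_len(na))] <- max_dist
  assigned <- lap_solve(C)
  gated <- assigned <= nb & D[cbind(seq_len(na), pmin(assigned, nb))] <= max_dist
  match_ab[gated] <- assigned[gated]
  match_ab
}

#' Link per-frame detections into trajectories
#'
#' Between consecutive frames, detections are matched one-to-one by the
#' nearest-neighbor method: candidate pairs within `max_link_dist` are
#' taken in ascending distance order (greedy; default) or by minimum total
#' distance (`method = "optimal"`). Unmatched detections terminate or
#' start trajectories. No gap closing.
#'
#' @param detections data frame `frame, z, y, x` (e.g. from
#'   [detect_nuclei_movie()]).
#' @param max_link_dist maximum frame-to-frame displacement in px.
#' @param method `"greedy"` or `"optimal"`.
#' @return data frame `track_id, frame, z, y, x` sorted by track then
#'   frame; attribute `max_link_dist` records the gate.
#' @export
link_nearest_neighbor <- function(detections, max_link_dist,
                                  method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(all(c("frame", "z", "y", "x") %in% names(detections)),
            max_link_dist > 0)
  if (length(unique(detections$frame)) < 2) {
    stop("need detections in at least 2 frames")
  }
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  by_frame <- split(seq_len(nrow(detections)), detections$frame)

  track_of <- rep(NA_integer_, nrow(detections))
  next_id <- 1L
  first <- by_frame[[as.character(frames[1])]]
  track_of[first] <- seq_len(length(first))
  next_id <- length(first) + 1L

  matcher <- if (method == "greedy") greedy_match else optimal_match
  for (k in seq_len(length(frames) - 1L)) {
    fa <- frames[k]; fb <- frames[k + 1L]
    ia <- by_frame[[as.character(fa)]]
    ib <- by_frame[[as.character(fb)]]
    A <- as.matrix(detections[ia, c("z", "y", "x")])
    B <- as.matrix(detections[ib, c("z", "y", "x")])
    m <- if (fb == fa + 1L) matcher(A, B, max_link_dist)
         else rep(NA_integer_, length(ia)) # non-contiguous: no links
    linked_b <- logical(length(ib))
    for (i in seq_along(ia)) {
      if (!is.na(m[i])) {
        track_of[ib[m[i]]] <- track_of[ia[i]]
        linked_b[m[i]] <- TRUE
      }
    }
    fresh <- which(!linked_b)
    if (length(fresh) > 0) {
      track_of[ib[fresh]] <- next_id + seq_along(fresh) - 1L
      next_id <- next_id + length(fresh)
    }
  }

  out <- data.frame(track_id = track_of,
                    frame = detections$frame,
                    z = detections$z, y = detections$y, x = detections$x)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  attr(out, "max_link_dist") <- max_link_dist
  attr(out, "method") <- method
  out
}

#' Detect and track nuclei in one call
#'
#' @inheritParams detect_nuclei_movie
#' @inheritParams link_nearest_neighbor
#' @return list with `detections` and `trajectories`.
#' @export
track_nuclei <- function(movie, params = dog_params(), threshold = "otsu",
                         min_separation = c(2, 4, 4), max_link_dist = 5,
                         method = "greedy") {
  det <- detect_nuclei_movie(movie, params, threshold, min_separation)
  trj <- link_nearest_neighbor(det, max_link_dist, method)
  list(detections = det, trajectories = trj)
}
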