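# Synthetic 3D+t nuclei movies: anisotropic Gaussian blobs moving as
# coherent sub-groups, independent random walkers, passing (antiparallel)
# pairs, or a coherent/independent mixture — with exact ground-truth
# positions, identities and pair structure.

#' Motion model for synthetic nuclei
#'
#' @param mode one of `"coherent_groups"`, `"independent_walk"`,
#'   `"passing_pairs"`, `"mixture"`.
#' @param n_cells number of nuclei.
#' @param step_scale displacement magnitude in px/frame (> 0).
#' @param coherence fraction of the displacement shared within a group, in
#'   \[0, 1\] (`coherent_groups` only; 1 = rigid common translation).
#' @param mixture_weight fraction of pairs moving coherently (`mixture`
#'   only), in \[0, 1\].
#' @param n_groups number of coherent groups (`coherent_groups` only).
#' @param rotation_rad_per_frame optional rigid rotation of each coherent
#'   group about its hinge (initial centroid), emulating swing-arm folding
#'   of cell-mass segments without simulating mechanics.
#' @return object of class `motion_model`.
#' @export
motion_model <- function(mode = c("coherent_groups", "independent_walk",
                                  "passing_pairs", "mixture"),
                         n_cells, step_scale = 1, coherence = 1,
                         mixture_weight = 0.5, n_groups = 3L,
                         rotation_rad_per_frame = 0) {
  mode <- match.arg(mode)
  stopifnot(n_cells >= 1, step_scale > 0,
            coherence >= 0, coherence <= 1,
            mixture_weight >= 0, mixture_weight <= 1, n_groups >= 1)
  if (mode %in% c("passing_pairs", "mixture") && n_cells %% 2L != 0L) {
    stop("pair-structured modes require an even n_cells")
  }
  structure(list(mode = mode, n_cells = as.integer(n_cells),
                 step_scale = step_scale, coherence = coherence,
                 mixture_weight = mixture_weight,
                 n_groups = as.integer(n_groups),
                 rotation_rad_per_frame = rotation_rad_per_frame),
            class = "motion_model")
}

# Isotropic random 3D unit vectors, n x 3 (z, y, x).
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# Place n points in box [margin, dims - margin] with pairwise Euclidean
# separation >= min_sep. Pair-structured modes place members of a pair at
# exactly pair_dist from each other so that designated pairs are spatial
# neighbors.
place_nuclei <- function(n, dims, min_sep, pair_structured = FALSE,
                         pair_dist = NULL, margin, max_tries = 5000L) {
  lo <- margin                 # per-axis vector
  hi <- dims - margin
  if (any(hi <= lo)) stop("volume too small for the requested margin")
  pos <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(paste0("could not place %d nuclei with separation %.1f px ",
                          "in a %s volume (placed %d); enlarge the volume or ",
                          "reduce n_cells"),
                   n, min_sep, paste(dims, collapse = "x"), placed))
    }
    p <- lo + stats::runif(3) * (hi - lo)
    if (pair_structured) {
      u <- random_unit_vectors(1)[1, ]
      q <- p + pair_dist * u
      if (any(q < lo | q > hi)) next
      prev <- pos[seq_len(placed), , drop = FALSE]
      if (placed > 0) {
        dmin <- min(sqrt(rowSums((prev - rep(p, each = placed))^2)),
                    sqrt(rowSums((prev - rep(q, each = placed))^2)))
        if (dmin < min_sep) next
      }
      pos[placed + 1L, ] <- p
      pos[placed + 2L, ] <- q
      placed <- placed + 2L
    } else {
      if (placed > 0) {
        prev <- pos[seq_len(placed), , drop = FALSE]
        if (min(sqrt(rowSums((prev - rep(p, each = placed))^2))) < min_sep) next
      }
      pos[placed + 1L, ] <- p
      placed <- placed + 1L
    }
  }
  pos
}

# One motion step: returns an n x 3 displacement matrix.
motion_step <- function(model, pos, state) {
  n <- model$n_cells
  s <- model$step_scale
  disp <- switch(
    model$mode,
    independent_walk = s * random_unit_vectors(n),
    coherent_groups = {
      g_step <- s * random_unit_vectors(model$n_groups)
      shared <- g_step[state$groups, , drop = FALSE]
      if (model$rotation_rad_per_frame != 0) {
        th <- model$rotation_rad_per_frame
        for (g in seq_len(model$n_groups)) {
          idx <- which(state$groups == g)
          rel <- pos[idx, c(2, 3), drop = FALSE] -
            rep(state$hinges[g, c(2, 3)], each = length(idx))
          rot <- cbind(rel[, 1] * cos(th) - rel[, 2] * sin(th),
                       rel[, 1] * sin(th) + rel[, 2] * cos(th))
          shared[idx, 2:3] <- shared[idx, 2:3] + (rot - rel)
        }
      }
      shared + (1 - model$coherence) * s * random_unit_vectors(n)
    },
    passing_pairs = {
      d <- matrix(0, n, 3)
      d[state$pairs[, 1], ] <- s * state$pair_dirs
      d[state$pairs[, 2], ] <- -s * state$pair_dirs
      d
    },
    mixture = {
      d <- s * random_unit_vectors(n)
      coh <- which(state$pair_coherent)
      for (k in coh) d[state$pairs[k, 2], ] <- d[state$pairs[k, 1], ]
      d
    }
  )
  disp
}

#' Generate a synthetic 3D+t nuclei movie with ground truth
#'
#' Nuclei are rendered as anisotropic Gaussian blobs (peak amplitude 1)
#' plus additive Gaussian noise of standard deviation `1/snr`. Initial
#' positions are drawn with pairwise separation at least
#' `4 * max(psf_sigmas)`; positions reflect at the volume margin so blobs
#' never leave the rendered field.
#'
#' @param model a [motion_model()].
#' @param shape integer volume dimensions `c(z, y, x)` in voxels.
#' @param frames number of frames, >= 2.
#' @param psf_sigmas blob Gaussian sigmas `c(sz, sy, sx)` in voxels.
#' @param snr peak-amplitude-to-noise-sd ratio; `Inf` for noise-free.
#' @param seed integer seed; identical seeds give identical movies.
#' @param interval_h frame interval in hours (metadata; 0.1 h default).
#' @param hard_core excluded-volume distance in px: nuclei are solid
#'   objects, so steps that would bring two centers closer than this are
#'   redrawn (coherent pairs jointly, preserving their shared direction).
#'   Default `3 * max(psf_sigmas)`; 0 disables. Not applied to
#'   `coherent_groups`, whose rigid translation preserves spacing by
#'   construction.
#' @return list with `movie` (numeric array z * y * x * frame), `truth`
#'   (list: `positions` data frame `frame, id, z, y, x`; `pairs` for
#'   pair-structured modes with `id_a, id_b, coherent`; `groups` for
#'   coherent mode), and `meta`.
#' @export
generate_nuclei_movie <- function(model, shape, frames,
                                  psf_sigmas = c(1.0, 2.2, 2.2),
                                  snr = 10, seed = 1L,
                                  interval_h = 0.1,
                                  hard_core = 3 * max(psf_sigmas)) {
  stopifnot(inherits(model, "motion_model"), length(shape) == 3,
            frames >= 2, all(psf_sigmas > 0), snr > 0)
  set.seed(as.integer(seed))
  n <- model$n_cells
  min_sep <- 4 * max(psf_sigmas)
  margin <- 3 * psf_sigmas     # anisotropic: thin z-stacks keep usable depth

  pair_structured <- model$mode %in% c("passing_pairs", "mixture")
  pos <- place_nuclei(n, shape, min_sep,
                      pair_structured = pair_structured,
                      pair_dist = min_sep, margin = margin)

  state <- list()
  if (model$mode == "coherent_groups") {
    groups <- rep(seq_len(model$n_groups), length.out = n)
    hinges <- t(vapply(seq_len(model$n_groups), function(g) {
      colMeans(pos[groups == g, , drop = FALSE])
    }, numeric(3)))
    state <- list(groups = groups, hinges = hinges)
  }
  if (pair_structured) {
    pairs <- cbind(seq(1L, n, by = 2L), seq(2L, n, by = 2L))
    state$pairs <- pairs
    state$pair_dirs <- random_unit_vectors(nrow(pairs))
    state$pair_coherent <- stats::runif(nrow(pairs)) < model$mixture_weight
  }

  all_pos <- array(NA_real_, dim = c(frames, n, 3))
  all_pos[1, , ] <- pos
  lo <- margin; hi <- shape - margin
  for (f in 2:frames) {
    d <- motion_step(model, pos, state)
    if (model$mode != "coherent_groups" && hard_core > 0) {
      pos <- step_with_hard_core(model, pos, d, state, lo, hi, hard_core)
      all_pos[f, , ] <- pos
      next
    }
    if (model$mode == "coherent_groups") {
      # bounce the shared step of a whole group so that perfect coherence
      # keeps displacements identical within the group
      for (g_ in seq_len(model$n_groups)) {
        idx <- which(state$groups == g_)
        for (ax in 1:3) {
          nxt <- pos[idx, ax] + d[idx, ax]
          if (any(nxt < lo[ax] | nxt > hi[ax])) d[idx, ax] <- -d[idx, ax]
        }
      }
      pos <- pos + d
    } else {
      pos <- pos + d
      # reflect per cell at the margins so blobs stay renderable
      for (ax in 1:3) {
        below <- pos[, ax] < lo[ax]
        above <- pos[, ax] > hi[ax]
        pos[below, ax] <- 2 * lo[ax] - pos[below, ax]
        pos[above, ax] <- 2 * hi[ax] - pos[above, ax]
      }
    }
    all_pos[f, , ] <- pos
  }

  movie <- array(0, dim = c(shape, frames))
  for (f in seq_len(frames)) {
    vol <- render_blobs(shape, matrix(all_pos[f, , ], ncol = 3), psf_sigmas)
    if (is.finite(snr)) {
      vol <- vol + stats::rnorm(length(vol), sd = 1 / snr)
    }
    movie[, , , f] <- vol
  }

  positions <- data.frame(
    frame = rep(seq_len(frames), each = n),
    id = rep(seq_len(n), frames),
    z = as.vector(t(all_pos[, , 1])),
    y = as.vector(t(all_pos[, , 2])),
    x = as.vector(t(all_pos[, , 3]))
  )
  truth <- list(positions = positions)
  if (pair_structured) {
    truth$pairs <- data.frame(id_a = state$pairs[, 1], id_b = state$pairs[, 2],
                              coherent = if (model$mode == "mixture")
                                state$pair_coherent else FALSE)
  }
  if (model$mode == "coherent_groups") truth$groups <- state$groups

  list(movie = movie, truth = truth,
       meta = list(generator = "nuclei", model = model, shape = shape,
                   frames = frames, psf_sigmas = psf_sigmas, snr = snr,
                   seed = as.integer(seed), interval_h = interval_h,
                   min_separation = min_sep))
}

# Sequential hard-core update: move each motion unit (a tied pair, or a
# single cell) by its proposed step; if a member would come closer than
# hard_core to any other nucleus the unit's step is redrawn (up to 20
# times; the unit then stays put for the frame). Reflection at the
# margins is applied to each candidate.
step_with_hard_core <- function(model, pos, d, state, lo, hi, hard_core) {
  n <- nrow(pos)
  s <- model$step_scale
  units <- if (model$mode %in% c("passing_pairs", "mixture")) {
    lapply(seq_len(nrow(state$pairs)), function(k) state$pairs[k, ])
  } else {
    as.list(seq_len(n))
  }
  # split tied mixture pairs: independent members move individually
  if (model$mode == "mixture") {
    tied <- state$pair_coherent
    units <- c(lapply(which(tied), function(k) state$pairs[k, ]),
               as.list(state$pairs[!tied, , drop = FALSE]))
  }
  reflect1 <- function(p) {
    for (ax in 1:3) {
      if (p[ax] < lo[ax]) p[ax] <- 2 * lo[ax] - p[ax]
      if (p[ax] > hi[ax]) p[ax] <- 2 * hi[ax] - p[ax]
    }
    p
  }
  new_pos <- pos
  for (u in units) {
    members <- as.integer(u)
    cand_d <- d[members, , drop = FALSE]
    for (try_ in 1:20) {
      cand <- t(vapply(seq_along(members), function(i) {
        reflect1(pos[members[i], ] + cand_d[i, ])
      }, numeric(3)))
      others <- new_pos[-members, , drop = FALSE]
      dmin <- if (nrow(others) == 0) Inf else
        min(apply(cand, 1, function(p) {
          min(sqrt(rowSums((others - rep(p, each = nrow(others)))^2)))
        }))
      if (length(members) == 2) {
        dmin <- min(dmin, sqrt(sum((cand[1, ] - cand[2, ])^2)))
      }
      if (dmin >= hard_core) {
        new_pos[members, ] <- cand
        break
      }
      if (try_ == 20) break # stay put this frame
      # redraw: tied pairs share one direction, passing pairs oppose,
      # untied members draw independently
      if (length(members) == 2 && model$mode == "passing_pairs") {
        uvec <- random_unit_vectors(1)[1, ]
        cand_d <- rbind(s * uvec, -s * uvec)
      } else if (length(members) == 2) {
        uvec <- random_unit_vectors(1)[1, ]
        cand_d <- rbind(s * uvec, s * uvec)
      } else {
        cand_d <- s * random_unit_vectors(1)
      }
    }
  }
  new_pos
}

# Render Gaussian blobs (peak 1) at positions (m x 3, z/y/x) into a volume.
render_blobs <- function(shape, pos, sigmas) {
  vol <- array(0, dim = shape)
  rad <- ceiling(4 * sigmas)
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ]
    idx <- lapply(1:3, function(ax) {
      max(1L, floor(p[ax] - rad[ax])):min(shape[ax], ceiling(p[ax] + rad[ax]))
    })
    if (any(vapply(idx, length, 0L) == 0L)) next
    gz <- exp(-(idx[[1]] - p[1])^2 / (2 * sigmas[1]^2))
    gy <- exp(-(idx[[2]] - p[2])^2 / (2 * sigmas[2]^2))
    gx <- exp(-(idx[[3]] - p[3])^2 / (2 * sigmas[3]^2))
    vol[idx[[1]], idx[[2]], idx[[3]]] <-
      vol[idx[[1]], idx[[2]], idx[[3]]] + outer(gz, outer(gy, gx))
  }
  vol
}
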