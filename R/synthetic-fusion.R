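# Synthetic spheroid-fusion movies: two discs whose center distance is
# programmed so that the contact neck (the chord of their intersection)
# follows a prescribed growth law.

# Center distance giving contact half-width h for disc radii r1, r2
# (lens geometry: the chord lies where the two circles intersect).
center_distance_for_neck <- function(h, r1, r2) {
  sqrt(r1^2 - h^2) + sqrt(r2^2 - h^2)
}

#' Generate a synthetic fusion movie with ground truth
#'
#' Two discs of radii `r1`, `r2` move together so that the width of their
#' contact (the intersection chord, perpendicular to the line of centers)
#' follows the programmed neck-growth law. The ground truth records the
#' programmed contact length and the doublet long-axis length
#' `r1 + r2 + d(t)`.
#'
#' @param radii disc radii `c(r1, r2)` in px.
#' @param neck_growth function mapping time in hours to contact width in
#'   px, or a list `list(rate = px_per_h)` for linear growth from 0.
#' @param frames number of frames, >= 2.
#' @param interval_h frame interval in hours.
#' @param seed integer seed (kept for a uniform calling convention;
#'   rendering is deterministic).
#' @return list with `movie` (logical array y * x * frame), `truth` (data
#'   frame `frame, time_h, contact_length_px, doublet_length_px`), and
#'   `meta`. Neck widths beyond the geometric maximum `2 * min(radii)`
#'   are clamped with a warning.
#' @export
generate_fusion_movie <- function(radii, neck_growth = list(rate = 8),
                                  frames = 19, interval_h = 0.5,
                                  seed = 1L) {
  stopifnot(length(radii) == 2, all(radii > 0), frames >= 2)
  r1 <- radii[1]; r2 <- radii[2]
  law <- if (is.function(neck_growth)) neck_growth
         else function(t) neck_growth$rate * t
  times <- (seq_len(frames) - 1) * interval_h
  w <- vapply(times, law, 0)
  if (any(w < 0)) stop("neck_growth law produced negative widths")
  w_max <- 2 * min(r1, r2) * 0.999
  if (any(w > w_max)) {
    warning(sprintf("neck width clamped to the geometric maximum %.1f px",
                    w_max))
    w <- pmin(w, w_max)
  }
  d <- center_distance_for_neck(w / 2, r1, r2)

  size <- ceiling(2 * (r1 + r2) + max(r1, r2)) + 20L
  cy <- size / 2
  movie <- array(FALSE, dim = c(size, size, frames))
  Y <- outer(seq_len(size), rep(1, size))
  X <- outer(rep(1, size), seq_len(size))
  for (f in seq_len(frames)) {
    cx1 <- (size - d[f]) / 2
    cx2 <- cx1 + d[f]
    movie[, , f] <- ((Y - cy)^2 + (X - cx1)^2 <= r1^2) |
      ((Y - cy)^2 + (X - cx2)^2 <= r2^2)
  }

  list(
    movie = movie,
    truth = data.frame(frame = seq_len(frames), time_h = times,
                       contact_length_px = w,
                       doublet_length_px = r1 + r2 + d),
    meta = list(generator = "fusion", radii = radii, interval_h = interval_h,
                img_size = size, seed = as.integer(seed))
  )
}
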